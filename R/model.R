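#' Construct a metabolic model
#'
#' The package's in-memory representation of a genome-scale metabolic
#' model: a metabolite table, a reaction table with flux bounds, and a
#' sparse stoichiometric matrix `S` (metabolites x reactions, negative
#' coefficients for consumption). One reaction may be flagged as the
#' biomass (objective) reaction.
#'
#' @param id model identifier.
#' @param mets data frame with columns `id`, `name`, `formula`, `charge`,
#'   `compartment`. `formula`/`charge` may be `NA`.
#' @param rxns data frame with columns `id`, `name`, `lb`, `ub`,
#'   `is_exchange`, `is_biomass`.
#' @param S sparse stoichiometric matrix with `dimnames` matching
#'   `mets$id` and `rxns$id`.
#' @param biomass_reaction_id id of the biomass reaction, or `NA` when the
#'   model has none.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, S, biomass_reaction_id = NA_character_) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  for (col in c("formula")) if (is.null(mets[[col]])) mets[[col]] <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_real_
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- NA_character_
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$is_exchange)) rxns$is_exchange <- FALSE
  if (is.null(rxns$is_biomass)) rxns$is_biomass <- FALSE
  S <- methods::as(methods::as(methods::as(S, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  rownames(S) <- mets$id
  colnames(S) <- rxns$id
  m <- structure(list(id = id, mets = mets, rxns = rxns, S = S,
                      biomass_reaction_id = biomass_reaction_id),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite/reaction ids,
#' consistent matrix dimensions, `lb <= ub`, non-empty stoichiometries,
#' exchange reactions touching exactly one metabolite, and a resolvable
#' biomass reaction id when present.
#'
#' @param model a [metabolic_model].
#' @return the model, invisibly; errors describe the offending entity.
#' @export
validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns; S <- model$S
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1L])
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1L])
  }
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns)) {
    stop("stoichiometric matrix dimensions do not match tables")
  }
  bad <- which(rxns$lb > rxns$ub)
  if (length(bad)) stop("lb > ub for reaction ", rxns$id[bad[1L]])
  nnz <- Matrix::colSums(S != 0)
  empty <- which(nnz == 0 & !rxns$is_exchange & !rxns$is_biomass)
  if (length(empty)) stop("empty stoichiometry for reaction ", rxns$id[empty[1L]])
  exch <- which(rxns$is_exchange & nnz != 1)
  if (length(exch)) {
    stop("exchange reaction ", rxns$id[exch[1L]], " must touch exactly one metabolite")
  }
  if (!is.na(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rxns$id) {
    stop("biomass reaction ", model$biomass_reaction_id, " not in model")
  }
  invisible(model)
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$mets), "\n",
      "  reactions:   ", nrow(x$rxns),
      " (", sum(x$rxns$is_exchange), " exchange)\n",
      "  biomass:     ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Stoichiometry of one reaction as a named vector
#'
#' @param model a [metabolic_model] (or anything with an `S` slot).
#' @param rxn_id reaction id.
#' @return named numeric vector over the participating metabolites.
#' @export
reaction_stoichiometry <- function(model, rxn_id) {
  col <- model$S[, rxn_id, drop = TRUE]
  col[col != 0]
}

#' Remove reactions from a model
#'
#' Deletes the named reactions; useful for building gapped test strains
#' from a complete parent model (paired with the database holding the
#' deleted reactions as repair candidates).
#'
#' @param model a [metabolic_model].
#' @param reaction_ids character vector of reaction ids to delete.
#' @param prune_orphans drop metabolites no longer used by any reaction.
#' @return the reduced model.
#' @export
knockout <- function(model, reaction_ids, prune_orphans = FALSE) {
  unknown <- setdiff(reaction_ids, model$rxns$id)
  if (length(unknown)) {
    stop("knockout: unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(reaction_ids) == 0L) return(model)
  keep <- !model$rxns$id %in% reaction_ids
  rxns <- model$rxns[keep, , drop = FALSE]
  S <- model$S[, keep, drop = FALSE]
  mets <- model$mets
  if (prune_orphans) {
    used <- Matrix::rowSums(S != 0) > 0
    mets <- mets[used, , drop = FALSE]
    S <- S[used, , drop = FALSE]
  }
  bid <- model$biomass_reaction_id
  if (!is.na(bid) && !bid %in% rxns$id) bid <- NA_character_
  metabolic_model(model$id, mets, rxns, S, bid)
}
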