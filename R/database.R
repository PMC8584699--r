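#' @title Universal reaction database
#' @description A curated set of candidate reactions used for gap
#'   filling, with the metabolite catalog (formulas, charges) needed for
#'   mass-balance checks. Curation removes biomass equations, exchange
#'   reactions, reactions on a user exclusion list (e.g. reactions found
#'   only in eukaryotes), and reactions that fail the mass-balance check;
#'   survivors are reset to fully reversible bounds, since candidate
#'   directionality is decided later by per-compartment flux variability
#'   analysis.
#' @name reaction-database
NULL

#' Construct a reaction database
#'
#' @param rxns reaction data frame (`id`, `name`, `lb`, `ub`).
#' @param S sparse stoichiometry over the catalog metabolites.
#' @param mets metabolite catalog (`id`, `name`, `formula`, `charge`,
#'   `compartment`).
#' @param provenance free-text source tag.
#' @return object of class `reaction_database`.
#' @export
reaction_database <- function(rxns, S, mets, provenance = "") {
  db <- structure(list(rxns = as.data.frame(rxns), S = S,
                       mets = as.data.frame(mets),
                       provenance = provenance),
                  class = "reaction_database")
  rownames(db$S) <- db$mets$id
  colnames(db$S) <- db$rxns$id
  db
}

#' @exportS3Method base::print
print.reaction_database <- function(x, ...) {
  cat("<reaction_database> ", nrow(x$rxns), " reactions over ",
      nrow(x$mets), " metabolites",
      if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"), "\n",
      sep = "")
  invisible(x)
}

#' An empty reaction database
#' @param mets optional metabolite catalog to carry.
#' @return a [reaction_database] with no reactions.
#' @export
empty_database <- function(mets = NULL) {
  if (is.null(mets)) {
    mets <- data.frame(id = character(), name = character(),
                       formula = character(), charge = numeric(),
                       compartment = character())
  }
  reaction_database(
    data.frame(id = character(), name = character(),
               lb = numeric(), ub = numeric()),
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(nrow(mets), 0L)),
    mets, provenance = "empty")
}

#' Read a raw reaction set for curation
#'
#' The file is any COBRA-style JSON / SBML model; its reactions become
#' curation candidates and its metabolites the catalog.
#'
#' @param path model file holding the universal reaction set.
#' @param flux_cap global flux cap.
#' @return list with `rxns`, `S`, `mets` suitable for [curate_database()].
#' @export
read_raw_database <- function(path, flux_cap = 1000) {
  m <- read_model(path, flux_cap = flux_cap, require_biomass = FALSE)
  list(rxns = m$rxns, S = m$S, mets = m$mets)
}

#' Curate a universal reaction database
#'
#' Applies, in order: removal of biomass equations (id/name pattern
#' match), removal of exchange reactions, removal of reactions on the
#' exclusion list, and removal of reactions whose mass balance is
#' `"imbalanced"` (always) or `"undetermined"` (by default; retain them
#' with `keep_undetermined = TRUE`, or whitelist ids). Retained
#' reactions are reset to fully reversible bounds `(-flux_cap, flux_cap)`.
#'
#' @param raw list with `rxns`, `S`, `mets` (see [read_raw_database()]),
#'   or a [metabolic_model] / [reaction_database] to (re-)curate.
#' @param exclusions reaction ids to drop (e.g. eukaryote-only list).
#' @param biomass_patterns case-insensitive patterns identifying biomass
#'   equations.
#' @param keep_undetermined retain reactions whose balance cannot be
#'   determined (missing formulas).
#' @param whitelist reaction ids exempt from the balance rule.
#' @param flux_cap global flux cap used for the reversible reset.
#' @param provenance free-text source tag stored on the database.
#' @return a [reaction_database]; the removal counts per rule are
#'   attached as `attr(db, "curation_report")` (a data frame).
#' @export
curate_database <- function(raw, exclusions = character(),
                            biomass_patterns = .default_biomass_patterns,
                            keep_undetermined = FALSE,
                            whitelist = character(),
                            flux_cap = 1000,
                            provenance = "") {
  rxns <- raw$rxns; S <- raw$S; mets <- raw$mets
  n0 <- nrow(rxns)
  rule <- rep(NA_character_, n0)

  is_bio <- rep(FALSE, n0)
  for (p in biomass_patterns) {
    is_bio <- is_bio | grepl(p, rxns$id, ignore.case = TRUE) |
      grepl(p, rxns$name, ignore.case = TRUE)
  }
  if (!is.null(rxns$is_biomass)) is_bio <- is_bio | rxns$is_biomass
  rule[is.na(rule) & is_bio] <- "biomass"

  nnz <- Matrix::colSums(S != 0)
  rule[is.na(rule) & nnz == 1] <- "exchange"
  rule[is.na(rule) & rxns$id %in% exclusions] <- "excluded"

  todo <- which(is.na(rule) & !rxns$id %in% whitelist)
  for (k in todo) {
    st <- S[, k, drop = TRUE]; st <- st[st != 0]
    v <- check_mass_balance(st, mets)
    if (v == "imbalanced") rule[k] <- "imbalanced"
    if (v == "undetermined" && !keep_undetermined) rule[k] <- "undetermined"
  }

  keep <- is.na(rule)
  rxns_k <- rxns[keep, c("id", "name"), drop = FALSE]
  rxns_k$lb <- rep(-flux_cap, nrow(rxns_k))
  rxns_k$ub <- rep(flux_cap, nrow(rxns_k))
  S_k <- S[, keep, drop = FALSE]
  used <- Matrix::rowSums(S_k != 0) > 0
  db <- reaction_database(rxns_k, S_k[used, , drop = FALSE],
                          mets[used, , drop = FALSE],
                          provenance = provenance)
  report <- as.data.frame(table(rule = factor(
    rule[!keep],
    levels = c("biomass", "exchange", "excluded", "imbalanced",
               "undetermined"))))
  names(report) <- c("rule", "removed")
  report <- rbind(report,
                  data.frame(rule = "retained", removed = sum(keep)))
  attr(db, "curation_report") <- report
  db
}

#' Write a curation report as TSV
#'
#' @param db a curated [reaction_database].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(db, path) {
  rep <- attr(db, "curation_report")
  if (is.null(rep)) stop("database carries no curation report")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
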