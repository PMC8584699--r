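#' @title Community model assembly
#' @description One namespaced compartment per organism (the organism's
#'   reactions plus candidate database reactions), coupled through a
#'   common metabolite pool. Each member's extracellular metabolites are
#'   linked to the pool by reversible transfer reactions; the pool talks
#'   to the environment through one exchange per pool metabolite, whose
#'   bounds come from the medium. The pool balance row for metabolite i
#'   reads `sum_n w_n v_ex(i)^n - v_ex(i)^c = 0` (uptake negative), with
#'   `w_n = 1` or, in the abundance-weighted variant, the member's
#'   relative abundance.
#' @name community-builder
NULL

#' Construct a medium
#'
#' @param bounds named list/vector mapping a pool metabolite base id to
#'   `c(lb, ub)` on its environment exchange, uptake negative. Entries
#'   named `"<base_id>@<tag>"` are member-scoped overrides applied to
#'   that member's transfer reaction instead.
#' @param default_policy bounds for unlisted pool metabolites:
#'   `"open_secretion_only"` (secretion free, uptake forbidden) or
#'   `"closed"` (no environment flux at all).
#' @return object of class `medium`.
#' @export
medium <- function(bounds = list(),
                   default_policy = c("open_secretion_only", "closed")) {
  default_policy <- match.arg(default_policy)
  bounds <- lapply(bounds, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2L || is.na(b[1]) || is.na(b[2])) {
      stop("medium: each bound entry must be c(lb, ub)")
    }
    if (b[1] > b[2]) stop("medium: lb > ub in a bound entry")
    b
  })
  structure(list(bounds = bounds, default_policy = default_policy),
            class = "medium")
}

.policy_bounds <- function(policy, cap) {
  switch(policy,
         open_secretion_only = c(0, cap),
         closed = c(0, 0))
}

# base id of an extracellular metabolite: strip the trailing "_e"
# compartment suffix (shared BiGG namespace is assumed across members).
.base_id <- function(met_id) sub("_e$", "", met_id)

.is_extracellular <- function(mets, extracellular = "e") {
  (!is.na(mets$compartment) & mets$compartment == extracellular) |
    grepl("_e$", mets$id)
}

.ns <- function(id, tag) paste0(id, "@", tag)

# canonical stoichiometry key: proportional columns get the same key
.stoich_key <- function(st) {
  if (length(st) == 0L) return("")
  st <- st[order(names(st))]
  st <- st / st[[1L]]
  paste(names(st), sprintf("%.10g", st), collapse = ";", sep = ":")
}

#' Build one organism compartment
#'
#' Namespaces the model into a community compartment and merges in the
#' database's candidate reactions. The model's original exchange
#' reactions are dropped (the pool transfers installed by
#' [build_community()] replace them). Database reactions already present
#' in the model -- same id, or the same canonical stoichiometry -- are
#' not duplicated; the rest enter fully reversible. Candidates that
#' cannot connect to the member's network are kept here and removed
#' later by FVA pruning.
#'
#' @param model a [metabolic_model] with a biomass reaction.
#' @param db a [reaction_database] (possibly [empty_database()]).
#' @param tag compartment namespace tag, unique within the community.
#' @param min_growth required minimum biomass flux for this member
#'   (must be `>= 0`; the gap-filling problem requires `> 0`).
#' @param flux_cap global flux cap.
#' @param extracellular compartment tag marking extracellular species.
#' @return object of class `organism_compartment`.
#' @export
build_compartment <- function(model, db, tag, min_growth,
                              flux_cap = 1000, extracellular = "e") {
  if (is.na(model$biomass_reaction_id)) {
    stop("model '", model$id, "' has no biomass reaction")
  }
  if (min_growth < 0) stop("min_growth must be >= 0")
  keep <- !model$rxns$is_exchange | model$rxns$is_biomass
  rxns <- model$rxns[keep, , drop = FALSE]
  S <- model$S[, keep, drop = FALSE]
  mets <- model$mets

  model_keys <- vapply(rxns$id, function(j) {
    .stoich_key(S[, j, drop = TRUE][S[, j] != 0])
  }, "")
  db_new <- rep(TRUE, nrow(db$rxns))
  if (nrow(db$rxns)) {
    db_keys <- vapply(seq_len(nrow(db$rxns)), function(k) {
      st <- db$S[, k, drop = TRUE]; .stoich_key(st[st != 0])
    }, "")
    db_new <- !(db$rxns$id %in% rxns$id) & !(db_keys %in% model_keys)
  }
  db_rxns <- db$rxns[db_new, , drop = FALSE]
  db_S <- db$S[, db_new, drop = FALSE]

  new_mets <- setdiff(rownames(db_S)[Matrix::rowSums(db_S != 0) > 0],
                      mets$id)
  if (length(new_mets)) {
    add <- db$mets[match(new_mets, db$mets$id), , drop = FALSE]
    mets <- rbind(mets[, c("id", "name", "formula", "charge", "compartment")],
                  add[, c("id", "name", "formula", "charge", "compartment")])
  }
  # assemble compartment S over the union metabolite set
  nm <- nrow(mets)
  Sm <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = c(nm, nrow(rxns) + nrow(db_rxns)))
  midx <- stats::setNames(seq_len(nm), mets$id)
  Ssum <- Matrix::summary(methods::as(S, "TsparseMatrix"))
  if (nrow(Ssum)) {
    Sm[cbind(midx[rownames(S)[Ssum$i]], Ssum$j)] <- Ssum$x
  }
  if (nrow(db_rxns)) {
    Dsum <- Matrix::summary(methods::as(db_S, "TsparseMatrix"))
    if (nrow(Dsum)) {
      Sm[cbind(midx[rownames(db_S)[Dsum$i]], nrow(rxns) + Dsum$j)] <- Dsum$x
    }
  }
  comp_rxns <- data.frame(
    id = .ns(c(rxns$id, db_rxns$id), tag),
    orig_id = c(rxns$id, db_rxns$id),
    lb = c(rxns$lb, if (nrow(db_rxns)) rep(-flux_cap, nrow(db_rxns))),
    ub = c(rxns$ub, if (nrow(db_rxns)) rep(flux_cap, nrow(db_rxns))),
    source = c(rep("model", nrow(rxns)), rep("database", nrow(db_rxns))),
    is_biomass = c(rxns$is_biomass, rep(FALSE, nrow(db_rxns))),
    stringsAsFactors = FALSE)
  comp_mets <- data.frame(
    id = .ns(mets$id, tag),
    orig_id = mets$id,
    is_extracellular = .is_extracellular(mets, extracellular),
    stringsAsFactors = FALSE)
  rownames(Sm) <- comp_mets$id
  colnames(Sm) <- comp_rxns$id
  structure(list(organism_id = model$id, tag = tag,
                 mets = comp_mets, rxns = comp_rxns, S = Sm,
                 biomass_reaction_id = .ns(model$biomass_reaction_id, tag),
                 min_growth = min_growth, flux_cap = flux_cap),
            class = "organism_compartment")
}

#' @exportS3Method base::print
print.organism_compartment <- function(x, ...) {
  cat("<organism_compartment> ", x$tag, " (", x$organism_id, ")\n",
      "  model reactions:    ", sum(x$rxns$source == "model"), "\n",
      "  database reactions: ", sum(x$rxns$source == "database"), "\n",
      "  min growth:         ", x$min_growth, "\n", sep = "")
  invisible(x)
}

#' Assemble a community model
#'
#' Builds one compartment per member (see [build_compartment()]),
#' creates one pool metabolite per distinct extracellular base id seen
#' in any member or in the medium, installs a reversible transfer
#' reaction per (member, pool metabolite) pair with coefficients -1 on
#' the member's extracellular species and +1 on the pool species, and
#' one environment exchange per pool metabolite with bounds from the
#' medium (the default policy covers unlisted metabolites).
#'
#' @param models list of [metabolic_model]s (optionally named; names
#'   become compartment tags, otherwise `m1`, `m2`, ...).
#' @param db a [reaction_database].
#' @param med a [medium].
#' @param min_growth numeric vector of per-member growth floors,
#'   recycled if scalar.
#' @param abundances optional numeric vector of relative abundances in
#'   `(0, 1]` (named by tag or positional), summing to 1.
#' @param flux_cap global flux cap.
#' @param extracellular extracellular compartment tag.
#' @return object of class `community_model`.
#' @export
build_community <- function(models, db, med = medium(),
                            min_growth = 0.1, abundances = NULL,
                            flux_cap = 1000, extracellular = "e") {
  if (length(models) < 1L) stop("build_community: need at least one model")
  tags <- names(models)
  if (is.null(tags) || any(!nzchar(tags))) {
    tags <- paste0("m", seq_along(models))
  }
  if (anyDuplicated(tags)) stop("duplicate member tags")
  min_growth <- rep_len(min_growth, length(models))
  if (!is.null(abundances)) {
    abundances <- rep_len(abundances, length(models))
    names(abundances) <- tags
    if (abs(sum(abundances) - 1) > 1e-6) {
      stop("abundances must sum to 1")
    }
    if (any(abundances <= 0)) stop("abundances must be positive")
  }
  members <- Map(function(m, tg, g) {
    build_compartment(m, db, tg, g, flux_cap = flux_cap,
                      extracellular = extracellular)
  }, models, tags, min_growth)
  names(members) <- tags

  member_ext <- lapply(members, function(cp) {
    cp$mets[cp$mets$is_extracellular, , drop = FALSE]
  })
  pool_ids <- unique(c(unlist(lapply(member_ext, function(d) .base_id(d$orig_id))),
                       grep("@", names(med$bounds), invert = TRUE,
                            value = TRUE)))
  orphan <- setdiff(grep("@", names(med$bounds), invert = TRUE, value = TRUE),
                    unlist(lapply(member_ext, function(d) .base_id(d$orig_id))))
  if (length(orphan)) {
    warning("medium names metabolite(s) absent from all members: ",
            paste(orphan, collapse = ", "), " (inert pool entries)")
  }
  pool <- data.frame(base_id = pool_ids,
                     pool_id = .ns(pool_ids, "pool"),
                     environment_exchange_id = paste0("EXC_", pool_ids),
                     stringsAsFactors = FALSE)

  mets <- do.call(rbind, lapply(members, function(cp) {
    data.frame(id = cp$mets$id, member = cp$tag, stringsAsFactors = FALSE)
  }))
  mets <- rbind(mets, data.frame(id = pool$pool_id, member = "pool"))

  rxn_list <- lapply(members, function(cp) {
    data.frame(id = cp$rxns$id, member = cp$tag, type = cp$rxns$source,
               orig_id = cp$rxns$orig_id, base_id = NA_character_,
               lb = cp$rxns$lb, ub = cp$rxns$ub,
               is_biomass = cp$rxns$is_biomass, stringsAsFactors = FALSE)
  })
  transfers <- do.call(rbind, lapply(members, function(cp) {
    ext <- cp$mets[cp$mets$is_extracellular, , drop = FALSE]
    if (nrow(ext) == 0L) return(NULL)
    data.frame(id = paste0("TR_", .base_id(ext$orig_id), "@", cp$tag),
               member = cp$tag, type = "transfer",
               orig_id = ext$id, base_id = .base_id(ext$orig_id),
               lb = -flux_cap, ub = flux_cap, is_biomass = FALSE,
               stringsAsFactors = FALSE)
  }))
  envx <- data.frame(id = pool$environment_exchange_id,
                     member = NA_character_, type = "env_exchange",
                     orig_id = pool$base_id, base_id = pool$base_id,
                     lb = NA_real_, ub = NA_real_, is_biomass = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- rbind(do.call(rbind, rxn_list), transfers, envx)
  rownames(rxns) <- NULL

  midx <- stats::setNames(seq_len(nrow(mets)), mets$id)
  pidx <- stats::setNames(midx[pool$pool_id], pool$base_id)
  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  off <- 0L
  for (cp in members) {
    Ssum <- Matrix::summary(methods::as(cp$S, "TsparseMatrix"))
    trip_i <- c(trip_i, midx[cp$mets$id[Ssum$i]])
    trip_j <- c(trip_j, off + Ssum$j)
    trip_x <- c(trip_x, Ssum$x)
    off <- off + ncol(cp$S)
  }
  if (!is.null(transfers) && nrow(transfers)) {
    jt <- off + seq_len(nrow(transfers))
    trip_i <- c(trip_i, midx[transfers$orig_id], pidx[transfers$base_id])
    trip_j <- c(trip_j, jt, jt)
    trip_x <- c(trip_x, rep(-1, nrow(transfers)), rep(1, nrow(transfers)))
    off <- off + nrow(transfers)
  }
  je <- off + seq_len(nrow(envx))
  trip_i <- c(trip_i, pidx[envx$base_id])
  trip_j <- c(trip_j, je)
  trip_x <- c(trip_x, rep(-1, nrow(envx)))
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$id, rxns$id))

  cm <- structure(list(members = members, pool = pool, mets = mets,
                       rxns = rxns, S = S, medium = med,
                       abundances = abundances, flux_cap = flux_cap),
                  class = "community_model")
  apply_medium(cm, med)
}

#' @exportS3Method base::print
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$members), " member(s): ",
      paste(names(x$members), collapse = ", "), "\n",
      "  pool metabolites: ", nrow(x$pool), "\n",
      "  reactions:        ", nrow(x$rxns), "\n", sep = "")
  invisible(x)
}

#' Apply a medium to a community
#'
#' Replaces every environment-exchange bound according to the medium
#' (listed base ids take their bounds, unlisted ones the default
#' policy). Member transfer bounds are untouched except for
#' member-scoped entries named `"<base_id>@<tag>"`. Idempotent.
#'
#' @param cm a [community_model].
#' @param med a [medium].
#' @return the updated community.
#' @export
apply_medium <- function(cm, med) {
  pol <- .policy_bounds(med$default_policy, cm$flux_cap)
  env <- which(cm$rxns$type == "env_exchange")
  for (k in env) {
    b <- med$bounds[[cm$rxns$base_id[k]]]
    if (is.null(b)) b <- pol
    cm$rxns$lb[k] <- b[1]; cm$rxns$ub[k] <- b[2]
  }
  scoped <- grep("@", names(med$bounds), value = TRUE)
  for (nm in scoped) {
    k <- which(cm$rxns$type == "transfer" &
                 cm$rxns$id == paste0("TR_", nm))
    if (length(k) == 0L) {
      warning("member-scoped medium entry '", nm,
              "' matches no transfer reaction")
      next
    }
    b <- med$bounds[[nm]]
    cm$rxns$lb[k] <- b[1]; cm$rxns$ub[k] <- b[2]
  }
  cm$medium <- med
  cm
}

# Community stoichiometry with pool-row weights applied to the transfer
# columns (w_n = 1 unweighted, = relative abundance in the weighted
# variant).
.community_S <- function(cm, weighted = FALSE) {
  S <- cm$S
  if (!weighted) return(S)
  if (is.null(cm$abundances)) {
    stop("weighted formulation requires member abundances")
  }
  tr <- which(cm$rxns$type == "transfer")
  pool_rows <- match(cm$pool$pool_id, cm$mets$id)
  w <- cm$abundances[cm$rxns$member[tr]]
  for (z in seq_along(tr)) {
    r <- pool_rows[match(cm$rxns$base_id[tr[z]], cm$pool$base_id)]
    S[r, tr[z]] <- S[r, tr[z]] * w[z]
  }
  S
}

#' Flux balance analysis on a community
#'
#' Maximizes one member's biomass flux (or the summed biomass of all
#' members) over the community polytope, optionally enforcing the other
#' members' growth floors.
#'
#' @param cm a [community_model].
#' @param member tag of the member whose biomass is maximized; `NULL`
#'   maximizes the sum over members.
#' @param enforce_floors apply every member's `min_growth` as a lower
#'   bound on its biomass flux.
#' @param weighted use abundance-weighted pool balance rows.
#' @param solver,time_limit passed to [solve_lp()].
#' @return list with `status`, `objective` (the maximized growth), and
#'   named `fluxes`.
#' @export
community_fba <- function(cm, member = NULL, enforce_floors = FALSE,
                          weighted = FALSE, solver = "auto",
                          time_limit = Inf) {
  S <- .community_S(cm, weighted)
  lb <- cm$rxns$lb; ub <- cm$rxns$ub
  if (enforce_floors) {
    for (cp in cm$members) {
      k <- match(cp$biomass_reaction_id, cm$rxns$id)
      lb[k] <- max(lb[k], cp$min_growth)
    }
  }
  obj <- numeric(nrow(cm$rxns))
  bio <- vapply(cm$members, function(cp) {
    match(cp$biomass_reaction_id, cm$rxns$id)
  }, integer(1))
  if (is.null(member)) obj[bio] <- 1 else {
    if (!member %in% names(cm$members)) stop("unknown member tag: ", member)
    obj[bio[[member]]] <- 1
  }
  prob <- lp_problem(obj, S, row_lb = rep(0, nrow(S)),
                     row_ub = rep(0, nrow(S)), lb = lb, ub = ub,
                     sense = "max", names = cm$rxns$id)
  sol <- solve_lp(prob, solver = solver, time_limit = time_limit)
  list(status = sol$status, objective = sol$objective, fluxes = sol$x)
}

#' Flux balance analysis on a standalone model
#'
#' Maximizes the biomass flux of a single model using its own exchange
#' reactions as the system boundary. When a medium is given, each
#' exchange reaction's bounds are replaced by the medium entry for its
#' metabolite's base id (default policy for unlisted ones).
#'
#' @param model a [metabolic_model].
#' @param med optional [medium].
#' @param objective reaction id to maximize (default: the biomass
#'   reaction).
#' @param solver passed to [solve_lp()].
#' @return list with `status`, `objective`, named `fluxes`.
#' @export
fba <- function(model, med = NULL, objective = NULL, solver = "auto") {
  if (is.null(objective)) objective <- model$biomass_reaction_id
  if (is.na(objective)) stop("model has no biomass reaction to maximize")
  lb <- model$rxns$lb; ub <- model$rxns$ub
  if (!is.null(med)) {
    cap <- max(abs(c(lb, ub)), 1000)
    pol <- .policy_bounds(med$default_policy, cap)
    for (k in which(model$rxns$is_exchange)) {
      st <- reaction_stoichiometry(model, model$rxns$id[k])
      b <- med$bounds[[.base_id(names(st)[1L])]]
      if (is.null(b)) b <- pol
      lb[k] <- b[1]; ub[k] <- b[2]
    }
  }
  obj <- as.numeric(model$rxns$id == objective)
  prob <- lp_problem(obj, model$S, row_lb = rep(0, nrow(model$S)),
                     row_ub = rep(0, nrow(model$S)), lb = lb, ub = ub,
                     sense = "max", names = model$rxns$id)
  sol <- solve_lp(prob, solver = solver)
  list(status = sol$status, objective = sol$objective, fluxes = sol$x)
}
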