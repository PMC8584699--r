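#' @title Synthetic community fixtures and the exhaustive oracle
#' @description Generates small linear-pathway communities with planted
#'   gaps (reactions moved from a member's backbone into the candidate
#'   database), optional parallel repair routes (to create symmetric
#'   alternative optima), optional planted cross-feeding (one member can
#'   obtain an intermediate from another instead of repairing its own
#'   backbone), and disconnected decoy reactions. Every network is mass
#'   balanced by construction (all metabolites carry the unit
#'   pseudo-formula `"X"`). The minimum repair count and all optimal
#'   repair sets are established at generation time by exhaustive search
#'   over candidate subsets, giving ground truth that is independent of
#'   the MILP path.
#' @name synthetic-fixtures
NULL

.fx_met <- function(id, compartment) {
  data.frame(id = id, name = id, formula = "X", charge = 0,
             compartment = compartment, stringsAsFactors = FALSE)
}

.fx_model <- function(id, mets, rxn_defs, biomass_id) {
  rxns <- data.frame(id = vapply(rxn_defs, `[[`, "", "id"),
                     name = vapply(rxn_defs, `[[`, "", "id"),
                     lb = vapply(rxn_defs, `[[`, 0, "lb"),
                     ub = vapply(rxn_defs, `[[`, 0, "ub"),
                     is_exchange = vapply(rxn_defs, `[[`, TRUE, "exch"),
                     is_biomass = vapply(rxn_defs, `[[`, TRUE, "bio"),
                     stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(nrow(mets), nrow(rxns)))
  rownames(S) <- mets$id
  for (k in seq_along(rxn_defs)) {
    st <- rxn_defs[[k]]$st
    S[cbind(match(names(st), mets$id), k)] <- st
  }
  metabolic_model(id, mets, rxns, S, biomass_id)
}

.rx <- function(id, st, lb = 0, ub = 1000, exch = FALSE, bio = FALSE) {
  list(id = id, st = st, lb = lb, ub = ub, exch = exch, bio = bio)
}

#' Generate a linear-pathway community fixture
#'
#' Each member is a chain: nutrient exchange -> transport -> `L` chain
#' steps -> biomass drain, with a member-specific nutrient in the
#' medium. `gaps_per_member` chain steps are deleted from each member
#' and placed in the shared candidate database. `alt_routes` plants,
#' per gap, that many parallel database reactions with identical
#' stoichiometry (symmetric repairs). With `cross_feed = TRUE`, member 1
#' carries a secretion route for an intermediate metabolite `xf_e` and
#' member 2 a matching uptake route, so repairing member 2 may be
#' unnecessary when the planted exchange bypasses its gap. `n_decoys`
#' disconnected two-metabolite reactions pad the database.
#'
#' All randomness (gap and route positions) is drawn from a generator
#' seeded with `seed`; the calling session's RNG state is restored on
#' exit, and a given seed reproduces the fixture byte for byte.
#'
#' @param n_members number of members (1-3 are the tested regimes).
#' @param chain_length backbone steps per member (>= 2).
#' @param gaps_per_member chain steps deleted per member.
#' @param n_decoys disconnected database decoys.
#' @param alt_routes parallel repair routes planted per gap.
#' @param cross_feed plant the member-1 -> member-2 exchange bypass.
#' @param min_growth growth floor used for feasibility (recycled).
#' @param uptake_limit nutrient uptake bound in the medium (flux units).
#' @param flux_cap global flux cap.
#' @param seed integer RNG seed (required).
#' @param compute_oracle establish `expected_min_repair` and all optimal
#'   supports by exhaustive search at generation time.
#' @param solver passed to the oracle's LP feasibility checks.
#' @return object of class `community_fixture`: `models` (named list),
#'   `database`, `medium`, `floors`, `expected_min_repair`,
#'   `oracle_supports` (list of sorted `"tag:reaction"` vectors),
#'   `spec` (the planted structure), `seed`.
#' @export
make_linear_fixture <- function(n_members = 2, chain_length = 4,
                                gaps_per_member = 1, n_decoys = 2,
                                alt_routes = 0, cross_feed = FALSE,
                                min_growth = 0.1, uptake_limit = 10,
                                flux_cap = 1000, seed,
                                compute_oracle = TRUE, solver = "auto") {
  stopifnot(n_members >= 1, chain_length >= 2,
            gaps_per_member >= 0, gaps_per_member <= chain_length)
  if (missing(seed)) stop("make_linear_fixture: seed is required")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  L <- chain_length
  models <- list()
  db_rxns <- list()
  db_mets <- list()
  planted_gaps <- list()
  xfeed <- NULL

  cf_exit <- if (cross_feed && n_members >= 2) sample(seq_len(L - 1), 1) else NA
  cf_entry <- if (cross_feed && n_members >= 2) sample(seq_len(L - 1), 1) else NA

  for (n in seq_len(n_members)) {
    tag <- paste0("org", n)
    smet <- sprintf("s%d_%d_c", n, 0:L)
    nut <- sprintf("nut%d_e", n)
    mets <- rbind(.fx_met(smet, "c"), .fx_met(nut, "e"))
    rx <- list(
      .rx(sprintf("EX_nut%d_e", n), stats::setNames(-1, nut),
          lb = -uptake_limit, ub = flux_cap, exch = TRUE),
      .rx(sprintf("T%d", n), stats::setNames(c(-1, 1), c(nut, smet[1]))))
    for (k in seq_len(L)) {
      rx[[length(rx) + 1L]] <-
        .rx(sprintf("C%d_%d", n, k),
            stats::setNames(c(-1, 1), c(smet[k], smet[k + 1])))
    }
    bio_id <- sprintf("BIO%d", n)
    rx[[length(rx) + 1L]] <- .rx(bio_id, stats::setNames(-1, smet[L + 1]),
                                 bio = TRUE)
    if (cross_feed && n_members >= 2 && n == 1L) {
      mets <- rbind(mets, .fx_met("xf_e", "e"))
      rx[[length(rx) + 1L]] <-
        .rx("SEC1", stats::setNames(c(-1, 1),
                                    c(sprintf("s1_%d_c", cf_exit), "xf_e")))
    }
    if (cross_feed && n_members >= 2 && n == 2L) {
      mets <- rbind(mets, .fx_met("xf_e", "e"))
      rx[[length(rx) + 1L]] <-
        .rx("UPT2", stats::setNames(c(-1, 1),
                                    c("xf_e", sprintf("s2_%d_c", cf_entry))))
    }
    model <- .fx_model(tag, mets, rx, bio_id)

    gaps <- sort(sample(seq_len(L), gaps_per_member))
    gap_ids <- sprintf("C%d_%d", n, gaps)
    planted_gaps[[tag]] <- gap_ids
    model <- knockout(model, gap_ids)
    models[[tag]] <- model

    for (g in seq_along(gaps)) {
      k <- gaps[g]
      st <- stats::setNames(c(-1, 1),
                            sprintf("s%d_%d_c", n, c(k - 1, k)))
      db_rxns[[length(db_rxns) + 1L]] <- .rx(gap_ids[g], st,
                                             lb = -flux_cap, ub = flux_cap)
      if (alt_routes > 0) {
        for (r in seq_len(alt_routes)) {
          db_rxns[[length(db_rxns) + 1L]] <-
            .rx(sprintf("ALT%d_%d_%d", n, k, r), st,
                lb = -flux_cap, ub = flux_cap)
        }
      }
    }
    db_mets[[length(db_mets) + 1L]] <- .fx_met(smet, "c")
  }
  if (cross_feed && n_members >= 2) {
    xfeed <- list(metabolite = "xf", from = "org1", to = "org2",
                  exit_step = cf_exit, entry_step = cf_entry)
  }
  for (d in seq_len(n_decoys)) {
    da <- sprintf("dx%d_a_c", d); db_ <- sprintf("dx%d_b_c", d)
    db_mets[[length(db_mets) + 1L]] <- .fx_met(c(da, db_), "c")
    db_rxns[[length(db_rxns) + 1L]] <-
      .rx(sprintf("DECOY%d", d), stats::setNames(c(-1, 1), c(da, db_)),
          lb = -flux_cap, ub = flux_cap)
  }

  cat_mets <- unique(do.call(rbind, db_mets))
  if (length(db_rxns)) {
    rxdf <- data.frame(id = vapply(db_rxns, `[[`, "", "id"),
                       name = vapply(db_rxns, `[[`, "", "id"),
                       lb = vapply(db_rxns, `[[`, 0, "lb"),
                       ub = vapply(db_rxns, `[[`, 0, "ub"),
                       stringsAsFactors = FALSE)
    Sdb <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow(cat_mets), nrow(rxdf)))
    rownames(Sdb) <- cat_mets$id
    for (k in seq_along(db_rxns)) {
      st <- db_rxns[[k]]$st
      Sdb[cbind(match(names(st), cat_mets$id), k)] <- st
    }
    database <- reaction_database(rxdf, Sdb, cat_mets,
                                  provenance = sprintf("fixture seed %d", seed))
  } else {
    database <- empty_database(cat_mets)
  }

  med_bounds <- stats::setNames(
    lapply(seq_len(n_members), function(n) c(-uptake_limit, flux_cap)),
    sprintf("nut%d", seq_len(n_members)))
  med <- medium(med_bounds, default_policy = "open_secretion_only")
  floors <- stats::setNames(rep_len(min_growth, n_members),
                            names(models))

  fx <- structure(list(models = models, database = database, medium = med,
                       floors = floors,
                       expected_min_repair = NA_integer_,
                       oracle_supports = NULL,
                       spec = list(n_members = n_members,
                                   chain_length = chain_length,
                                   planted_gaps = planted_gaps,
                                   planted_exchange = xfeed,
                                   n_decoys = n_decoys,
                                   alt_routes = alt_routes),
                       seed = seed, flux_cap = flux_cap),
                  class = "community_fixture")
  if (compute_oracle) {
    orc <- oracle_gapfill(models, database, med, floors,
                          flux_cap = flux_cap, solver = solver)
    if (!orc$feasible) {
      stop("infeasible fixture: planted gaps not repairable from database")
    }
    fx$expected_min_repair <- orc$min_size
    fx$oracle_supports <- orc$supports
  }
  fx
}

#' @exportS3Method base::print
print.community_fixture <- function(x, ...) {
  cat("<community_fixture> seed ", x$seed, ": ",
      length(x$models), " member(s), ",
      nrow(x$database$rxns), " database reaction(s), min repair ",
      x$expected_min_repair, "\n", sep = "")
  invisible(x)
}

#' Canonical key of a solution's added-reaction set
#'
#' @param added per-member added list (e.g. `solution$added`).
#' @return sorted character vector of `"tag:reaction"` strings.
#' @export
support_key <- function(added) {
  sort(unlist(lapply(names(added), function(tg) {
    if (length(added[[tg]])) paste0(tg, ":", added[[tg]]) else character()
  })))
}

#' Exhaustive gap-filling oracle
#'
#' Breadth-first search over candidate subsets in increasing
#' cardinality: a subset is feasible when the community LP with exactly
#' those candidates enabled (and all growth floors enforced) is
#' feasible. Returns every minimum-cardinality subset. Intended for
#' small databases; the search is capped at `max_candidates` binaries.
#'
#' @param models named list of member models.
#' @param database the candidate [reaction_database].
#' @param med the [medium].
#' @param floors named growth floors per member.
#' @param abundances,weighted abundance-weighted variant passthrough.
#' @param flux_cap global flux cap.
#' @param max_candidates refuse larger searches.
#' @param solver passed to the LP feasibility checks.
#' @return list: `feasible` (with the full database), `min_size`,
#'   `supports` (list of sorted `"tag:reaction"` keys), `n_tested`.
#' @export
oracle_gapfill <- function(models, database, med, floors,
                           abundances = NULL, weighted = FALSE,
                           flux_cap = 1000, max_candidates = 20,
                           solver = "auto") {
  cm <- build_community(models, database, med, min_growth = floors,
                        abundances = abundances, flux_cap = flux_cap)
  problem <- formulate_gapfill(cm, growth_floors = floors,
                               weighted = weighted)
  nc <- nrow(problem$cand)
  if (nc > max_candidates) {
    stop("oracle_gapfill: ", nc, " candidates exceed the search cap (",
         max_candidates, ")")
  }
  n_tested <- 0L
  if (nc > 0 &&
      !support_feasible(problem, seq_len(nc), solver = solver)) {
    return(list(feasible = FALSE, min_size = NA_integer_,
                supports = list(), n_tested = 1L))
  }
  for (size in 0:nc) {
    subsets <- if (size == 0L) list(integer()) else {
      utils::combn(nc, size, simplify = FALSE)
    }
    hits <- list()
    for (sub in subsets) {
      n_tested <- n_tested + 1L
      if (support_feasible(problem, sub, solver = solver)) {
        hits[[length(hits) + 1L]] <- sub
      }
    }
    if (length(hits)) {
      supports <- lapply(hits, function(sub) {
        support_key(.added_list(problem,
                                seq_len(nc) %in% sub))
      })
      return(list(feasible = TRUE, min_size = size,
                  supports = supports, n_tested = n_tested))
    }
  }
  list(feasible = FALSE, min_size = NA_integer_, supports = list(),
       n_tested = n_tested)
}
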