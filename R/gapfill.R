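#' @title Community gap-filling MILP
#' @description The core optimization: minimize the number of database
#'   reactions added across all members, subject to per-compartment
#'   steady state, model-reaction bounds, binary-gated candidate bounds,
#'   per-member growth floors, and the common-pool balance rows
#'   (optionally abundance-weighted). Alternative optima are enumerated
#'   with solver-agnostic integer cuts on the set of added reactions.
#' @name gapfill-core
NULL

#' Formulate the community gap-filling problem
#'
#' Builds the MILP: one continuous flux variable per community reaction,
#' one binary per database candidate per compartment. A candidate's flux
#' is gated by its binary (`y*lb <= v <= y*ub`), each member's biomass
#' flux must reach its floor, and every metabolite row (member and pool)
#' is at steady state. Binaries are ordered lexicographically by member
#' tag then reaction id, so reported solutions are stable across runs.
#'
#' @param cm a [community_model], pruned (see [reduce_community()]) or
#'   not.
#' @param growth_floors named numeric vector (by member tag) of required
#'   minimum growth rates; defaults to the members' `min_growth`. All
#'   floors must be positive -- a zero floor would never force repairs.
#' @param weighted use the abundance-weighted pool balance (requires
#'   `cm$abundances`).
#' @return object of class `gapfill_problem`.
#' @export
formulate_gapfill <- function(cm, growth_floors = NULL, weighted = FALSE) {
  if (is.null(growth_floors)) {
    growth_floors <- vapply(cm$members, function(cp) cp$min_growth,
                            numeric(1))
  }
  growth_floors <- growth_floors[names(cm$members)]
  if (anyNA(growth_floors) || any(growth_floors <= 0)) {
    stop("growth floors must be positive for every member")
  }
  if (weighted && is.null(cm$abundances)) {
    stop("weighted formulation requires member abundances")
  }
  S <- .community_S(cm, weighted)
  nv <- nrow(cm$rxns)
  ci <- which(cm$rxns$type == "database")
  ci <- ci[order(cm$rxns$member[ci], cm$rxns$orig_id[ci])]
  nc <- length(ci)
  cand <- data.frame(member = cm$rxns$member[ci],
                     reaction_id = cm$rxns$id[ci],
                     orig_id = cm$rxns$orig_id[ci],
                     flux_col = ci, y_col = nv + seq_len(nc),
                     stringsAsFactors = FALSE)

  lb <- cm$rxns$lb; ub <- cm$rxns$ub
  # gating requires the flux bound interval to contain 0 when y = 0
  lb[ci] <- pmin(lb[ci], 0); ub[ci] <- pmax(ub[ci], 0)
  for (tg in names(cm$members)) {
    k <- match(cm$members[[tg]]$biomass_reaction_id, cm$rxns$id)
    lb[k] <- max(lb[k], growth_floors[[tg]])
  }

  m <- nrow(S)
  A_ss <- cbind(S, Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(m, nc)))
  if (nc > 0) {
    gate_up <- Matrix::sparseMatrix(
      i = c(seq_len(nc), seq_len(nc)),
      j = c(cand$flux_col, cand$y_col),
      x = c(rep(1, nc), -cm$rxns$ub[ci]),
      dims = c(nc, nv + nc))
    gate_lo <- Matrix::sparseMatrix(
      i = c(seq_len(nc), seq_len(nc)),
      j = c(cand$flux_col, cand$y_col),
      x = c(rep(1, nc), -cm$rxns$lb[ci]),
      dims = c(nc, nv + nc))
    A <- rbind(A_ss, gate_up, gate_lo)
    row_lb <- c(rep(0, m), rep(-Inf, nc), rep(0, nc))
    row_ub <- c(rep(0, m), rep(0, nc), rep(Inf, nc))
  } else {
    A <- A_ss
    row_lb <- rep(0, m); row_ub <- rep(0, m)
  }
  obj <- c(numeric(nv), rep(1, nc))
  vlb <- c(lb, rep(0, nc)); vub <- c(ub, rep(1, nc))
  binary <- c(rep(FALSE, nv), rep(TRUE, nc))
  nms <- c(cm$rxns$id, paste0("y.", cand$reaction_id, recycle0 = TRUE))

  structure(list(community = cm, cand = cand, n_flux = nv,
                 growth_floors = growth_floors, weighted = weighted,
                 A = A, row_lb = row_lb, row_ub = row_ub,
                 lb = vlb, ub = vub, obj = obj, binary = binary,
                 names = nms),
            class = "gapfill_problem")
}

#' @exportS3Method base::print
print.gapfill_problem <- function(x, ...) {
  cat("<gapfill_problem> ", length(x$community$members), " member(s), ",
      nrow(x$cand), " binary candidate(s), ", x$n_flux,
      " flux variables\n", sep = "")
  invisible(x)
}

# Assemble an lp_problem from a gapfill_problem plus integer-cut rows.
# Each cut is a list(cols = y columns, lb = , ub = ).
.gapfill_lp <- function(p, cuts = list(), fix_y = NULL) {
  A <- p$A; row_lb <- p$row_lb; row_ub <- p$row_ub
  if (length(cuts)) {
    cut_rows <- Matrix::sparseMatrix(
      i = rep(seq_along(cuts), lengths(lapply(cuts, `[[`, "cols"))),
      j = unlist(lapply(cuts, `[[`, "cols")),
      x = 1, dims = c(length(cuts), ncol(A)))
    A <- rbind(A, cut_rows)
    row_lb <- c(row_lb, vapply(cuts, `[[`, 0, "lb"))
    row_ub <- c(row_ub, vapply(cuts, `[[`, 0, "ub"))
  }
  lb <- p$lb; ub <- p$ub; binary <- p$binary
  if (!is.null(fix_y)) {
    lb[p$cand$y_col] <- fix_y; ub[p$cand$y_col] <- fix_y
    binary[] <- FALSE
  }
  lp_problem(p$obj, A, row_lb, row_ub, lb, ub, sense = "min",
             binary = binary, names = p$names)
}

# LP re-solve with the binaries fixed: maximizes the summed member
# biomass so reported fluxes are a meaningful FBA point of the repaired
# community.
.refit_fluxes <- function(p, yfix, solver, time_limit) {
  prob <- .gapfill_lp(p, fix_y = yfix)
  bio <- vapply(p$community$members, function(cp) {
    match(cp$biomass_reaction_id, p$community$rxns$id)
  }, integer(1))
  prob$obj[] <- 0; prob$obj[bio] <- 1; prob$sense <- "max"
  solve_lp(prob, solver = solver, time_limit = time_limit)
}

#' Is a given support (set of added reactions) feasible?
#'
#' Fixes the binaries to the indicator of `support` and tests LP
#' feasibility of the community with growth floors enforced. This is the
#' primitive behind the exhaustive oracle and the irreducibility check.
#'
#' @param problem a [formulate_gapfill()] problem.
#' @param support integer vector of rows of `problem$cand` forming the
#'   support (empty = add nothing).
#' @param solver passed to [solve_lp()].
#' @return `TRUE` when the fixed-support LP is feasible.
#' @export
support_feasible <- function(problem, support, solver = "auto") {
  yfix <- numeric(nrow(problem$cand))
  yfix[support] <- 1
  prob <- .gapfill_lp(problem, fix_y = yfix)
  prob$obj[] <- 0
  sol <- solve_lp(prob, solver = solver)
  sol$status == "optimal"
}

# turn a 0/1 binary vector into the per-member added-reaction list
.added_list <- function(p, ysel) {
  sup <- p$cand[ysel, , drop = FALSE]
  out <- lapply(names(p$community$members), function(tg) {
    sort(sup$orig_id[sup$member == tg])
  })
  names(out) <- names(p$community$members)
  out
}

#' Solve the community gap-filling MILP
#'
#' Minimizes the number of added database reactions. Binaries of the
#' incumbent are rounded at 0.5 and re-verified by fixing them and
#' re-solving the LP (whose fluxes, an FBA point of the repaired
#' community, are the ones reported). On infeasibility the error names
#' the members whose floor still cannot be met when all other members'
#' floors are relaxed.
#'
#' @param problem a [gapfill_problem].
#' @param solver,time_limit,mip_gap passed to [solve_lp()].
#' @param cuts internal: integer-cut rows from the enumeration loop.
#' @return object of class `gapfill_solution`: `status`,
#'   `objective_value`, `added` (per-member reaction ids), `fluxes`,
#'   `growth` (per-member biomass flux), `support` (candidate rows),
#'   `solver_meta`.
#' @export
solve_gapfill <- function(problem, solver = "auto", time_limit = Inf,
                          mip_gap = 0, cuts = list()) {
  t0 <- proc.time()[["elapsed"]]
  prob <- .gapfill_lp(problem, cuts = cuts)
  sol <- solve_lp(prob, solver = solver, time_limit = time_limit,
                  mip_gap = mip_gap)
  if (sol$status %in% c("infeasible", "error", "unbounded")) {
    hint <- NULL
    if (sol$status == "infeasible" && length(cuts) == 0L) {
      hint <- .infeasibility_hint(problem, solver)
    }
    out <- structure(list(status = "infeasible", objective_value = NA_integer_,
                          added = NULL, fluxes = NULL, growth = NULL,
                          support = integer(),
                          infeasible_members = hint,
                          solver_meta = list(backend = solver,
                                             runtime = proc.time()[["elapsed"]] - t0)),
                     class = "gapfill_solution")
    return(out)
  }
  ysel <- sol$x[problem$cand$y_col] > 0.5
  yfix <- as.numeric(ysel)
  ref <- .refit_fluxes(problem, yfix, solver, time_limit)
  fluxes <- if (ref$status == "optimal") {
    ref$x[seq_len(problem$n_flux)]
  } else {
    sol$x[seq_len(problem$n_flux)]
  }
  names(fluxes) <- problem$community$rxns$id
  growth <- vapply(problem$community$members, function(cp) {
    fluxes[[cp$biomass_reaction_id]]
  }, numeric(1))
  structure(list(
    status = if (sol$status == "time_limit") "time_limit" else "optimal",
    objective_value = as.integer(round(sum(yfix))),
    added = .added_list(problem, ysel),
    fluxes = fluxes,
    growth = growth,
    support = which(ysel),
    solver_meta = list(backend = solver, gap = mip_gap,
                       runtime = proc.time()[["elapsed"]] - t0)),
    class = "gapfill_solution")
}

# which members' floors fail even alone (all other floors relaxed)?
.infeasibility_hint <- function(problem, solver) {
  cm <- problem$community
  failing <- character()
  for (tg in names(cm$members)) {
    lb <- problem$lb
    for (other in setdiff(names(cm$members), tg)) {
      k <- match(cm$members[[other]]$biomass_reaction_id, cm$rxns$id)
      lb[k] <- min(0, lb[k])
    }
    prob <- lp_problem(problem$obj, problem$A, problem$row_lb,
                       problem$row_ub, lb, problem$ub, sense = "min",
                       binary = problem$binary, names = problem$names)
    sol <- solve_lp(prob, solver = solver)
    if (sol$status != "optimal") failing <- c(failing, tg)
  }
  failing
}

#' @exportS3Method base::print
print.gapfill_solution <- function(x, ...) {
  cat("<gapfill_solution> status: ", x$status, "\n", sep = "")
  if (x$status %in% c("optimal", "time_limit")) {
    cat("  reactions added: ", x$objective_value, "\n", sep = "")
    for (tg in names(x$added)) {
      if (length(x$added[[tg]])) {
        cat("    ", tg, ": ", paste(x$added[[tg]], collapse = ", "),
            "\n", sep = "")
      }
    }
    cat("  growth: ",
        paste(sprintf("%s=%.4g", names(x$growth), x$growth),
              collapse = ", "), "\n", sep = "")
  } else if (length(x$infeasible_members)) {
    cat("  floors unreachable even alone for: ",
        paste(x$infeasible_members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate alternative gap-filling solutions
#'
#' Repeatedly solves the MILP, each time excluding all previously found
#' supports with an integer cut (`sum(y in support) <= |support| - 1`;
#' excluding an empty support requires at least one binary on). With
#' `allow_suboptimal = TRUE` the list continues into strictly worse
#' objectives (the "k best" reading); with `FALSE` enumeration stops
#' when the objective first exceeds the optimum, and
#' `exhaustive_at_optimum` reports that every optimal support was found.
#'
#' @param problem a [gapfill_problem].
#' @param k maximum number of solutions.
#' @param allow_suboptimal keep enumerating past the optimal objective.
#' @param solver,time_limit,mip_gap passed to each solve; `time_limit`
#'   is the per-solve budget.
#' @return object of class `enumeration_result`: `solutions` (best
#'   first), `exhaustive_at_optimum`, `cuts_applied`.
#' @export
enumerate_alternatives <- function(problem, k = 10,
                                   allow_suboptimal = TRUE,
                                   solver = "auto", time_limit = Inf,
                                   mip_gap = 0) {
  stopifnot(k >= 1)
  solutions <- list()
  cuts <- list()
  exhaustive <- FALSE
  best <- NA_integer_
  all_y <- problem$cand$y_col
  repeat {
    sol <- solve_gapfill(problem, solver = solver, time_limit = time_limit,
                         mip_gap = mip_gap, cuts = cuts)
    if (sol$status == "infeasible") { exhaustive <- TRUE; break }
    if (is.na(best)) best <- sol$objective_value
    if (!allow_suboptimal && sol$objective_value > best) {
      exhaustive <- TRUE
      break
    }
    solutions[[length(solutions) + 1L]] <- sol
    if (length(solutions) >= k) break
    sup_cols <- problem$cand$y_col[sol$support]
    if (length(sup_cols) == 0L && length(all_y) == 0L) {
      # no candidates at all: the empty support is the only support
      exhaustive <- TRUE
      break
    }
    cuts[[length(cuts) + 1L]] <- if (length(sup_cols)) {
      list(cols = sup_cols, lb = -Inf, ub = length(sup_cols) - 1)
    } else {
      list(cols = all_y, lb = 1, ub = Inf)
    }
  }
  structure(list(solutions = solutions,
                 exhaustive_at_optimum = exhaustive,
                 cuts_applied = length(cuts)),
            class = "enumeration_result")
}

#' @exportS3Method base::print
print.enumeration_result <- function(x, ...) {
  objs <- vapply(x$solutions, `[[`, 0L, "objective_value")
  cat("<enumeration_result> ", length(x$solutions), " solution(s), ",
      "objectives: ", paste(objs, collapse = ", "),
      if (x$exhaustive_at_optimum) " (exhaustive at optimum)", "\n",
      sep = "")
  invisible(x)
}

#' Materialize added reactions into a member model
#'
#' Returns the model with the solution's added reactions for that
#' member inserted with their original reversible bounds
#' `(-flux_cap, +flux_cap)` -- the FVA-tightened bounds are artifacts of
#' the community reduction and are not exported to the standalone model.
#'
#' @param model the member's original [metabolic_model].
#' @param solution a [gapfill_solution].
#' @param db the [reaction_database] the solution drew from.
#' @param member member tag in the solution (defaults to the single
#'   member when the solution has one).
#' @param flux_cap reversible bound magnitude for added reactions.
#' @return the gap-filled [metabolic_model].
#' @export
apply_solution <- function(model, solution, db, member = NULL,
                           flux_cap = 1000) {
  if (is.null(member)) {
    if (length(solution$added) != 1L) {
      stop("solution has several members; say which one")
    }
    member <- names(solution$added)
  }
  add <- solution$added[[member]]
  if (is.null(add) || length(add) == 0L) return(model)
  miss <- setdiff(add, db$rxns$id)
  if (length(miss)) {
    stop("solution adds reaction(s) absent from database: ",
         paste(miss, collapse = ", "))
  }
  mets <- model$mets
  for (rid in add) {
    st <- db$S[, rid, drop = TRUE]; st <- st[st != 0]
    new <- setdiff(names(st), mets$id)
    if (length(new)) {
      mets <- rbind(mets,
                    db$mets[match(new, db$mets$id),
                            c("id", "name", "formula", "charge",
                              "compartment")])
    }
  }
  rxns <- rbind(model$rxns,
                data.frame(id = add,
                           name = db$rxns$name[match(add, db$rxns$id)],
                           lb = -flux_cap, ub = flux_cap,
                           is_exchange = FALSE, is_biomass = FALSE,
                           stringsAsFactors = FALSE))
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(nrow(mets), nrow(rxns)))
  old <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
  if (nrow(old)) {
    S[cbind(match(rownames(model$S)[old$i], mets$id), old$j)] <- old$x
  }
  for (z in seq_along(add)) {
    st <- db$S[, add[z], drop = TRUE]; st <- st[st != 0]
    S[cbind(match(names(st), mets$id), ncol(model$S) + z)] <- st
  }
  metabolic_model(model$id, mets, rxns, S, model$biomass_reaction_id)
}

#' Apply a solution to all members and verify growth in the community
#'
#' Gap-fills each member model, rebuilds the community (with an empty
#' candidate database), and computes each member's maximum FBA growth
#' with every member's floor enforced. An error is raised when any
#' verified growth falls below its floor (that would indicate a bound
#' restoration or tolerance bug upstream).
#'
#' @param models named list of original member models (names = tags used
#'   when the community was built).
#' @param solution a [gapfill_solution].
#' @param db the [reaction_database].
#' @param med the [medium].
#' @param growth_floors named numeric floors per member.
#' @param abundances,weighted abundance-weighted variant passthrough.
#' @param flux_cap global flux cap.
#' @param solver passed to the LP solves.
#' @param tol feasibility slack on the floor comparison.
#' @return list with `models` (gap-filled) and `growth` (named vector).
#' @export
apply_and_verify <- function(models, solution, db, med, growth_floors,
                             abundances = NULL, weighted = FALSE,
                             flux_cap = 1000, solver = "auto",
                             tol = 1e-6) {
  tags <- names(models)
  if (is.null(tags)) stop("models must be a named list (tags)")
  filled <- lapply(tags, function(tg) {
    apply_solution(models[[tg]], solution, db, member = tg,
                   flux_cap = flux_cap)
  })
  names(filled) <- tags
  cm <- build_community(filled, empty_database(), med,
                        min_growth = growth_floors[tags],
                        abundances = abundances, flux_cap = flux_cap)
  growth <- vapply(tags, function(tg) {
    r <- community_fba(cm, member = tg, enforce_floors = TRUE,
                       weighted = weighted, solver = solver)
    if (r$status != "optimal") {
      stop("verification FBA failed for member ", tg,
           " (status ", r$status, ")")
    }
    r$objective
  }, numeric(1))
  low <- growth < growth_floors[tags] - tol
  if (any(low)) {
    stop("verified growth below floor for: ",
         paste(tags[low], collapse = ", "))
  }
  list(models = filled, growth = growth)
}
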