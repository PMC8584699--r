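#' @title Flux variability reduction of the candidate set
#' @description Before the MILP is formulated, each organism compartment
#'   is analysed on its own with every pool transfer opened wide and the
#'   growth requirement relaxed to zero. Under that relaxation the
#'   compartment's feasible set over-approximates any flux assignment the
#'   compartment can take inside any community (other members may supply
#'   or drain any pool metabolite), so the per-candidate flux intervals
#'   it yields are valid bounds in the full problem: candidates whose
#'   interval is `{0}` can never carry flux and are deleted, and the
#'   survivors' bounds are tightened to the interval (rounded outward by
#'   a tolerance), which shrinks the MILP without touching its optimum.
#' @name fva-reduction
NULL

# LP skeleton for one compartment: compartment stoichiometry plus one
# open boundary column per extracellular metabolite (standing in for
# the pool transfer). Returns the constraint matrix and bounds.
.compartment_lp <- function(comp, med = NULL, relax_growth = TRUE) {
  cap <- comp$flux_cap
  ext <- comp$mets[comp$mets$is_extracellular, , drop = FALSE]
  nr <- nrow(comp$rxns)
  S <- comp$S
  if (nrow(ext)) {
    B <- Matrix::sparseMatrix(i = match(ext$id, comp$mets$id),
                              j = seq_len(nrow(ext)), x = -1,
                              dims = c(nrow(comp$mets), nrow(ext)))
    S <- cbind(S, B)
  }
  lb <- comp$rxns$lb; ub <- comp$rxns$ub
  bio <- match(comp$biomass_reaction_id, comp$rxns$id)
  lb[bio] <- if (relax_growth) min(0, lb[bio]) else max(lb[bio], comp$min_growth)
  if (nrow(ext)) {
    if (is.null(med)) {
      xlb <- rep(-cap, nrow(ext)); xub <- rep(cap, nrow(ext))
    } else {
      pol <- .policy_bounds(med$default_policy, cap)
      bl <- lapply(.base_id(ext$orig_id), function(b) {
        bb <- med$bounds[[b]]; if (is.null(bb)) pol else bb
      })
      xlb <- vapply(bl, `[`, 0, 1L); xub <- vapply(bl, `[`, 0, 2L)
    }
    lb <- c(lb, xlb); ub <- c(ub, xub)
  }
  list(S = S, lb = lb, ub = ub, n_rxn = nr,
       names = c(comp$rxns$id, if (nrow(ext)) paste0("XB_", ext$id)))
}

#' Flux variability analysis over a compartment's database candidates
#'
#' Computes the LP-exact minimum and maximum flux of every database
#' candidate reaction in the compartment, under the compartment's model
#' bounds, with every boundary (pool transfer) opened to
#' `(-flux_cap, +flux_cap)` -- or constrained by `med` when one is given
#' -- and the biomass lower bound relaxed to 0 when
#' `relax_growth = TRUE` (the default; a gapped compartment typically
#' cannot grow yet, and the relaxation is what makes subsequent pruning
#' sound in every community context).
#'
#' @param comp an [organism_compartment].
#' @param med optional [medium] restricting the boundary; `NULL` (the
#'   sound default) leaves all boundaries fully open.
#' @param relax_growth relax the member's growth floor to 0 during FVA.
#' @param reactions ids (namespaced or original) to analyse; default all
#'   database candidates.
#' @param solver passed to [solve_lp()].
#' @return data frame of class `fva_result` with columns `reaction_id`,
#'   `orig_id`, `min`, `max`; the relaxation is described in
#'   `attr(, "context")`.
#' @export
run_compartment_fva <- function(comp, med = NULL, relax_growth = TRUE,
                                reactions = NULL, solver = "auto") {
  lpk <- .compartment_lp(comp, med, relax_growth)
  if (any(lpk$lb > lpk$ub)) {
    bad <- lpk$names[which(lpk$lb > lpk$ub)[1L]]
    stop("infeasible relaxation: lb > ub for ", bad)
  }
  if (is.null(reactions)) {
    reactions <- comp$rxns$id[comp$rxns$source == "database"]
  } else {
    reactions <- ifelse(reactions %in% comp$rxns$id, reactions,
                        .ns(reactions, comp$tag))
  }
  m <- nrow(lpk$S)
  res <- data.frame(reaction_id = reactions,
                    orig_id = comp$rxns$orig_id[match(reactions, comp$rxns$id)],
                    min = rep(NA_real_, length(reactions)),
                    max = rep(NA_real_, length(reactions)),
                    stringsAsFactors = FALSE)
  obj0 <- numeric(ncol(lpk$S))
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], lpk$names)
    obj <- obj0; obj[j] <- 1
    for (sense in c("min", "max")) {
      prob <- lp_problem(obj, lpk$S, row_lb = rep(0, m), row_ub = rep(0, m),
                         lb = lpk$lb, ub = lpk$ub, sense = sense,
                         names = lpk$names)
      sol <- solve_lp(prob, solver = solver)
      if (sol$status != "optimal") {
        stop("FVA ", sense, " for ", reactions[k],
             " did not solve (status ", sol$status, ")")
      }
      res[[sense]][k] <- sol$objective
    }
  }
  if (any(res$min > res$max + 1e-7, na.rm = TRUE)) {
    stop("FVA produced min > max; solver tolerance problem")
  }
  attr(res, "context") <- list(
    relax_growth = relax_growth,
    boundary = if (is.null(med)) "open" else "medium",
    flux_cap = comp$flux_cap)
  class(res) <- c("fva_result", class(res))
  res
}

#' Prune and tighten a compartment from FVA results
#'
#' Database candidates whose FVA interval lies within `zero_tol` of zero
#' on both sides are deleted (they can never carry flux); the survivors'
#' bounds become the FVA interval rounded outward by `zero_tol` (which
#' prevents tolerance-induced infeasibility in the MILP). Model
#' reactions are untouched.
#'
#' @param comp an [organism_compartment].
#' @param fva result of [run_compartment_fva()] covering the
#'   compartment's database candidates.
#' @param zero_tol pruning/rounding tolerance (flux units).
#' @return the pruned compartment; pruned ids are recorded in
#'   `attr(, "pruned")`.
#' @export
prune_and_tighten <- function(comp, fva, zero_tol = 1e-6) {
  dbi <- which(comp$rxns$source == "database")
  if (length(dbi) == 0L) {
    attr(comp, "pruned") <- character()
    return(comp)
  }
  k <- match(comp$rxns$id[dbi], fva$reaction_id)
  if (anyNA(k)) {
    stop("FVA result does not cover candidate(s): ",
         paste(comp$rxns$id[dbi][is.na(k)], collapse = ", "))
  }
  vmin <- fva$min[k]; vmax <- fva$max[k]
  dead <- abs(vmin) <= zero_tol & abs(vmax) <= zero_tol
  comp$rxns$lb[dbi] <- vmin - zero_tol
  comp$rxns$ub[dbi] <- vmax + zero_tol
  drop <- dbi[dead]
  if (length(drop)) {
    keep <- setdiff(seq_len(nrow(comp$rxns)), drop)
    pruned_ids <- comp$rxns$id[drop]
    comp$rxns <- comp$rxns[keep, , drop = FALSE]
    comp$S <- comp$S[, keep, drop = FALSE]
    attr(comp, "pruned") <- pruned_ids
  } else {
    attr(comp, "pruned") <- character()
  }
  comp
}

#' FVA-reduce every compartment of a community
#'
#' Convenience wrapper: runs [run_compartment_fva()] and
#' [prune_and_tighten()] on each member and rebuilds the community
#' matrices.
#'
#' @param cm a [community_model].
#' @param zero_tol pruning tolerance.
#' @param relax_growth passed to [run_compartment_fva()].
#' @param solver passed to [solve_lp()].
#' @return the reduced community; a pruning report data frame
#'   (`member`, `reaction_id`, `min`, `max`, `pruned`) is attached as
#'   `attr(, "fva_report")`.
#' @export
reduce_community <- function(cm, zero_tol = 1e-6, relax_growth = TRUE,
                             solver = "auto") {
  report <- list()
  for (tg in names(cm$members)) {
    comp <- cm$members[[tg]]
    fva <- run_compartment_fva(comp, relax_growth = relax_growth,
                               solver = solver)
    comp2 <- prune_and_tighten(comp, fva, zero_tol)
    pruned <- attr(comp2, "pruned")
    if (nrow(fva)) {
      report[[tg]] <- data.frame(member = tg,
                                 reaction_id = fva$reaction_id,
                                 min = fva$min, max = fva$max,
                                 pruned = fva$reaction_id %in% pruned,
                                 stringsAsFactors = FALSE)
    }
    # drop pruned columns / tighten bounds in the global tables
    drop <- match(pruned, cm$rxns$id)
    if (length(drop)) {
      keep <- setdiff(seq_len(nrow(cm$rxns)), drop)
      cm$rxns <- cm$rxns[keep, , drop = FALSE]
      cm$S <- cm$S[, keep, drop = FALSE]
    }
    ki <- match(comp2$rxns$id, cm$rxns$id)
    cm$rxns$lb[ki] <- comp2$rxns$lb
    cm$rxns$ub[ki] <- comp2$rxns$ub
    cm$members[[tg]] <- comp2
  }
  attr(cm, "fva_report") <- do.call(rbind, unname(report))
  cm
}

#' Write an FVA/pruning report as TSV
#'
#' @param cm a community returned by [reduce_community()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fva_report <- function(cm, path) {
  rep <- attr(cm, "fva_report")
  if (is.null(rep)) stop("community carries no FVA report; run reduce_community()")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
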