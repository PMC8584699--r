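#' @title Post-solution reporting
#' @description Turns gap-filling solutions into exchange-flux tables,
#'   cross-feeding edge lists, added-reaction frequency summaries across
#'   alternative optima, and quality flags for fluxes that hug the
#'   global cap or run in opposed reaction pairs (a pairwise signature
#'   of thermodynamically infeasible cycles).
#' @name reporting
NULL

.as_solution_list <- function(solutions) {
  if (inherits(solutions, "enumeration_result")) return(solutions$solutions)
  if (inherits(solutions, "gapfill_solution")) return(list(solutions))
  solutions
}

#' Extract exchange fluxes and cross-feeding edges
#'
#' For every solution, tabulates each member's pool-transfer flux
#' (positive = secretion into the pool, negative = uptake) and the
#' environment exchange flux per pool metabolite, and derives
#' cross-feeding edges: metabolite `i` flows from member `a` to member
#' `b` in a solution when `a` secretes and `b` consumes `i` (both above
#' `tol`). The consensus table keeps edges present in at least half the
#' solutions.
#'
#' @param solutions an [enumeration_result], a single
#'   [gapfill_solution], or a list of solutions.
#' @param cm the [community_model] the solutions refer to.
#' @param tol minimum absolute transfer flux for an edge.
#' @return object of class `exchange_report`: `fluxes` (solution_rank,
#'   metabolite, member, flux), `environment` (solution_rank, metabolite,
#'   flux), `edges` (solution_rank, metabolite, from, to, magnitude),
#'   `consensus` (metabolite, from, to, frequency).
#' @export
extract_exchanges <- function(solutions, cm, tol = 1e-6) {
  sols <- .as_solution_list(solutions)
  if (length(sols) == 0L) stop("no solutions to report on")
  tr <- cm$rxns[cm$rxns$type == "transfer", , drop = FALSE]
  env <- cm$rxns[cm$rxns$type == "env_exchange", , drop = FALSE]
  fluxes <- list(); envf <- list(); edges <- list()
  for (r in seq_along(sols)) {
    fx <- sols[[r]]$fluxes
    fluxes[[r]] <- data.frame(solution_rank = r, metabolite = tr$base_id,
                              member = tr$member,
                              flux = as.numeric(fx[tr$id]),
                              stringsAsFactors = FALSE)
    envf[[r]] <- data.frame(solution_rank = r, metabolite = env$base_id,
                            flux = as.numeric(fx[env$id]),
                            stringsAsFactors = FALSE)
    f <- fluxes[[r]]
    for (met in unique(f$metabolite)) {
      fm <- f[f$metabolite == met, , drop = FALSE]
      prod <- fm[fm$flux > tol, , drop = FALSE]
      cons <- fm[fm$flux < -tol, , drop = FALSE]
      if (nrow(prod) && nrow(cons)) {
        eg <- expand.grid(from = prod$member, to = cons$member,
                          stringsAsFactors = FALSE)
        eg$magnitude <- pmin(prod$flux[match(eg$from, prod$member)],
                             -cons$flux[match(eg$to, cons$member)])
        edges[[length(edges) + 1L]] <-
          cbind(data.frame(solution_rank = r, metabolite = met,
                           stringsAsFactors = FALSE), eg)
      }
    }
  }
  fluxes <- do.call(rbind, fluxes)
  envf <- do.call(rbind, envf)
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(solution_rank = integer(), metabolite = character(),
               from = character(), to = character(),
               magnitude = numeric(), stringsAsFactors = FALSE)
  }
  key <- unique(edges[, c("metabolite", "from", "to")])
  consensus <- if (nrow(key)) {
    key$frequency <- vapply(seq_len(nrow(key)), function(z) {
      sum(edges$metabolite == key$metabolite[z] &
            edges$from == key$from[z] & edges$to == key$to[z])
    }, 0) / length(sols)
    key[key$frequency >= 0.5, , drop = FALSE]
  } else {
    cbind(key, frequency = numeric())
  }
  structure(list(fluxes = fluxes, environment = envf, edges = edges,
                 consensus = consensus, n_solutions = length(sols)),
            class = "exchange_report")
}

#' @exportS3Method base::print
print.exchange_report <- function(x, ...) {
  cat("<exchange_report> ", x$n_solutions, " solution(s), ",
      nrow(x$edges), " cross-feeding edge(s) (",
      nrow(x$consensus), " consensus)\n", sep = "")
  if (nrow(x$consensus)) print(x$consensus, row.names = FALSE)
  invisible(x)
}

#' Frequency of added reactions across alternative solutions
#'
#' @param solutions an [enumeration_result] or list of solutions.
#' @param cm the [community_model].
#' @return data frame (`member`, `reaction_id`, `frequency`) sorted by
#'   decreasing frequency; fractions are in `[0, 1]` and independent of
#'   solution order.
#' @export
summarize_additions <- function(solutions, cm) {
  sols <- .as_solution_list(solutions)
  if (length(sols) == 0L) stop("no solutions to summarize")
  recs <- list()
  for (s in sols) {
    for (tg in names(s$added)) {
      for (rid in s$added[[tg]]) {
        recs[[length(recs) + 1L]] <- c(tg, rid)
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(member = character(), reaction_id = character(),
                      frequency = numeric()))
  }
  tab <- as.data.frame(table(member = vapply(recs, `[`, "", 1L),
                             reaction_id = vapply(recs, `[`, "", 2L)))
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  tab$frequency <- tab$Freq / length(sols)
  tab$Freq <- NULL
  tab$member <- as.character(tab$member)
  tab$reaction_id <- as.character(tab$reaction_id)
  tab[order(-tab$frequency, tab$member, tab$reaction_id), , drop = FALSE]
}

#' Flag unrealistic fluxes and paired-reaction cycles
#'
#' `near_bound` collects reactions whose solution flux either reaches
#' `near_bound_fraction` of its own bound magnitude or exceeds
#' `abs_threshold` outright (the repaired networks of small communities
#' run at the order of 10 flux units, so fluxes of order 100 hugging the
#' cap are a symptom of an unconstrained cycle, not biology).
#' `cycle_pairs` scans reaction pairs within each member whose
#' normalized stoichiometries are negatives of each other (or identical)
#' and whose fluxes are both above `abs_threshold` with opposed net
#' direction -- the pairwise signature of a thermodynamically infeasible
#' cycle.
#'
#' @param solution a [gapfill_solution].
#' @param cm the [community_model].
#' @param near_bound_fraction fraction of a reaction's own bound.
#' @param abs_threshold absolute flux threshold.
#' @return object of class `quality_flags`: `near_bound` (reaction ids),
#'   `cycle_pairs` (data frame `rxn_a`, `rxn_b`), `trust_penalty`
#'   (total flag count), thresholds.
#' @export
flag_quality <- function(solution, cm, near_bound_fraction = 0.9,
                         abs_threshold = 100) {
  fx <- solution$fluxes
  ids <- cm$rxns$id
  v <- as.numeric(fx[ids])
  bound <- pmax(abs(cm$rxns$lb), abs(cm$rxns$ub))
  nb <- ids[!is.na(v) &
              (abs(v) >= near_bound_fraction * bound |
                 abs(v) >= abs_threshold)]
  big <- which(!is.na(v) & abs(v) >= abs_threshold &
                 cm$rxns$type %in% c("model", "database"))
  pairs <- list()
  if (length(big) > 1L) {
    keys <- vapply(big, function(j) {
      st <- cm$S[, j, drop = TRUE]; st <- st[st != 0]
      .stoich_key(st)
    }, "")
    sgn <- vapply(big, function(j) {
      st <- cm$S[, j, drop = TRUE]; st <- st[st != 0]
      sign(st[order(names(st))][[1L]])
    }, 0)
    for (a in seq_along(big)) {
      for (b in seq_len(a - 1L)) {
        if (cm$rxns$member[big[a]] != cm$rxns$member[big[b]]) next
        if (keys[a] != keys[b]) next
        same_orient <- sgn[a] == sgn[b]
        opposed <- if (same_orient) {
          v[big[a]] * v[big[b]] < 0   # same equation, opposite flux
        } else {
          v[big[a]] * v[big[b]] > 0   # mirrored equation, same-signed flux
        }
        if (opposed) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            rxn_a = ids[big[b]], rxn_b = ids[big[a]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cycle_pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(rxn_a = character(), rxn_b = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(near_bound = nb, cycle_pairs = cycle_pairs,
                 trust_penalty = length(nb) + nrow(cycle_pairs),
                 near_bound_fraction = near_bound_fraction,
                 abs_threshold = abs_threshold),
            class = "quality_flags")
}

#' @exportS3Method base::print
print.quality_flags <- function(x, ...) {
  cat("<quality_flags> near-bound: ", length(x$near_bound),
      ", cycle pairs: ", nrow(x$cycle_pairs),
      " (penalty ", x$trust_penalty, ")\n", sep = "")
  invisible(x)
}

#' Write the exchange report tables as TSV
#'
#' @param report an [extract_exchanges()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_exchange_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$fluxes, file.path(dir, "transfer_fluxes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$environment,
                     file.path(dir, "environment_fluxes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$edges, file.path(dir, "crossfeeding_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Export the consensus cross-feeding graph as GraphViz DOT
#'
#' @param report an [extract_exchanges()] result.
#' @param path output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_crossfeeding_dot <- function(report, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("digraph crossfeeding {", con)
  writeLines("  rankdir=LR;", con)
  cs <- report$consensus
  for (z in seq_len(nrow(cs))) {
    writeLines(sprintf('  "%s" -> "%s" [label="%s (%.0f%%)"];',
                       cs$from[z], cs$to[z], cs$metabolite[z],
                       100 * cs$frequency[z]), con)
  }
  writeLines("}", con)
  invisible(path)
}
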