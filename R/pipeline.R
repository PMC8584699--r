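#' @title End-to-end pipeline
#' @description One call from configuration to artifact directory:
#'   read models/database/medium, curate, build the community, FVA
#'   reduce, solve and enumerate, verify, and write all reports plus a
#'   machine-readable run manifest.
#' @name pipeline
NULL

#' Validate a run configuration
#'
#' @param config list (or path to a JSON/YAML file) with fields:
#'   `models` (character paths), `floors` (positive numerics, one per
#'   model), `database` (path), `medium` (path, optional), `abundances`
#'   (optional), `weighted` (flag), `k` (>= 1 alternatives), `solver`,
#'   `time_limit`, `zero_tol`, `flux_cap`, `outdir`, `seed`.
#' @return the normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package needed to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(medium = NULL, abundances = NULL, weighted = FALSE,
                   k = 10, solver = "auto", time_limit = 7200,
                   zero_tol = 1e-6, flux_cap = 1000,
                   outdir = "comgapfill_out", seed = 1L,
                   allow_suboptimal = TRUE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  }
  if (is.null(config$models) || length(config$models) < 1L) {
    stop("config: at least one model path is required")
  }
  miss <- config$models[!file.exists(unlist(config$models))]
  if (length(miss)) stop("config: model file(s) not found: ",
                         paste(miss, collapse = ", "))
  if (is.null(config$database)) stop("config: database path is required")
  if (!file.exists(config$database)) {
    stop("config: database file not found: ", config$database)
  }
  if (!is.null(config$medium) && !file.exists(config$medium)) {
    stop("config: medium file not found: ", config$medium)
  }
  config$floors <- as.numeric(unlist(config$floors))
  if (length(config$floors) != length(config$models)) {
    config$floors <- rep_len(config$floors, length(config$models))
  }
  if (any(is.na(config$floors)) || any(config$floors <= 0)) {
    stop("config: growth floors must be positive")
  }
  if (config$k < 1) stop("config: k must be >= 1")
  config
}

#' Run the full community gap-filling pipeline
#'
#' @param config see [validate_run_config()].
#' @return invisibly, a list with the community, the enumeration result
#'   and the output directory. Artifacts written: `curation_report.tsv`,
#'   `fva_report.tsv`, `solution_<rank>.json`, `flux_table.tsv`,
#'   exchange report TSVs, `additions.tsv`, `quality_flags.json`,
#'   gap-filled model JSONs, `crossfeeding.dot`, `manifest.json`.
#' @export
run_gapfill_pipeline <- function(config) {
  config <- validate_run_config(config)
  set.seed(config$seed)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  models <- lapply(unlist(config$models), read_model,
                   flux_cap = config$flux_cap)
  names(models) <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(names(models))) {
    names(models) <- paste0("m", seq_along(models))
  }
  floors <- stats::setNames(config$floors, names(models))

  raw <- read_raw_database(config$database, flux_cap = config$flux_cap)
  db <- curate_database(raw, flux_cap = config$flux_cap,
                        provenance = config$database)
  write_curation_report(db, file.path(outdir, "curation_report.tsv"))

  med <- if (is.null(config$medium)) medium() else read_medium(config$medium)

  cm <- build_community(models, db, med, min_growth = floors,
                        abundances = config$abundances,
                        flux_cap = config$flux_cap)
  cm <- reduce_community(cm, zero_tol = config$zero_tol,
                         solver = config$solver)
  write_fva_report(cm, file.path(outdir, "fva_report.tsv"))

  problem <- formulate_gapfill(cm, growth_floors = floors,
                               weighted = isTRUE(config$weighted))
  enum <- enumerate_alternatives(problem, k = config$k,
                                 allow_suboptimal =
                                   isTRUE(config$allow_suboptimal),
                                 solver = config$solver,
                                 time_limit = config$time_limit)
  if (length(enum$solutions) == 0L) {
    stop("community gap-filling infeasible: no solution at any size")
  }
  best <- enum$solutions[[1L]]

  for (r in seq_along(enum$solutions)) {
    s <- enum$solutions[[r]]
    jsonlite::write_json(
      list(rank = r, status = s$status,
           objective_value = s$objective_value, added = s$added,
           growth = as.list(s$growth)),
      file.path(outdir, sprintf("solution_%02d.json", r)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  flux_tab <- data.frame(reaction_id = names(best$fluxes),
                         member = cm$rxns$member,
                         type = cm$rxns$type,
                         flux = as.numeric(best$fluxes))
  utils::write.table(flux_tab, file.path(outdir, "flux_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  xr <- extract_exchanges(enum, cm)
  write_exchange_report(xr, outdir)
  write_crossfeeding_dot(xr, file.path(outdir, "crossfeeding.dot"))
  utils::write.table(summarize_additions(enum, cm),
                     file.path(outdir, "additions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qf <- flag_quality(best, cm)
  jsonlite::write_json(list(near_bound = qf$near_bound,
                            cycle_pairs = qf$cycle_pairs,
                            trust_penalty = qf$trust_penalty),
                       file.path(outdir, "quality_flags.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ver <- apply_and_verify(models, best, db, med, floors,
                          abundances = config$abundances,
                          weighted = isTRUE(config$weighted),
                          flux_cap = config$flux_cap,
                          solver = config$solver)
  for (tg in names(ver$models)) {
    write_model(ver$models[[tg]],
                file.path(outdir, paste0("gapfilled_", tg, ".json")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("comgapfill")),
    seed = config$seed, solver = config$solver,
    flux_cap = config$flux_cap, zero_tol = config$zero_tol,
    k = config$k, weighted = isTRUE(config$weighted),
    floors = as.list(floors),
    objective = best$objective_value,
    added = best$added,
    verified_growth = as.list(ver$growth),
    n_solutions = length(enum$solutions),
    exhaustive_at_optimum = enum$exhaustive_at_optimum)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(community = cm, enumeration = enum, outdir = outdir,
                 manifest = manifest))
}
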