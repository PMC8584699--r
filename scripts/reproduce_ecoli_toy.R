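#!/usr/bin/env Rscript

# External-data reproduction: the two-strain E. coli core community.
#
# Downloads the BiGG e_coli_core model (network access required; this is
# deliberately NOT a unit test), derives a glucose-utilizer and an
# acetate-utilizer strain by deleting reactions from the core network,
# and runs community gap-filling with the deleted reactions (plus the
# rest of the core network) as the candidate database. The classic
# construction deletes reactions so the glucose utilizer keeps glucose
# uptake but loses acetate-producing routes while the acetate utilizer
# loses glucose uptake and part of the TCA cycle; the seven deletions
# encoded below follow the usual pathway-map version of that
# construction and are an approximation, not an exact strain copy.
#
# Reference points for comparison: a minimal repair adds 1 reaction to
# the glucose utilizer and 2 to the acetate utilizer; growth floors 0.9
# and 0.09 1/h; the unfilled glucose utilizer grows at 1.15 1/h alone.

suppressPackageStartupMessages(library(comgapfill))

url <- "http://bigg.ucsd.edu/static/models/e_coli_core.json"
dest <- file.path(tempdir(), "e_coli_core.json")
if (!file.exists(dest)) {
  message("downloading ", url)
  utils::download.file(url, dest, quiet = TRUE)
}

core <- read_model(dest)
cat("core model:", nrow(core$mets), "metabolites,",
    nrow(core$rxns), "reactions\n")

glc_deletions <- c("PGM", "MALS", "SUCOAS", "PFL", "PTAr")
ac_deletions <- c("GLCpts", "CS")

glc <- knockout(core, glc_deletions)
glc$id <- "ecoli_glc"
ac <- knockout(core, ac_deletions)
ac$id <- "ecoli_ac"

# candidate database: the full core reaction set, curated (biomass,
# exchanges and imbalanced reactions removed; the rest made reversible)
db <- curate_database(core, provenance = "e_coli_core")
cat("curated database:", nrow(db$rxns), "candidate reactions\n")

# aerobic glucose medium in core-model convention; acetate only via the
# partner strain
med <- medium(list(
  glc__D = c(-10, 1000), o2 = c(-1000, 1000), nh4 = c(-1000, 1000),
  pi = c(-1000, 1000), h2o = c(-1000, 1000), h = c(-1000, 1000),
  co2 = c(-1000, 1000)), default_policy = "open_secretion_only")

solo <- fba(glc, med)
cat(sprintf("glucose utilizer alone, before gap-filling: %.3f 1/h\n",
            solo$objective))

floors <- c(glc = 0.9, ac = 0.09)
cm <- build_community(list(glc = glc, ac = ac), db, med,
                      min_growth = floors)
cm <- reduce_community(cm)
en <- enumerate_alternatives(formulate_gapfill(cm, floors), k = 10,
                             time_limit = 300)
best <- en$solutions[[1]]
cat("best solution adds", best$objective_value, "reactions:\n")
for (tg in names(best$added)) {
  cat("  ", tg, ":", paste(best$added[[tg]], collapse = ", "), "\n")
}
cat(sprintf("verified growth: glc %.3f, ac %.3f 1/h\n",
            best$growth[["glc"]], best$growth[["ac"]]))
xr <- extract_exchanges(en, cm)
print(xr$consensus)
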