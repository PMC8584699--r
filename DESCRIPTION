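Package: comgapfill
Title: Community-Aware Gap Filling for Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gap filling of genome-scale metabolic models in a microbial
    community context. Members of a community are compartmentalized and
    coupled through a common metabolite pool, and a mixed-integer linear
    program selects the minimum number of reactions from a curated
    universal reaction database so that every member reaches a required
    growth rate, allowing metabolite exchange between members to stand in
    for missing reactions. Includes flux variability analysis to tighten
    candidate-reaction bounds and prune the search space, solver-agnostic
    enumeration of alternative optima via integer cuts, cross-feeding and
    added-reaction reports with quality flags for unrealistic fluxes, a
    reader/writer for COBRA-style JSON and SBML Level 3 FBC models,
    database curation by mass balance, and a synthetic-community fixture
    generator with an exhaustive gap-filling oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: GLPK solver command-line executable (glpsol)
Config/testthat/edition: 3
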