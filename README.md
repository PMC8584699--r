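# comgapfill

Gap filling for genome-scale metabolic models, done at the level of a
microbial community rather than one organism at a time.

Automatically reconstructed metabolic models usually contain gaps:
missing reactions that make biomass production infeasible in silico
even though the organism demonstrably grows. Classical gap-filling
patches each model in isolation, which over-fills it — a model is forced
to synthesize every biomass precursor itself even when, in its natural
community, a partner organism supplies the missing metabolite. For
organisms that coexist (gut symbionts, syntrophic consortia,
co-cultures), the community context is part of the evidence, and using
it yields smaller, better-supported repairs plus testable predictions of
cross-feeding.

## The optimization at the core

Each member *n* of an *N*-member community becomes a compartment holding
its model reactions `J_Model` and candidate reactions `J_Database` drawn
from a curated universal database. Compartments exchange metabolites
with one another and with the environment only through a common
metabolite pool. The package solves the MILP

```
minimize   sum_n sum_{j in J_Database^n} y_j^n

subject to sum_j S_ij^n v_j^n = 0                 for all i, n   (steady state)
           lb_j <= v_j^n <= ub_j                  j in J_Model^n
           y_j^n lb_j <= v_j^n <= y_j^n ub_j      j in J_Database^n
           v_Biomass^n >= v_Biomass^n,min         for all n      (growth floors)
           y_j^n in {0, 1}
           -v_ex(i)^c + sum_n w_n v_ex(i)^n = 0   for all pool metabolites i
```

with `w_n = 1`, or `w_n` = the member's relative abundance in the
abundance-weighted variant (member fluxes are per gram dry weight, so
weighting the pool balance corrects community-level mass balance).
Uptake is negative, secretion positive (COBRA exchange convention), and
the medium sets the environment-exchange bounds `v_ex(i)^c`.

Before the MILP is built, each compartment is analysed by flux
variability analysis with all pool transfers opened and the growth
requirement relaxed: candidates whose flux interval is exactly zero are
deleted and the rest get their interval as bounds, which shrinks the
MILP without touching its optimum. Alternative optimal repair sets are
enumerated with integer cuts, and solutions are post-processed into
cross-feeding edges, added-reaction frequencies, and quality flags for
fluxes that hug the bound cap or run in opposed reaction pairs
(pairwise thermodynamically infeasible cycles).

## Installation and requirements

```sh
R CMD INSTALL .
```

Depends on `Matrix`, `jsonlite` and `xml2`, and requires the GLPK
command-line solver `glpsol` on the `PATH` (set `COMGAPFILL_GLPSOL` to
point at it otherwise). Run the test suite with
`Rscript -e 'devtools::test()'`.

## Worked example

The bundled generator builds small communities with known ground truth.
Here, two linear-pathway organisms each have one reaction deleted from
their backbone; member 1 additionally secretes an intermediate (`xf`)
that member 2 can import downstream of its own deletion:

```r
library(comgapfill)

fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                          gaps_per_member = 1, n_decoys = 2,
                          cross_feed = TRUE, seed = 11)
fx
#> <community_fixture> seed 11: 2 member(s), 4 database reaction(s), min repair 1

cm <- build_community(fx$models, fx$database, fx$medium,
                      min_growth = fx$floors)
cm <- reduce_community(cm)             # FVA pruning of candidates
sol <- solve_gapfill(formulate_gapfill(cm, fx$floors))
sol
#> <gapfill_solution> status: optimal
#>   reactions added: 1
#>     org1: C1_4
#>   growth: org1=9.9, org2=0.1
```

Although both members are gapped, one added reaction suffices: member
2's missing step is bypassed by the planted exchange, so only member 1's
backbone (`C1_4`) needs repair — exactly what the exhaustive oracle
reports as the minimum (`fx$expected_min_repair` is 1). Growth is in
the fixture's arbitrary flux units, with member 2 held at its 0.1 floor
by the metabolite it receives. Enumerating and extracting exchanges
shows the predicted cross-feeding:

```r
en <- enumerate_alternatives(formulate_gapfill(cm, fx$floors), k = 10,
                             allow_suboptimal = FALSE)
extract_exchanges(en, cm)
#> <exchange_report> 1 solution(s), 1 cross-feeding edge(s) (1 consensus)
#>  metabolite from   to frequency
#>          xf org1 org2         1
```

Real models go through the same path: `read_model()` (SBML Level 3 FBC
or COBRA JSON), `curate_database()` (drops biomass equations, exchange
reactions, an exclusion list, and mass-imbalanced reactions), then
`build_community()` with a `medium()`. `run_gapfill_pipeline()` wraps
the whole chain and writes solution JSONs, flux/exchange TSV tables,
DOT cross-feeding graphs and a run manifest;
`inst/cli/comgapfill.R` exposes it as a shell command with
`curate-db`, `build-community`, `fva-prune`, `gapfill`, `report` and
`make-fixture` subcommands.

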