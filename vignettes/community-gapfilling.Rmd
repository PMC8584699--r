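---
title: "Community-aware gap filling: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-aware gap filling: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comgapfill)
```

## The problem

A genome-scale metabolic model (GSMM) is a stoichiometric matrix `S`
over metabolites and reactions, flux bounds per reaction, and a biomass
reaction whose flux is the growth rate. Automated reconstructions carry
gaps — missing reactions that leave some biomass precursor unproducible
— so flux balance analysis (FBA) predicts zero or infeasible growth for
organisms that demonstrably grow. Gap filling selects reactions from a
universal database to restore feasibility. Doing this per organism
ignores a strong piece of evidence for community organisms: metabolites
may arrive from a partner rather than from a missing internal pathway.
This package fills gaps at the community level, which both reduces the
number of added reactions and turns the repair into a prediction of
metabolic interactions.

## The community model

`build_community()` creates one compartment per member: the member's
reactions (its original boundary exchanges removed) plus every curated
database reaction as a gated candidate, all ids namespaced by a member
tag. Extracellular species are linked to a common metabolite pool: for
each member and each extracellular base id there is one reversible
transfer reaction with coefficient −1 on the member's extracellular
species and +1 on the pool species, and each pool metabolite has one
environment exchange whose bounds come from the medium. Uptake is
negative throughout (COBRA convention). The pool balance row for
metabolite *i* is

\[ -v^c_{ex(i)} + \sum_n w_n\, v^n_{ex(i)} = 0 , \]

so whatever members jointly secrete either accumulates in the
environment (positive environment exchange) or is consumed by other
members. Two structural assumptions matter:

* **Shared namespace.** Pool identity is the extracellular metabolite id
  after stripping the `_e` compartment suffix; members exchange a
  metabolite exactly when their extracellular species share a base id.
  Models and database must therefore use one nomenclature (e.g. BiGG).
  Cross-namespace metabolite mapping is out of scope.
* **Replaced boundaries.** A member's own exchange reactions are
  replaced by pool transfers; the member talks to the environment only
  through the pool. Keeping both would double-count the boundary and
  let a member bypass the shared medium.

The gap-filling MILP minimizes the number of added database reactions
subject to per-compartment steady state, model bounds, binary-gated
candidate bounds, a positive growth floor per member, and the pool
balance rows. A zero floor is rejected by `formulate_gapfill()`: it
would make the trivial empty repair optimal for that member and the
method degenerates.

### Abundance weighting

Member fluxes are per gram dry weight of that member, so summing them
in the pool row implicitly assumes equal biomass. When relative
abundances are known, the weighted variant sets \(w_n\) to the
abundance fraction, which restores community-level mass balance. This
weighting of the pool rows is our reading of "correcting the community
mass balance" for per-gDW fluxes; with all weights equal the optimum
provably coincides with the unweighted one (tested), and weights enter
only the pool rows, never the objective.

## FVA reduction and why it is sound

Candidates enter fully reversible at the global cap, which makes the
MILP large. `run_compartment_fva()` computes, per candidate, its exact
flux interval in a relaxation of the compartment: every pool transfer
opened to ±cap and the biomass floor dropped to zero
(`relax_growth = TRUE`). That relaxation over-approximates any flux
state the compartment can occupy inside *any* community under *any*
medium — partners may supply or drain arbitrary amounts of every pool
metabolite, and the member need not grow. Consequently a candidate
whose interval is `{0}` can never carry flux in a feasible community
state and `prune_and_tighten()` deletes it; surviving candidates get
the interval, rounded outward by `zero_tol`, as bounds. Pruning
therefore never changes the MILP optimum (asserted over seeded random
communities in the tests). Two deliberate choices:

* FVA runs with the growth floor relaxed because gapped compartments
  typically cannot grow yet; enforcing the floor would make the FVA LP
  infeasible exactly where gap filling is needed.
* When a medium is passed to FVA explicitly, the intervals tighten and
  pruning is sound only for communities under that medium or wider
  ones; the sound fully-open relaxation is the default.

The reduction's payoff is structural: a database reaction written over
one member's metabolites is disconnected in every other member's
compartment and is pruned there, so the binary count drops roughly by a
factor of the member count before the MILP is ever solved.

## Solving and enumerating

The MILP and all LPs go to GLPK's `glpsol` through a thin LP-file
interface (`solve_lp()`); feasibility and integrality are at GLPK's
defaults, the optimality gap is 0 (proven optima), and variable order
is fixed lexicographically (member tag, then reaction id) so the
incumbent is reproducible run to run. Incumbent binaries are rounded at
0.5 and re-verified by fixing them and re-solving the LP; the fluxes
reported with a solution are that LP's optimum with summed member
biomass as objective, i.e. an FBA point of the repaired community.

Alternative optima are enumerated solver-agnostically: after each
solution the support `{(n,j) : y^n_j = 1}` is excluded with the integer
cut \(\sum_{(n,j)\in\text{support}} y^n_j \le |\text{support}| - 1\)
(excluding an empty support instead requires at least one binary on),
and the MILP is re-solved. With `allow_suboptimal = FALSE` enumeration
stops when the objective first rises, and `exhaustive_at_optimum`
certifies that every optimal support was found; with `TRUE` the list
continues into the "k best" sense. A solution's identity is its support
— flux degeneracy within one support is not enumerated, matching how
repair sets are usually reported.

## Reporting

`extract_exchanges()` tabulates transfer and environment fluxes per
solution and derives cross-feeding edges: metabolite *i* flows from
member *a* to member *b* when *a*'s transfer flux is above `1e-6` and
*b*'s below `−1e-6` in the same solution. Concurrent environment
involvement does not cancel an edge (members may share a medium
nutrient and still feed each other). `summarize_additions()` gives the
fraction of solutions containing each added reaction.
`flag_quality()` marks fluxes at ≥ 90% of their own bound or above 100
flux units outright — small repaired communities run at order 10
mmol·gDW⁻¹·h⁻¹, so order-100 fluxes pinned to the cap indicate an
unconstrained cycle, not biology — and scans for reaction pairs with
mirrored stoichiometry and opposed large fluxes, the pairwise signature
of a thermodynamically infeasible cycle. Both thresholds are
configurable; the cycle scan is a heuristic, not a loopless/TFA
analysis (see Limitations).

## Database curation

`curate_database()` drops, in order: biomass equations (case-insensitive
id/name patterns, default `"biomass"`), exchange reactions, an explicit
exclusion list (e.g. reactions found only in eukaryotes — no algorithmic
rule can decide this, so it is the caller's list), and reactions whose
element/charge balance fails. Balance is checked from Hill-style
formulas (`parse_formula()`, pseudo-elements allowed, decimal counts
accepted for averaged formulas); a reaction with any formula-less
participant is `undetermined` and excluded by default
(`keep_undetermined = TRUE` retains, a whitelist exempts ids; when only
a charge is missing the charge test is skipped rather than discarding
the reaction). Survivors are reset to fully reversible bounds — the
database's own directionality annotations are deliberately discarded
because FVA re-derives directionality per compartment.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `flux_cap` | 1000 | mmol·gDW⁻¹·h⁻¹ | standard COBRA stand-in for unbounded fluxes; every bound is finite so LPs cannot be unbounded |
| `min_growth` (floors) | user | h⁻¹ (or d⁻¹) | experimental growth of each member under the simulated condition; must be > 0 |
| `zero_tol` | 1e-6 | flux | pruning threshold and outward rounding of FVA bounds; prevents tolerance-induced infeasibility |
| `mip_gap` | 0 | – | repair counts are small integers; proving optimality is cheap and the oracle comparison requires it |
| `k` | 10 | – | alternative solutions examined; matches the usual "ten best" reporting depth |
| `near_bound_fraction` / `abs_threshold` | 0.9 / 100 | – / flux | quality flags; see Reporting |

## The synthetic generator and what passing tests mean

`make_linear_fixture()` builds members as linear chains (nutrient
exchange → transport → `chain_length` conversions → biomass drain) and
plants: gaps (chain steps moved into the database), parallel duplicate
routes (symmetric optima for enumeration tests), a cross-feeding bypass
(member 1 secretes an intermediate member 2 can import downstream of
its gap), and disconnected decoys. All metabolites carry the unit
pseudo-formula `"X"`, so fixtures pass mass-balance curation by
construction and fixture logic stays independent of formula parsing.
Ground truth — the minimum repair count and *all* optimal supports — is
computed at generation by `oracle_gapfill()`, an exhaustive
breadth-first search over candidate subsets tested by LP feasibility,
which shares no code path with the MILP search.

The validation suite runs 200 seeded fixtures (1–3 members, chains of
3–4 steps, up to 12 binaries each — sizes chosen so the exhaustive
oracle stays tractable) plus dedicated degenerate cases; the
acceptance script re-runs 60 fresh ones per invocation. What this does
*not* show: fixtures are acyclic single-currency chains, so they do not
exercise cofactor coupling, internal cycles, redox balancing, or the
alternate-optimum explosion of genome-scale networks. On real models
the method's correctness arguments (pruning soundness, oracle
equivalence of the MILP, constraint satisfaction) still hold — they are
structural — but solution *quality* depends on database curation and on
exchange-bound realism, and per-member repair splits are sensitive to
alternate optima.

## Numerical choices and degenerate inputs

Bounds beyond the cap (including infinities) are clipped on read.
Gating uses the candidate's FVA bounds as big-M coefficients — the
tightest valid values — and candidate variable bounds are widened to
include 0 so `y = 0` is always consistent. Binary rounding at 0.5 is
followed by a fixed-binary LP re-solve, so reported fluxes satisfy all
constraints to LP tolerance rather than MIP tolerance (residuals in the
suite sit at ~1e-12, asserted ≤ 1e-6). Infeasible communities are
diagnosed by re-solving with each member's floor kept in isolation,
naming the members whose floor is unreachable even with the full
database. Empty databases, zero candidates after pruning, media naming
unknown metabolites (warning, inert pool entry), and communities of one
are all defined paths with tests.

## Limitations

* No thermodynamic analysis: infeasible cycles are flagged pairwise,
  not eliminated; loopless FVA is out of scope.
* No dynamics or spatial structure (no dFBA/COMETS-style simulation);
  the community is one steady-state snapshot under one medium.
* One shared namespace across members and database; no metabolite
  translation layer.
* The eukaryote-only exclusion during curation is a user-supplied list,
  not an inference.
* Abundance weighting is a pool-row correction, not a full
  biomass-coupled community FBA (SteadyCom-style coupling is a
  different model).
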