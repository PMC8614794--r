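---
title: "Fuzzy multiobjective target identification in paired metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy multiobjective target identification in paired metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtarget)
```

## The problem

An ideal anticancer metabolic intervention is lethal to the tumour and nearly
invisible to healthy tissue. Given a pair of constraint-based metabolic
models — a cancer model (CA) and a basal/normal model (BL) sharing most of
their reaction content — `fluxtarget` searches for gene, reaction, or
metabolite ("antimetabolite") interventions that simultaneously

1. abolish growth of the treated cancer model,
2. preserve viability of the perturbed normal model (high ATP output, low
   growth),
3. push the perturbed normal flux pattern *away* from the cancer template,
   and
4. keep it *close* to the normal template.

The four goals are scored with linear fuzzy membership grades, aggregated by
a mean–min rule into a single hierarchical fitness, and optimized by a
nested differential-evolution search whose every fitness call solves two
nested optimization problems per model.

## Inner problems: FBA and unique flux distributions

Each model is split into non-negative forward/backward flux slots
(`vf - vb = v`), so treatment restrictions are always simple interval
restrictions on non-negative slots. For a given treatment the package
solves, for the treated CA and the perturbed BL model separately:

* **FBA** — maximize `w_atp * v_ATP + w_biomass * v_biomass` subject to
  steady state `N (vf - vb) = 0` and slot bounds. The defaults are
  CA `(0, 1)` (mortality is judged purely on growth) and BL `(1, 1)`
  (viability trades off ATP production and growth); the study that motivated
  this design never states its weights, so both are configurable and every
  shipped test records the weights it uses.
* **Flux minimization (the "unique flux distribution" stage)** — minimize
  the sum of squared *internal* forward and backward fluxes subject to the
  same constraints plus attainment of the FBA optimum. Strict convexity on
  the internal subspace makes the internal flux pattern unique, which is
  what makes template comparison meaningful. Boundary (exchange) reactions
  are excluded from the objective sum; they carry a tiny ridge weight
  (`1e-6`) instead, which keeps the quadratic form positive definite for
  the dual-method QP solver and makes the full solution unique while
  perturbing internal fluxes negligibly.

Numerical choices: the attainment constraint is relaxed by a relative
`1e-6` to absorb LP/QP tolerance mismatch; a treated model whose polytope
is empty is reported as an all-zero "infeasible" state rather than an error
(an infeasible cancer model is maximally dead, and the search must be able
to grade it); a model is classified "dead" when growth is the sole
objective term and its optimum falls at or below `1e-10` flux units
(mmol gDW^-1 h^-1).

The linear programs are solved by a dense two-phase primal simplex with
Bland's anti-cycling rule implemented in the package, sized for the small
models this package targets; pinned variables are eliminated before
pivoting, and basic artificials are driven out between phases. The
quadratic stage uses the Goldfarb–Idnani dual method (`quadprog`). At every
returned optimum the steady-state residual is required to be below `1e-6`,
and internal fluxes are reproducible across variable orderings to `1e-6`
(both are asserted in the test suite).

## The grade hierarchy

Every objective is normalised by a linear membership grade between two
anchors, clipped to [0, 1], and grades are combined with the idempotent
mean–min conjunction `(mean + min) / 2`:

* `eta_cvtr` — mortality of the treated cancer model: minimizing
  membership of treated growth on `[0, untreated growth optimum]`; growth
  at or below `1e-10` grades exactly 1.
* `eta_atp_pb`, `eta_biomass_pb`, `eta_cvpb` — perturbed-normal viability:
  maximizing membership of ATP output on `[0, untreated ATP optimum]`,
  minimizing membership of growth on `[0, untreated growth optimum]`,
  aggregated by mean–min. The anchor pairs are configurable: the reported
  reference grades (perturbed viability 0.625 at "63% of maximal ATP")
  cannot be reproduced exactly under any single obvious anchor pair, so the
  anchors used in the original study are treated as unrecoverable and the
  defaults above are this package's own choice.
* `eta_sf`, `eta_lf`, `eta_sm`, `eta_lm`, `eta_v`, `eta_m`, `eta_dv` —
  metabolic deviation. Per reaction the deviation scale is
  `d_i = max(|v_CA,i - v_BL,i|, eps * max(1, |v_BL,i|))` with `eps = 1e-6`.
  Dissimilarity-from-cancer memberships `clip(|v_PB - v_CA|/d, 0, 1)` are
  averaged over reactions where the cancer template runs below the normal
  template (`eta_sf`) and above it (`eta_lf`); the same construction on
  compartment-pooled metabolite-flow rates gives `eta_sm` and `eta_lm`.
  Similarity-to-normal memberships `1 - clip(|v_PB - v_BL|/d, 0, 1)` are
  averaged over all internal reactions (`eta_v`) and all species
  (`eta_m`). The exact functional forms behind these six grades are not
  recoverable from the methods text that motivated the package, so this
  smaller/larger-than-normal × flux/metabolite-flow construction is the
  package's own definition; it is deliberately simple, scale-invariant, and
  replaceable. Partition membership uses a tolerance of the same size as
  the `d`-floor so that reactions where the two templates agree to
  numerical noise land in neither partition; an empty partition grades
  vacuously 1.
* Aggregation: `eta_cv = mean_min(eta_cvtr, eta_cvpb)`,
  `eta_dv = mean_min(six deviation grades)`,
  `eta_se = mean_min(eta_cvpb, eta_dv)` (higher = fewer predicted side
  effects), and the overall fitness
  `eta_d = (eta_cv + min(eta_cv, eta_dv)) / 2`.

The mean–min reading of the aggregation formulas is locked by regression
tests: with `eta_cvtr = 1` it reproduces the published side-effect grades
of 28 of the 30 reference treatments (`reference_grades()`) to ±0.001. The
remaining two antimetabolite rows (`hmgcoa`, `ump`) are inconsistent with
the identity *as printed* by about 0.007; back-solving suggests a
typographical slip in their printed cell-viability grades (0.712 and 0.701
where 0.719 and 0.709 would make the rows self-consistent). The package
reports them as printed and the corresponding acceptance test documents the
discrepancy rather than masking it.

## Treatments

* **Gene** targets evaluate GPR rules jointly under the knocked set
  (isozymes rescue, complexes fail); every disabled reaction has both slots
  restricted to `[0, strength × original bound]`. Default strength 0 is a
  full knockout, matching the lethality language of the motivating study;
  partial repression is a knob.
* **Reaction** targets restrict both slots directly (inhibit) or raise the
  forward lower bound to `strength × template flux` (enhance).
* **Metabolite** targets block synthesis: every *internal* slot that
  produces the species — positive stoichiometric contribution in that
  slot's direction, pooled across compartments — is restricted; consuming
  slots are untouched. This producer-blocking rule is the package's own
  definition (the appendix that specified the original bound construction
  is not available); it matches the pharmacology of antimetabolites, which
  act on synthesis. Enhancement ("supplementation") is a minimum-production
  constraint at `factor × the normal-template production rate` (default
  1.5), added as a linear constraint rather than a bound change, because a
  supplement acts on a metabolite, not on any single reaction.

The same construction rule is applied to both models of the pair; the
per-model GPRs and stoichiometry decide which slots are touched.

## Outer search

The outer problem — choose an index vector `z` of 1–3 candidate targets
maximizing `eta_d` — is solved by a nested hybrid differential evolution:
DE/rand/1 mutation with rounding and clipping to integer pool indices,
binomial crossover, duplicate repair by resampling from unused pool
members, greedy selection, and a migration phase that re-randomizes all but
the best individual when the population fitness spread drops below a
tolerance. Multi-target searches use two candidate groups (first slot from
the prior best one-target hits, remaining slots from the rest) to cut the
combinatorics. Defaults `NP = 20`, `F = 0.7`, `CR = 0.8`, 100 generations,
migration tolerance 0.01 are this package's choices (the original
parameterization is in an unavailable appendix) and are all configurable.
Fitness values are memoized by the canonicalised target set, so the number
of inner solves is bounded by the number of distinct candidates visited,
and runs are exactly reproducible under a fixed seed. An exhaustive
enumerator with identical ranking rules (fitness, then side-effect grade,
then lexicographic ids) serves as the test oracle on pools small enough to
enumerate.

## Metabolite flows and factor analysis

The metabolite-flow (flux-sum) rate of a base species is its total
production pooled across compartment instances: positive-coefficient
contributions of forward fluxes plus production by consumers running
backwards. For species untouched by boundary reactions, production equals
consumption at any steady-state optimum — asserted to `1e-6` per fixture.
Perturbation profiles are summarised as `log2((r + p)/(r_BL + p))` with
pseudo-flow `p = 1e-9` guarding zero flows (the motivating text is silent
on this; the value only matters for flows within a factor of ~100 of zero),
and rows unchanged across all columns (`|L| < 1e-6`) are dropped.
Compartments are pooled *before* the log transform, following the flow
definition's compartment summation.

Factor analysis of a fold-change matrix (species as variables, conditions
as observations) is an in-repo implementation of iterated principal-axis
extraction — communalities start at squared multiple correlations and are
iterated to `1e-4`, capped at 500 iterations with an explicit
non-convergence error — followed by orthogonal quartimax rotation via
pairwise planar rotations with the classical closed-form angle. It is
validated against synthetic oracles (a rank-one matrix must load ≥95% of
common variance on one factor; orthogonal block designs must separate;
rotation must preserve communalities), not against any external
implementation, since none is available in the package's dependency set.

## The toy generator

`make_toy_pair()` emits a paired CA/BL model small enough for exhaustive
oracles (about 18 reactions, 11 species, 2 compartments) yet exercising
every code path: a shared core (glucose uptake → glycolysis-like step →
ATP demand + biomass), a reversible transporter, two redundant precursor
routes (the second gated by a planted *safe* gene whose knockout changes
nothing), a cancer-only biomass precursor synthesized through the planted
*lethal* gene's reaction, an overflow (lactate-like) branch, and a
configurable number of low-capacity side branches whose bounds are drawn
from the seeded RNG. The tumour-like bound shift (double uptake plus a
permissive overflow sink in CA) makes the two untreated templates genuinely
different, which keeps all six deviation grades non-degenerate.

Every planted property is verified before a pair is returned, by a
deliberately independent route: a net-flux (unsplit) FBA assembled directly
from the model tables and solved as a ridge-regularized quadratic program
(ridge `1e-7`), a different algorithm from the package's simplex. The
ridge biases optima by well under the assertion tolerances used
(`1e-6` for lethality, `1e-4` for optimum preservation). What the toys do
*not* emulate: realistic network size, cofactor coupling, compartmental
transport costs, or degenerate alternate optima at genome scale — so
passing tests demonstrate correctness of the machinery, not biological
fidelity of any particular prediction.

## Problem sizes and limitations

The shipped tests and the acceptance script run on the toy scale: candidate
pools of ≤ 12 targets, exhaustive baselines of ≤ 66 combinations,
default-parameter searches over 100 generations — all solvable in seconds
with the dense simplex. Genome-scale models (thousands of reactions) are
outside the intended envelope of the bundled solvers; the solver layer is
isolated behind `solve_fba()` / `solve_ufd()` precisely so a sparse
industrial backend could be substituted. Other known limitations: only
linear membership functions are provided; the deviation-grade construction
is an explicit stand-in for an unrecoverable original; and the
reported-grade regression inherits the two typographical inconsistencies
discussed above.
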