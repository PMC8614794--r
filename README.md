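# fluxtarget

Fuzzy multiobjective identification of anticancer metabolic targets in
paired constraint-based models.

`fluxtarget` is for computational/systems biologists who have a pair of
genome-scale (or toy-scale) metabolic models — a cancer model (CA) and a
basal/normal model (BL) — and want to rank gene knockouts, reaction
modulations, and antimetabolite-style interventions by how selectively they
kill the cancer model while sparing the normal one.

## The method

For a candidate intervention Ω_TR, two nested problems are solved per model
over split non-negative fluxes (v = vf − vb):

```
FBA:  max  w_atp·v_ATP + w_biomass·v_biomass
      s.t. N (vf − vb) = 0,   bounds + treatment restrictions

UFD:  min  Σ_{i ∈ Ω_Int} (vf_i² + vb_i²)
      s.t. same constraints,  objective ≥ FBA optimum
```

The quadratic second stage makes the internal flux pattern unique, so the
perturbed normal state can be compared meaningfully against the untreated
CA and BL templates. Each goal is scored by a linear membership grade
η ∈ [0, 1] and grades combine with the mean–min conjunction
`mean_min(g…) = (mean(g) + min(g)) / 2`:

```
η_CV  = mean_min(η_CVTR, η_CVPB)        # kill cancer, keep normal viable
η_DV  = mean_min(η_SF, η_SM, η_LF, η_LM, η_v, η_M)   # metabolic deviation
η_SE  = mean_min(η_CVPB, η_DV)          # side-effect grade (higher = safer)
η_D   = (η_CV + min(η_CV, η_DV)) / 2    # hierarchical fitness
```

The outer integer search over candidate targets (1–3 per combination) is a
nested hybrid differential evolution with memoized fitness; an exhaustive
enumerator with the same ranking rules serves as its oracle. Metabolite-flow
(flux-sum) rates, log2 fold-change matrices against the BL template, and
iterated principal-factor analysis with quartimax rotation summarise how a
treatment reshapes metabolism. A paired toy-model generator with planted
lethal/safe targets makes the whole pipeline testable end to end.

## Worked example

```r
library(fluxtarget)

pair <- make_toy_pair(toy_config(seed = 7))
tpl  <- compute_templates(pair$ca, pair$bl)

pool   <- candidate_pools(lapply(pair$bl$genes, function(g) target("gene", g)))
ranked <- run_search(pair$ca, pair$bl, pool, K = 1,
                     config = nhde_config(seed = 3), templates = tpl)
head(ranked[, c("treatment", "eta_cvtr", "eta_cvpb", "eta_dv", "eta_se", "eta_d")], 3)
```

```
                treatment eta_cvtr  eta_cvpb    eta_dv    eta_se     eta_d
1 gene:g_lethal:inhibit:0        1 0.9999992 1.0000000 0.9999994 0.9999994
2    gene:g_gly:inhibit:0        1 0.2500000 0.4328704 0.2957176 0.4351852
3    gene:g_oxp:inhibit:0        1 0.2500000 0.4328704 0.2957176 0.4351852
```

The planted lethal gene tops the ranking with η_CVTR = 1 (the treated
cancer model's growth optimum fell below the 1e-10 death threshold) and
η_SE ≈ 1 (the perturbed normal model is indistinguishable from its own
template: full ATP output, flux pattern unchanged). The runner-up knockouts
also kill the cancer model but collapse the normal model's ATP production
(η_CVPB = 0.25), i.e. they are predicted to be toxic.

The same machinery runs from a shell:

```sh
Rscript inst/scripts/fluxtarget.R make-fixtures --out fx --seed 7
Rscript inst/scripts/fluxtarget.R identify --ca fx/ca.json --bl fx/bl.json \
        --approach gene --k 1 --seed 3 --out run1
# top candidate: gene:g_lethal:inhibit:0 (eta_d = 1.000)
Rscript inst/scripts/fluxtarget.R grade --ca fx/ca.json --bl fx/bl.json met:caprec:inhibit
```

`reference_grades()` ships the published membership-grade triples
(η_CV, η_DV, η_SE) for thirty reported colorectal-cancer interventions;
they lock the mean–min aggregation arithmetic via regression tests (see the
methods vignette for the two rows that are inconsistent as printed).

## Layout

- `R/` — model container + I/O (JSON / SBML-FBC / TSV), GPR logic, split
  models, LP/QP inner solvers, treatment construction, grade hierarchy,
  NHDE search, flow and factor analysis, CLI workflow functions
- `inst/scripts/fluxtarget.R` — thin command-line dispatcher
- `tests/testthat/` — unit, property, and acceptance tests
- `vignettes/methods.Rmd` — the model, its assumptions, tunables, and
  design decisions
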