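---
title: "Closed-loop optimization of cryopreservation extender media: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optimization of cryopreservation extender media: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoevolve)
```

This vignette is the package's account of its methods: the optimization
loop, the surrogate models, the statistical evaluation layer, the synthetic
"virtual lab" that stands in for wet-lab measurement, and the design
decisions taken where the procedure was genuinely open. Nothing here states
an empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The formulation space

Eleven media components are optimized simultaneously; each has a unit, a
concentration range, a scalar reference value and an `active` flag
(`extender_space()`). Two deliberate conventions:

* **Zero always validates.** The split-sample commercial control lacks
  several optimized components whose ranges exclude zero (melatonin
  2–3 mM, CLC 0.5–1 mg/mL), and components removed mid-campaign keep their
  ledger column with value 0. `validate_formulation()` therefore treats an
  exact 0 as "component absent" for any component, while any non-zero value
  must respect the bounds (active components) or equal the frozen value
  (inactive ones). This keeps one schema across the whole campaign.
* **The control extender includes 6% v/v glycerol.** The classical
  tris–citrate–fructose egg-yolk recipe is carried in mM as an attribute
  (fructose 55.5 mM ↔ 1.0% w/v via its 180.16 g/mol molar mass); glycerol
  at the 6% industry-standard level is part of the control because a
  glycerol-free frozen control would be biologically implausible and could
  not produce the 60–70% post-thaw motility band the control is defined by.

Batch-recipe conversion (`to_recipe()`) maps space units to dispensing
units (mL for v/v liquids, mg via % w/v or molar mass, µL of concentrated
stock for glutathione/melatonin, ng for NGF) and computes the water filler
volume. Stock concentrations and molar masses are configurable data
(`default_conversions()`), not assertions about any particular lab's
stocks; the shipped top-extender recipe fixture assumes a 10 mL batch,
consistent with its summed liquid volumes.

## 2. Differential evolution

The optimizer is DE/rand/1/bin ("strategy 1"): for each target vector,
three mutually distinct donors r1, r2, r3 are drawn, and each coordinate
becomes `x_r3 + F (x_r1 − x_r2)` with probability CR, otherwise the
target's value. Defaults: population 8 (one experimental batch),
`F = 0.9`, `CR = 0.5`.

Decisions taken where standard practice had to fill gaps:

* **Forced mutation coordinate.** One uniformly chosen coordinate per
  trial always takes the mutant value, the standard binomial-crossover
  guard against trials identical to their targets.
* **Initialization** uses Latin-hypercube stratification per component
  (`lhs::randomLHS`): with 8 members in 11 dimensions, plain uniform
  sampling can leave entire octiles of a range unsampled; LHS guarantees
  coverage ("spans the entire parameter space") at this tiny population
  size.
* **Late-campaign jitter.** From generation 11 onward every mutated
  coordinate receives an extra `reference × U(−10%, +10%)`. The reference
  value used is the component's upper bound — the only per-component
  scalar the design table prints; this is recorded as an assumption and is
  configurable (`reference` column of the space).
* **Selection is pooled top-N** over parents ∪ trials ("only the highest
  scoring individuals from both populations"), not classic per-index
  replacement; the classic rule is available as
  `de_config(selection = "pairwise")`. Ties break in favour of trial
  vectors (fresh material), then lexicographically by id, making selection
  deterministic.
* **Bound handling is clipping**, not reflection or resampling:
  concentrations cannot be negative, and clipping is what lets the
  optimizer park a harmful component exactly at 0.

## 3. Surrogate models

Both surrogates map a 12-dimensional feature vector to post-thaw total
motility (%). Features are the 11 components min–max scaled by their design
bounds (degenerate bounds map to 0) plus the **water filler fraction** as
the 12th input — the design space has 11 variables but the model
specification calls for 12 inputs, and the batch water column is the only
remaining degree of freedom of a recipe; the choice is configurable
(`surrogate_config(input_dim = ...)`).

* **Network** (`fit_ann()`): 12 inputs, one hidden layer of 12 rectified
  linear units, one linear output; L2 penalty 1e-4; mean-squared-error
  loss. The training budget is unspecified by the procedure the package
  follows, so it is fixed for reproducibility: full-batch Adam
  (rate 0.01) on standardized targets, seeded He initialization, an epoch
  cap (default 2000) and early stop after 200 epochs without loss
  improvement. Refits under the same seed are bit-identical.
* **Gaussian process** (`fit_gpr()`): squared-exponential kernel with a
  length-scale per feature plus an additive observation-noise term, on
  standardized targets; hyperparameters maximize the log marginal
  likelihood (analytic gradients, L-BFGS-B, seeded restarts, bounds
  `[1e-3, 1e3]` on every scale). Replicate bulls score the same
  formulation at identical features, so duplicate feature rows are pooled
  by averaging their targets before fitting — an exact reduction for GP
  regression with i.i.d. noise that also keeps the kernel matrix small.
  `predict(..., se.fit = TRUE)` exposes the predictive SD, which is near
  the fitted noise level inside dense data and grows toward
  `sqrt(signal + noise)` far from the training hull.

**Cross-validation and model selection.** `kfold_cv()` assigns all pairs
to 10 seeded disjoint folds and averages held-out MSEs. At the surrogate
coupling generation (default 7), both models are trained on all completed
generations but the last, predict the last one, and `compare_models()`
runs the evaluation battery: Kruskal–Wallis omnibus over
{experimental, network, GP}, pairwise Dunn tests, per-model
Fligner–Killeen spread comparison with the experimental sample, and
per-model Mann–Whitney equivalence. The selection rule prefers, among
models not significantly different in location from the experiment, the
single model whose *spread* is homoscedastic with it — a model that tracks
assay dispersion is more useful to a screening loop than one that merely
matches the center — falling back to the lower cross-validated MSE. The
rule is symmetric under relabeling of the models.

**Coupling.** From the coupling generation onward the optimizer proposes
`candidate_oversampling × 8` trials (default 32) and the selected model
keeps the 8 with the highest predicted motility (greedy mean acquisition;
no expected-improvement variants). This is the only coupling consistent
with an unchanged experimental throughput of 8 extenders per generation.
The surrogate always trains on and predicts *total* motility, also in
relative-metric generations: within a generation the control term is a
per-bull constant, so candidate ranking is unaffected.

## 4. The statistical evaluation layer

`mann_whitney_equivalence()` implements the two-sample Mann–Whitney test
for equivalence (Wellek's formulation), whose null hypothesis is
non-equivalence. With ties weighted ½,

* `W+ = (1/mn) Σ Σ [1{x > y} + ½·1{x = y}]` estimates `P(X > Y)`;
* `σ̂²` is the U-statistic variance estimate
  `(E[h²] − W² + (n−1)(π̂_xyy − W²) + (m−1)(π̂_xxy − W²)) / (mn)` with
  `π̂_xyy, π̂_xxy` the shared-X and shared-Y second-order U-statistics.
  (The familiar `W(1−W)` first term is the tie-free special case; with
  ½-weighted ties the kernel is not 0/1 and `E[h²]` is the correct term —
  it also makes all-tied samples correctly degenerate.)
* `CRIT = sqrt(χ²₁;α(ncp = (ε̄/σ̂)²))`, `ε̄ = (ε1+ε2)/2`, and equivalence
  is established (`REJ = 1`) iff `|W+ − center| / σ̂ < CRIT` with
  `center = ½ + (ε2−ε1)/2`. Defaults: α = 0.05, symmetric margins 0.15.
* Degenerate edge: `σ̂ = 0` with `W+` pinned at the center (all values
  tied) is an error; `σ̂ = 0` away from the center (complete separation)
  returns `REJ = 0` — non-equivalence obviously cannot be rejected.

Published summary tuples are treated as *inputs* to the decision rule in
regression tests, never as outputs to reproduce: the critical bounds
printed alongside them are mutually inconsistent under any single formula
(two tuples share σ̂ = 0.07 and ε = 0.15 yet print CRIT 0.52 and 0.63), so
only the decision `REJ` is checkable.

Kruskal–Wallis and Fligner–Killeen delegate to `stats::kruskal.test()` and
`stats::fligner.test()`; the Dunn post-hoc (tie-corrected pairwise z tests
on mean ranks) is implemented in-package since base R lacks it, reporting
both unadjusted and Holm-adjusted p-values (the Holm column is the one
decisions use; the adjustment method is otherwise unspecified upstream).
All three are verified against independent from-scratch implementations in
the test suite.

`generation_summary()` reports medians ± SD per generation of per-bull
pooled values (straw replicates averaged within bull), and
`relative_total_motility()` is the per-sample treatment/control ratio; a
non-positive control motility is a metric error, not silently dropped.

## 5. The virtual lab

The synthetic stand-in for all wet-lab measurement has two parts.

**Ground-truth surface** (`response_surface()`): baseline + concave
Gaussian bumps per component + signed pairwise interaction products on
bound-normalized concentrations + linear monotone penalties, truncated to
[0, 100] last. This is the simplest family that encodes the campaign's
qualitative biology with a known, exposable optimum
(`surface_argmax()`). The default `benchmark_surface()`:

| term | choice | rationale |
|---|---|---|
| baseline 18% | random media freeze poorly | early-generation medians ~25% |
| glycerol bump (opt 6, amp 22) | dominant permeating CPA at the 6% industry level | largest single effect |
| ethylene glycol slope −2.2/% plus glycerol×EG −6 | EG-containing media do worse; redundancy/antagonism with glycerol | optimum has zero EG |
| fructose bump amp 2 | dispensable energy source | removing it costs <2 points |
| NGF slope −16/(mg/mL) | detrimental additive, worth removing mid-campaign | removal visibly helps |
| egg yolk (opt 16, amp 16), tris, milk, trehalose, CLC, melatonin bumps | classical membrane-stabilizer/buffer/sugar optima | control lands at ≈67.6%, optimum 91% |

The exposed argmax is computed by cyclic coordinate ascent on dense
per-coordinate grids; for this family it is exact because every
interaction involves a component (EG) whose optimum sits at an interaction
zero, and the test suite cross-checks it by dense grid search over
2-component slices.

**Noise model** (`noise_model()`): an additive per-bull effect
(`sd_bull`, default 8%) shared between a bull's treatment and control
straws, plus i.i.d. per-straw noise (`sd_within`, default 5%), clamping to
[0, 100] applied last. The shared bull effect is what makes the relative
metric variance-reducing *by construction*, mirroring its purpose of
controlling for individual bull variability. No per-straw variance
estimates exist upstream, so the defaults are free parameters chosen once:
they give per-generation SDs of bull-pooled motilities around 7–12%,
consistent with the mid-campaign range of reported generation SDs
(≈3–17%), and sit between the "significant within and among animal
variability" extremes a production herd shows. Deliberate simplifications,
hence limits of what passing tests show about real data:

* noise is homoscedastic and Gaussian per straw — real motility counts are
  bounded percentages with skewed, formulation-dependent error;
* bull effects are exchangeable draws — real herds have structured
  (seasonal, genetic) bull covariance and repeated ejaculates;
* truncation is by clamping, not resampling — negligible bias at the
  default SDs but visible if SDs are pushed far higher;
* the declining generation SDs seen late in a real campaign are treated as
  population convergence, not heteroscedastic measurement error;
* no mechanistic cryobiology (osmolality, ice formation, CASA imaging) is
  modelled; kinetic/cytometry fields exist only as data schema.

## 6. The campaign loop

`run_campaign()` wires the pieces together with the study's protocol:
generation 0 is the evaluated LHS population; each later generation
proposes trials, screens them (from the coupling generation), assays 8
extenders × 4 fresh bulls × 3 straws plus the split-sample control, scores
under the scheduled metric (total motility through generation 17, relative
from 18), and applies pooled selection. NGF is removed at generation 19 by
default (`removals`), freezing its column at 0. Re-testing protocols
(holdout re-tests of earlier top performers) are supported by scoring
externally supplied records rather than hard-coded as an algorithm step.

* **Scoring unit** for selection is the per-formulation *median* across
  bulls of per-bull pooled values — robust to the long-tailed bull
  variability the campaign is designed around; the mean is a config
  alternative.
* **Convergence** is declared when the Kruskal–Wallis omnibus across the
  last 3 generations' 32-value motility samples has p ≥ 0.05, checked from
  generation 21 (the protocol's own convergence window) — earlier checks
  would mistake early noisy plateaus for convergence; a generation cap
  (default 21) always applies and can be the sole stop
  (`check_convergence = FALSE`).
* **Budget invariant**: tested formulations per generation never exceed
  the population size regardless of oversampling, because screening
  happens before the assay.
* **Reproducibility**: every stochastic stage seeds R's generator from
  `substream_seed(seed, generation, stage)`; ledgers are therefore
  byte-identical across re-runs *and* across resume-from-prefix, which the
  test suite checks at the file level.
* **External mode** (`ingest_external()`) validates real-lab records
  (schema, [0,100] range with offending row numbers, coverage of every
  proposed formulation, control records per bull) before they enter the
  ledger.
* **Generation-vs-control equivalence** in the final report compares the
  32 bull-pooled treatment values with the 4 per-bull control values
  (m = 32, n = 4); whether the upstream protocol pooled differently is not
  recoverable, and both pooling modes are reachable through the exported
  statistics functions.

## 7. Problem sizes used by the tests

The suite exercises the full loop at the study's own scale: 8 formulations
× 4 bulls × 3 straws per generation; a 20-generation noiseless campaign
for optimum recovery (the package recovers ≥95% of the benchmark optimum
there, asserted in `test-acceptance.R`); ten 21-generation campaigns under
default noise for the top-5 recovery property; 2000 simulations at
m = n = 32 for the equivalence test's size at its margin; and 100–200
random fixtures for the brute-force statistical oracles. DE oracle replays
run at populations 4–8 in 2–11 dimensions. These sizes are the package's
chosen verification scale; all are generated in code at test time.

## 8. Known limitations

* The virtual lab is a calibration target, not a cryobiological model;
  conclusions about real extender chemistry require the external-ingest
  mode and real assays.
* The network reports no predictive uncertainty (`predict_sd()` is `NA`
  for it); only the GP can feed uncertainty-aware acquisition, and only
  greedy-mean screening is implemented.
* Under the late-campaign reference jitter, harmful components are
  repeatedly re-injected at up to 10% of their reference value; when their
  motility cost at such doses is below the assay noise floor, trace
  amounts can persist in highly-ranked media — the optimizer finds the
  optimum's *value* long before it purges the last traces of a weakly
  harmful component.
* Classic per-index DE selection, alternative DE strategies and
  self-adaptive F/CR are out of scope; only `rand/1/bin` (with the pooled
  selection used by the campaign) is provided.
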