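# cryoevolve

Closed-loop, machine-learning-guided optimization of bull sperm
cryopreservation extender media.

## The problem

Post-thaw sperm recovery depends on a medium ("extender") with many
interacting components — buffer, membrane stabilizers (egg yolk, milk),
permeating cryoprotectants (glycerol, ethylene glycol), sugars (fructose,
trehalose), cholesterol-loaded cyclodextrin, and antioxidants (glutathione,
melatonin, nerve growth factor). A 3-level factorial screen over 11 such
components would need 3^11 = 177,147 treatment combinations, infeasible in
animals whose post-thaw recovery varies strongly both among and within
bulls. `cryoevolve` implements the alternative: an iterative campaign where
a differential-evolution optimizer proposes a small batch of candidate
extenders each generation, a split-sample assay scores them against a
commercial control, and a regression surrogate of post-thaw motility screens
candidates before they reach the (costly) assay.

The package is for reproductive-cryobiology groups running such campaigns
(the external-ingest mode consumes real CASA motility ledgers) and for
methods work on surrogate-assisted experimental design: a configurable
"virtual lab" — a ground-truth motility response surface plus an
among-/within-bull noise model — stands in for all wet-lab measurement, so
the entire closed loop is testable and exactly reproducible.

## What is inside

* **Formulation space** (`extender_space()`, `load_space()`,
  `validate_formulation()`, `clip_to_bounds()`, `to_recipe()`): the
  11-component design space with published concentration ranges, plus batch
  recipe conversion and the constant control extender.
* **Optimizer** (`init_population()`, `mutate_rand_1_bin()`,
  `select_top()`): DE/rand/1/bin with mutation factor *F* = 0.9 and
  crossover rate *CR* = 0.5. Each trial coordinate is
  `x_r3 + F (x_r1 − x_r2)` with probability *CR* (donors r1, r2, r3
  mutually distinct from the target); after generation 10 every mutated
  coordinate also receives `ref × U(−10%, +10%)` jitter to re-inflate
  variation. Survivors are the top-N of parents ∪ trials, pooled.
* **Surrogates** (`fit_ann()`, `fit_gpr()`, `kfold_cv()`,
  `compare_models()`, `screen_candidates()`): a 12–12–1 rectified-linear
  network (L2 = 1e-4, MSE loss) and an anisotropic squared-exponential
  Gaussian process with observation noise, compared by ten-fold
  cross-validated MSE, Kruskal–Wallis/Dunn location tests and
  Fligner–Killeen spread tests against experimental motility; the selected
  model screens oversampled DE trial pools down to the 8-extender
  experimental batch from generation 7 onward.
* **Equivalence statistics** (`mann_whitney_equivalence()`,
  `kruskal_wallis()`, `dunn_posthoc()`, `fligner_killeen()`): Wellek's
  Mann–Whitney test for equivalence. With samples x (m) and y (n),

      W+ = (1 / mn) Σᵢ Σⱼ [ 1{xᵢ > yⱼ} + ½·1{xᵢ = yⱼ} ]

  estimates P(X > Y); its U-statistic standard error σ̂ and the
  noncentral-χ² critical bound `CRIT = sqrt(χ²₁;α((ε̄/σ̂)²))` give the
  decision `REJ = 1 ⇔ |W+ − ½| / σ̂ < CRIT` at the symmetric margin
  ε̄ = 0.15 — the null hypothesis is *non*-equivalence.
* **Campaign orchestration** (`campaign_config()`, `run_campaign()`,
  `run_generation()`, `rank_top_media()`, `write_ledgers()`): the full
  generation loop with the study's metric schedule (total motility through
  generation 17, relative total motility — treatment/control per bull —
  thereafter), scheduled component removals (NGF at generation 19),
  plateau-based convergence testing, CSV ledgers that are byte-identical
  under a fixed seed (including resume-from-prefix), and external-lab
  ingest with validation.

## Worked example

An eight-generation virtual campaign with the default benchmark surface
(control extender ≈ 68% true motility, global optimum 91%):

```r
library(cryoevolve)
cfg <- campaign_config(seed = 1, max_generations = 8)
report <- run_campaign(cfg)
report
#> Campaign finished at generation 8 (generation cap)
#>  generation metric n_pairs   median        sd control_median best_score
#>           0  total      32 57.60637  7.025168       71.38804   66.31169
#>           1  total      32 52.51844 12.664408       67.65794   68.13083
#>           ...
#>           7  total      32 82.13068  9.559335       70.07932   86.17086
#>           8  total      32 80.99174  5.824841       67.72837   86.17086
#>
#> Top media (by mean relative total motility):
#>  formulation_id mean_relative mean_total mean_control
#>         g08_t04      1.236275   85.41535     69.26459
#>         ...
#> Top-5 vs control: 84.3% vs 69.6% (21.2% improvement)
```

Each row is one generation: 32 formulation–bull motility pairs (8 extenders
× 4 bulls, straws in triplicate) plus the split-sample control; the median
climbs from ~53% toward the surface optimum while `best_score` (elitist
best pooled score) never decreases. From generation 7 the `model_tag`
column records which surrogate screened the candidates.

The equivalence test prints the same tuple the campaign reports use:

```r
set.seed(42)
gen21 <- rnorm(32, 66, 8); control <- rnorm(4, 65, 6)
mann_whitney_equivalence(gen21, control, equivalence_config())
#> Mann-Whitney equivalence test: m = 32, n = 4, eps = (-0.15, 0.15)
#>   W+ = 0.6094, sigma_hat = 0.1280, CRIT = 0.1244, REJ = 0
#>   (non-equivalence not rejected)
```

The virtual lab's optimum is exposed for benchmarking:

```r
s <- extender_space()
surface_argmax(benchmark_surface(s), s)$value
#> [1] 91
```

## Documentation

See the methods vignette
(`vignettes/closed-loop-extender-optimization.Rmd`) for the model and
procedure details, the virtual-lab assumptions, and known limitations.
A thin command-line front end lives at `inst/cli/extender_campaign.R`
(`simulate` / `run` / `stats`).
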