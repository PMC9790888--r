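test_that("the exposed argmax maximizes the noiseless surface", {
  s <- extender_space()
  surf <- benchmark_surface(s)
  am <- surface_argmax(surf, s)
  expect_length(validate_formulation(am$formulation, s), 0)
  conc <- stats::setNames(am$formulation$concentrations, component_names(s))
  expect_equal(unname(conc["ethylene_glycol"]), 0)
  expect_equal(unname(conc["ngf"]), 0)
  # dense grid search over all 2-component slices through the argmax never
  # beats the exposed maximum
  act <- which(s$components$active)
  for (pair in list(c("glycerol", "ethylene_glycol"),
                    c("tris", "egg_yolk"), c("trehalose", "fructose"),
                    c("milk", "ngf"), c("clc", "melatonin"))) {
    i <- match(pair[1], component_names(s))
    j <- match(pair[2], component_names(s))
    g1 <- seq(s$components$lower[i], s$components$upper[i], length.out = 61)
    g2 <- seq(s$components$lower[j], s$components$upper[j], length.out = 61)
    grid <- expand.grid(a = g1, b = g2)
    X <- matrix(rep(am$formulation$concentrations, each = nrow(grid)),
                nrow = nrow(grid))
    colnames(X) <- component_names(s)
    X[, i] <- grid$a; X[, j] <- grid$b
    expect_lte(max(true_motility(X, surf, s)), am$value + 1e-5)
  }
})

test_that("the surface encodes the campaign's qualitative biology", {
  s <- extender_space()
  surf <- benchmark_surface(s)
  am <- surface_argmax(surf, s)
  best <- am$formulation$concentrations
  # adding ethylene glycol to the argmax strictly decreases motility
  with_eg <- best
  with_eg[match("ethylene_glycol", component_names(s))] <- 2
  expect_lt(true_motility(with_eg, surf, s), am$value)
  # the NGF penalty is exactly linear: slope * dose
  ngf_idx <- match("ngf", component_names(s))
  with_ngf <- best
  with_ngf[ngf_idx] <- 0.4
  slope <- surf$penalties$slope[surf$penalties$name == "ngf"]
  expect_equal(true_motility(with_ngf, surf, s) - am$value, slope * 0.4)
  # the control extender sits in the observed 60-70% band
  ctl <- true_motility(control_extender(s), surf, s)
  expect_gt(ctl, 60); expect_lt(ctl, 70)
  # dropping fructose entirely costs almost nothing (dispensable component)
  no_fruc <- best
  no_fruc[match("fructose", component_names(s))] <- 0
  expect_lt(am$value - true_motility(no_fruc, surf, s), 2)
})

test_that("noiseless assays reproduce the surface exactly and are seeded", {
  s <- extender_space()
  surf <- benchmark_surface(s)
  cfg <- de_config(seed = 5)
  pop <- init_population(s, cfg)
  quiet <- noise_model(0, 0)
  set.seed(9); bulls <- make_bulls(4, quiet)
  set.seed(10)
  recs <- simulate_assay(pop, bulls, 3, surf, s, quiet, generation = 1)
  mu <- true_motility(pop, surf, s)
  for (k in seq_len(8)) {
    got <- recs$total_motility[recs$formulation_id == pop$id[k]]
    expect_equal(got, rep(mu[k], 12))
  }
  # determinism: identical ledger under an identical stream
  set.seed(10)
  recs2 <- simulate_assay(pop, bulls, 3, surf, s, quiet, generation = 1)
  expect_identical(recs, recs2)
})

test_that("assays have the study shape: 8 x 4 bulls = 32 pooled pairs", {
  s <- extender_space()
  surf <- benchmark_surface(s)
  pop <- init_population(s, de_config(seed = 2))
  set.seed(1); bulls <- make_bulls(4)
  recs <- simulate_assay(pop, bulls, 3, surf, s, noise_model(),
                         generation = 1)
  trt <- recs[recs$formulation_id != "control", ]
  expect_equal(nrow(trt), 8 * 4 * 3)
  pooled <- pooled_metric_values <- unique(trt[, c("formulation_id", "bull_id")])
  expect_equal(nrow(pooled), 32)
  # control present for every bull, replicate-matched
  ctl <- recs[recs$formulation_id == "control", ]
  expect_equal(nrow(ctl), 4 * 3)
  expect_setequal(unique(ctl$bull_id), unique(trt$bull_id))
  expect_true(all(recs$total_motility >= 0 & recs$total_motility <= 100))
})

test_that("bull effects are shared between treatment and control straws", {
  s <- small_space()
  surf <- small_surface()
  f <- population(matrix(c(5, 40, 0.5), nrow = 1,
                         dimnames = list(NULL, component_names(s))),
                  id = "f1")
  ctl <- formulation(c(5, 40, 0.5), id = "control", provenance = "control")
  nm <- noise_model(sd_bull = 20, sd_within = 0)
  set.seed(33); bulls <- make_bulls(6, nm)
  recs <- simulate_assay(f, bulls, 2, surf, s, nm, control = ctl)
  # same formulation as control, no within-straw noise: ratio exactly 1
  trt <- recs[recs$formulation_id == "f1", ]
  expect_equal(trt$total_motility, trt$control_motility)
  expect_true(stats::sd(trt$total_motility) > 0)  # bull effect is there
})

test_that("assay means converge to the true surface value", {
  s <- small_space()
  surf <- small_surface()
  f <- population(matrix(c(3, 20, 0.5), nrow = 1,
                         dimnames = list(NULL, component_names(s))),
                  id = "f1")
  ctl <- formulation(c(5, 40, 0.5), id = "control", provenance = "control")
  nm <- noise_model(sd_bull = 0, sd_within = 6)
  set.seed(44)
  bulls <- make_bulls(1, nm)
  recs <- simulate_assay(f, bulls, 4000, surf, s, nm, control = ctl)
  vals <- recs$total_motility[recs$formulation_id == "f1"]
  mu <- true_motility(f, surf, s)
  se <- 6 / sqrt(4000)
  expect_lt(abs(mean(vals) - mu), 3 * se)
})

test_that("study fixtures have the campaign ledger schema and counts", {
  s <- extender_space()
  fx <- make_study_fixture(5, surface = benchmark_surface(s), space = s,
                           seed = 3)
  trt <- fx$motility[fx$motility$formulation_id != "control", ]
  pairs <- unique(trt[, c("generation", "formulation_id", "bull_id")])
  expect_equal(nrow(pairs), 5 * 8 * 4)
  expect_equal(nrow(fx$formulations), 5 * 8)
  expect_true(all(c("generation", "formulation_id", "provenance",
                    component_names(s)) %in% names(fx$formulations)))
  # controls exist for every (generation, bull)
  ctl <- fx$motility[fx$motility$formulation_id == "control", ]
  expect_equal(nrow(unique(ctl[, c("generation", "bull_id")])), 20)
  # empty fixture keeps headers
  fx0 <- make_study_fixture(0, space = s)
  expect_equal(nrow(fx0$motility), 0)
  expect_true(all(c("total_motility", "control_motility") %in%
                    names(fx0$motility)))
  # reproducible under the same seed
  fx2 <- make_study_fixture(5, surface = benchmark_surface(s), space = s,
                            seed = 3)
  expect_identical(fx, fx2)
})
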