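fast_cfg <- function(seed = 1, ...) {
  campaign_config(seed = seed,
                  surrogate = surrogate_config(epochs = 400,
                                               gpr_restarts = 1,
                                               seed = seed),
                  ...)
}

test_that("one generation tests 8 formulations plus control, 32 pairs", {
  cfg <- fast_cfg(seed = 11, max_generations = 2, surrogate_start = 99)
  st <- init_campaign(cfg)
  st <- run_generation(st)
  g1 <- st$motility[st$motility$generation == 1, ]
  trt <- g1[g1$formulation_id != "control", ]
  expect_equal(length(unique(trt$formulation_id)), 8)
  expect_equal(nrow(unique(trt[, c("formulation_id", "bull_id")])), 32)
  expect_equal(nrow(trt), 96)  # triplicate straws
  ctl <- g1[g1$formulation_id == "control", ]
  expect_equal(nrow(ctl), 12)
  # ledger includes the control row among tested formulations
  forms1 <- st$formulations[st$formulations$generation == 1, ]
  expect_true("control" %in% forms1$formulation_id)
  expect_equal(nrow(forms1), 9)
})

test_that("the tested batch never exceeds the population size even when
           oversampling for the surrogate", {
  cfg <- fast_cfg(seed = 12, max_generations = 3, surrogate_start = 3,
                  check_convergence = FALSE)
  st <- init_campaign(cfg)
  for (g in 1:3) st <- run_generation(st)
  for (g in 0:3) {
    recs <- st$motility[st$motility$generation == g &
                          st$motility$formulation_id != "control", ]
    expect_lte(length(unique(recs$formulation_id)), 8)
  }
  # surrogate was active: predictions ledger is non-empty from gen 3
  expect_true(all(st$predictions$generation >= 3))
  expect_equal(nrow(st$predictions), 8)
  expect_true(all(st$predictions$model_tag %in% c("ann", "gpr")))
})

test_that("campaign ledgers are byte-identical under a fixed seed and under
           resume-from-prefix", {
  cfg <- fast_cfg(seed = 13, max_generations = 4, surrogate_start = 3,
                  check_convergence = FALSE)
  full1 <- resume_campaign(init_campaign(cfg), max_generations = 4)
  full2 <- resume_campaign(init_campaign(cfg), max_generations = 4)
  # stop after 2 generations, then resume to 4
  st <- init_campaign(cfg)
  st <- run_generation(st); st <- run_generation(st)
  resumed <- resume_campaign(st, max_generations = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  write_ledgers(full1, d1); write_ledgers(full2, d2)
  write_ledgers(resumed, d3)
  for (f in c("formulations.csv", "motility.csv", "predictions.csv",
              "summary.csv")) {
    ref <- readBin(file.path(d1, f), "raw",
                   file.info(file.path(d1, f))$size)
    expect_identical(readBin(file.path(d2, f), "raw", length(ref) + 10),
                     ref, label = paste("rerun", f))
    expect_identical(readBin(file.path(d3, f), "raw", length(ref) + 10),
                     ref, label = paste("resume", f))
  }
})

test_that("every ledgered formulation validates against the space", {
  cfg <- fast_cfg(seed = 14, max_generations = 2, surrogate_start = 99)
  st <- init_campaign(cfg)
  st <- run_generation(st); st <- run_generation(st)
  comp <- component_names(st$space)
  for (i in seq_len(nrow(st$formulations))) {
    f <- formulation(as.numeric(st$formulations[i, comp]))
    expect_length(validate_formulation(f, st$space), 0)
  }
})

test_that("the metric schedule switches scoring to relative motility", {
  cfg <- fast_cfg(seed = 15, max_generations = 3, surrogate_start = 99,
                  metric_relative_from = 2, check_convergence = FALSE)
  st <- init_campaign(cfg)
  for (g in 1:3) st <- run_generation(st)
  expect_equal(st$summary$metric, c("total", "total", "relative",
                                    "relative"))
  # relative medians sit near 1, total medians near the motility scale
  expect_lt(max(st$summary$median[st$summary$metric == "relative"]), 3)
  expect_gt(min(st$summary$median[st$summary$metric == "total"]), 10)
})

test_that("scheduled component removal zeroes the column and helps on a
           surface that penalizes it", {
  cfg <- fast_cfg(seed = 16, max_generations = 4, surrogate_start = 99,
                  removals = list("3" = "ngf"),
                  check_convergence = FALSE,
                  lab = list(mode = "virtual", noise = noise_model(0, 0)))
  st <- init_campaign(cfg)
  for (g in 1:4) st <- run_generation(st)
  post <- st$formulations[st$formulations$generation >= 3 &
                            st$formulations$provenance == "mutant", ]
  expect_true(all(post$ngf == 0))
  expect_false(st$space$components$active[
    st$space$components$name == "ngf"])
  # noiseless: the post-removal tested batch beats the pre-removal one
  expect_gt(st$summary$median[st$summary$generation == 4],
            st$summary$median[st$summary$generation == 2])
})

test_that("external records are validated before ingestion", {
  s <- extender_space()
  pop <- init_population(s, de_config(seed = 17), generation = 1)
  good <- data.frame(
    generation = 1,
    formulation_id = rep(c(pop$id, "control"), each = 2),
    bull_id = rep(c("b1", "b2"), 9),
    replicate = 1,
    total_motility = stats::runif(18, 30, 70),
    control_motility = 55)
  expect_silent(ingest_external(good, pop))
  bad_range <- good
  bad_range$total_motility[4] <- 104
  expect_error(ingest_external(bad_range, pop), "row\\(s\\) 4")
  missing_form <- good[good$formulation_id != pop$id[3], ]
  expect_error(ingest_external(missing_form, pop), pop$id[3])
  no_ctrl <- good[good$formulation_id != "control", ]
  expect_error(ingest_external(no_ctrl, pop), "control records")
  expect_error(ingest_external(good[, -4], pop), "missing column")
})

test_that("top-media ranking orders by mean relative motility and reports
           the percent improvement", {
  recs <- data.frame(
    generation = 1,
    formulation_id = rep(c("good", "mid", "weak"), each = 4),
    bull_id = rep(c("b1", "b2"), 6),
    replicate = rep(1:2, 6),
    total_motility = c(72, 70, 71, 69,  60, 62, 61, 59,  40, 42, 41, 39),
    control_motility = 50)
  top <- rank_top_media(recs, k = 2)
  expect_equal(top$summary$formulation_id, c("good", "mid"))
  expect_equal(top$summary$mean_relative[1], mean(c(71, 70)) / 50)
  expect_equal(top$mean_treatment, mean(c(70.5, 60.5)))
  expect_equal(top$improvement_pct,
               100 * (mean(c(70.5, 60.5)) / 50 - 1))
  expect_warning(rank_top_media(recs, k = 5), "3 scored")
  # the published validation arithmetic: 31.9% vs 25.2% -> 26.6%
  expect_equal(round(percent_improvement(31.9, 25.2), 1), 26.6)
  expect_equal(percent_improvement(50, 50), 0)
})

test_that("campaign reports expose the trajectory and control comparison", {
  cfg <- fast_cfg(seed = 18, max_generations = 3, surrogate_start = 99,
                  check_convergence = FALSE)
  rep <- run_campaign(cfg)
  expect_s3_class(rep, "campaign_report")
  expect_equal(nrow(rep$summary), 4)  # generations 0-3
  expect_equal(nrow(rep$top_media$summary), 5)
  expect_s3_class(rep$control_comparison, "equivalence_result")
  expect_true(all(c("median", "sd", "control_median") %in%
                    names(rep$summary)))
})

test_that("campaign configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 42",
    "max_generations: 5",
    "metric_relative_from: 4",
    "surrogate_start: 3",
    "de:",
    "  population_size: 6",
    "  F: 0.9",
    "  CR: 0.5",
    "surrogate:",
    "  epochs: 300",
    "noise:",
    "  sd_bull: 4",
    "  sd_within: 2"), path)
  cfg <- load_campaign_config(path)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$de$population_size, 6L)
  expect_equal(cfg$surrogate$epochs, 300L)
  expect_equal(cfg$lab$noise$sd_bull, 4)
  expect_equal(cfg$metric_relative_from, 4L)
})
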