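# Naive GP posterior oracle: plain solve() on dense matrices, independent of
# the implementation's Cholesky path.
oracle_gp_posterior <- function(model, Xnew) {
  X <- model$X
  k <- function(a, b) {
    model$sf2 * exp(-0.5 * sum(((a - b) / model$ell)^2))
  }
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- k(X[i, ], X[j, ])
  K <- K + diag(model$sn2 + 1e-10, n)
  yt <- drop(K %*% model$alpha)  # reconstruct standardized targets
  Kinv_y <- solve(K, yt)
  mean_out <- numeric(nrow(Xnew)); sd_out <- numeric(nrow(Xnew))
  for (q in seq_len(nrow(Xnew))) {
    ks <- vapply(1:n, function(i) k(X[i, ], Xnew[q, ]), numeric(1))
    mean_out[q] <- model$mu + model$sdy * sum(ks * Kinv_y)
    v <- model$sf2 - drop(crossprod(ks, solve(K, ks)))
    sd_out[q] <- model$sdy * sqrt(max(v, 0) + model$sn2)
  }
  list(mean = mean_out, sd = sd_out)
}

test_that("featurization scales by bounds and appends the water fraction", {
  s <- extender_space()
  f <- formulation(c(50, 0, 0, 0, 7, 0, 0, 0.5, 0.5, 2, 0))
  z <- featurize(f, s)
  expect_equal(ncol(z), 12)
  expect_equal(unname(z[1, "glycerol"]), 1)       # upper bound -> 1
  expect_equal(unname(z[1, "tris"]), 1)
  expect_equal(unname(z[1, "glutathione"]), 0)    # degenerate bounds -> 0
  expect_equal(unname(z[1, "water_fraction"]), 1 - (50 + 7) / 100)
  lows <- formulation(c(0, 0, 0, 0, 0, 0, 0, 0.5, 0.5, 2, 0))
  zl <- featurize(lows, s)
  expect_true(all(zl[1, 1:11] == 0))
  expect_equal(unname(zl[1, "water_fraction"]), 1)  # maximal filler
})

test_that("featurize/defeaturize round-trips active components", {
  s <- extender_space()
  pop <- init_population(s, de_config(seed = 31))
  Z <- featurize(pop, s)
  X <- defeaturize(Z, s)
  expect_equal(unname(X), unname(pop$X), tolerance = 1e-12)
})

test_that("the network matches its stated topology and learns a clean target", {
  s <- extender_space()
  set.seed(71)
  pop <- init_population(s, de_config(population_size = 60, seed = 71))
  X <- featurize(pop, s)
  y <- 20 + 30 * X[, "glycerol"] + 15 * X[, "egg_yolk"] - 10 * X[, "ngf"]
  cfg <- surrogate_config(seed = 4)
  model <- fit_ann(X, y, cfg)
  expect_equal(topology(model), c(12, 12, 1))
  expect_lt(mean((predict(model, X) - y)^2), 1.0)
  # fixed seed: refitting reproduces identical predictions
  model2 <- fit_ann(X, y, cfg)
  expect_identical(predict(model, X), predict(model2, X))
  expect_error(fit_ann(X[0, , drop = FALSE], numeric(0)), "no training")
})

test_that("the GP interpolates with a tiny noise floor and matches a naive
           posterior oracle", {
  set.seed(81)
  X <- matrix(stats::runif(40), ncol = 2)
  y <- 50 + 20 * sin(3 * X[, 1]) + 10 * X[, 2]
  near_zero <- surrogate_config(gpr_noise = 1e-6, gpr_restarts = 1, seed = 2)
  model <- fit_gpr(X, y, near_zero)
  expect_lt(max(abs(predict(model, X) - y)), 1e-4)
  # posterior algebra agrees with a from-scratch solve() implementation
  Xnew <- matrix(stats::runif(10), ncol = 2)
  noisy <- fit_gpr(X, y + stats::rnorm(20, 0, 2),
                   surrogate_config(seed = 2))
  mine <- predict(noisy, Xnew, se.fit = TRUE)
  oracle <- oracle_gp_posterior(noisy, Xnew)
  expect_equal(mine$fit, oracle$mean, tolerance = 1e-8)
  expect_equal(mine$se.fit, oracle$sd, tolerance = 1e-8)
})

test_that("GP predictive uncertainty grows away from the training hull", {
  set.seed(82)
  X <- matrix(stats::runif(60, 0.3, 0.7), ncol = 2)
  y <- 40 + 25 * X[, 1] + stats::rnorm(30, 0, 2)
  model <- fit_gpr(X, y, surrogate_config(seed = 3))
  sd_in <- mean(predict_sd(model, X))
  far <- matrix(c(3, 3, -2, 4, 5, -1), ncol = 2, byrow = TRUE)
  sd_out <- predict_sd(model, far)
  expect_true(all(sd_out > sd_in))
  # duplicated feature rows (replicate bulls) are pooled, not an error
  Xd <- rbind(X, X)
  yd <- c(y, y + stats::rnorm(30, 0, 2))
  expect_silent(fit_gpr(Xd, yd, surrogate_config(seed = 3)))
})

test_that("k-fold CV partitions the data and averages fold MSEs", {
  set.seed(91)
  X <- matrix(stats::runif(60), ncol = 2)
  y <- 10 + 5 * X[, 1]
  cfg <- surrogate_config(cv_folds = 10, seed = 6)
  oracle_factory <- function(Xtr, ytr) {
    structure(list(), class = "oracle_model")
  }
  assign("predict.oracle_model",
         function(object, newdata, ...) 10 + 5 * as.matrix(newdata)[, 1],
         envir = globalenv())
  on.exit(rm("predict.oracle_model", envir = globalenv()), add = TRUE)
  cv <- kfold_cv(oracle_factory, X, y, cfg, model_tag = "oracle")
  expect_equal(cv$mean_mse, 0)
  expect_length(cv$fold_mse, 10)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(tabulate(cv$folds), rep(3, 10))  # disjoint cover of 30 pairs
  expect_equal(cv$mean_mse, mean(cv$fold_mse))
  # hand-enumerated two-point case with a constant-mean learner:
  # each fold predicts the other point's value -> squared errors 400, 400
  const_factory <- function(Xtr, ytr) {
    structure(list(m = mean(ytr)), class = "const_model")
  }
  assign("predict.const_model",
         function(object, newdata, ...) rep(object$m, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  cv2 <- kfold_cv(const_factory, matrix(c(0, 1), ncol = 1), c(40, 60),
                  surrogate_config(cv_folds = 2, seed = 1), "const")
  expect_equal(sort(cv2$fold_mse), c(400, 400))
  expect_equal(cv2$mean_mse, 400)
  expect_error(kfold_cv(const_factory, matrix(1:3, ncol = 1), 1:3,
                        surrogate_config(cv_folds = 10)), "folds")
})

test_that("model selection flags heteroscedastic predictions and is
           symmetric under relabeling", {
  set.seed(101)
  experimental <- stats::rnorm(32, 50, 15)
  narrow <- stats::rnorm(32, 50, 3)    # one fifth the experimental spread
  matched <- stats::rnorm(32, 50, 15)
  rep1 <- compare_models(narrow, matched, experimental,
                         tags = c("narrow", "matched"))
  expect_lt(rep1$fligner$narrow$p_value, 0.05)
  expect_gt(rep1$fligner$matched$p_value, 0.05)
  expect_identical(rep1$selected, "matched")
  # relabeling the two models does not change which predictions win
  rep2 <- compare_models(matched, narrow, experimental,
                         tags = c("matched", "narrow"))
  expect_identical(rep2$selected, "matched")
  # identical prediction sets carry no signal: falls back to CV MSE
  cv <- list(a = structure(list(mean_mse = 100), class = "cv_result"),
             b = structure(list(mean_mse = 200), class = "cv_result"))
  rep3 <- compare_models(matched, matched, experimental,
                         tags = c("a", "b"), cv = cv)
  expect_identical(rep3$selected, "a")
  expect_match(rep3$reason, "MSE")
  expect_error(compare_models(narrow[1:5], matched, experimental),
               "aligned")
})

test_that("the selection pathway reproduces the campaign outcome on a
           variance-faithful virtual fixture", {
  # GP-style predictions track experimental dispersion; network-style
  # predictions compress it; the rule must pick the former
  s <- extender_space()
  fx <- make_study_fixture(2, surface = benchmark_surface(s), space = s,
                           seed = 9)
  vals <- cryoevolve:::pooled_metric_values(
    fx$motility[fx$motility$formulation_id != "control", ], "total")
  experimental <- vals$value
  set.seed(102)
  gpr_like <- experimental + stats::rnorm(length(experimental), 0, 4)
  ann_like <- mean(experimental) +
    0.2 * (experimental - mean(experimental)) +
    stats::rnorm(length(experimental), 0, 1)
  rep <- compare_models(ann_like, gpr_like, experimental,
                        tags = c("ann", "gpr"))
  expect_identical(rep$selected, "gpr")
})

test_that("surrogate screening keeps the predicted-best candidates and
           improves the tested batch", {
  s <- extender_space()
  surf <- benchmark_surface(s)
  set.seed(111)
  train_pop <- init_population(s, de_config(population_size = 80))
  Xtr <- featurize(train_pop, s)
  ytr <- true_motility(train_pop, surf, s) +
    stats::rnorm(80, 0, 3)
  model <- fit_gpr(Xtr, ytr, surrogate_config(seed = 5))
  cand <- init_population(s, de_config(population_size = 64), generation = 1)
  screened <- screen_candidates(model, cand, 8, s)
  expect_length(screened, 8)
  # k = all candidates is the identity up to ordering
  all_kept <- screen_candidates(model, cand, 64, s)
  expect_setequal(all_kept$id, cand$id)
  # kept ids are exactly the top-k by prediction
  preds <- predict(model, featurize(cand, s))
  expect_setequal(screened$id, cand$id[order(-preds)][1:8])
  # screened batches are truly better than unscreened at matched budget
  unscreened_mean <- mean(true_motility(
    cand$X[1:8, , drop = FALSE], surf, s))
  screened_mean <- mean(true_motility(screened, surf, s))
  expect_gt(screened_mean, unscreened_mean)
  expect_error(screen_candidates(model, cand, 100, s), "fewer candidates")
  expect_error(screen_candidates(list(), cand, 8, s), "fitted surrogate")
})
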