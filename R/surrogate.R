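#' Surrogate-model configuration
#'
#' Both post-thaw-motility surrogates are configured here: a feed-forward
#' network with 12 inputs (11 design variables plus the water filler
#' fraction), one hidden layer of 12 rectified-linear units, one linear
#' output, L2 penalty 1e-4 and mean-squared-error loss; and a Gaussian
#' process with an anisotropic squared-exponential kernel plus an
#' observation-noise term, fitted by marginal-likelihood optimization.
#' Ten-fold cross-validation scores both.
#'
#' @param input_dim number of model inputs.
#' @param hidden_units hidden-layer width of the network.
#' @param l2_penalty L2 regularization weight (>= 0).
#' @param cv_folds folds for cross-validation (>= 2).
#' @param epochs,learn_rate full-batch Adam budget for the network.
#' @param gpr_noise if not `NULL`, fixes the GP observation-noise SD (on the
#'   standardized-target scale) instead of optimizing it.
#' @param gpr_restarts seeded restarts for the marginal-likelihood
#'   optimization.
#' @param seed seed for initialization, fold assignment and restarts.
#' @return an object of class `surrogate_config`.
#' @export
surrogate_config <- function(input_dim = 12, hidden_units = 12,
                             l2_penalty = 1e-4, cv_folds = 10,
                             epochs = 2000, learn_rate = 0.01,
                             gpr_noise = NULL, gpr_restarts = 2,
                             seed = 1L) {
  if (input_dim < 1) stop("input_dim must be >= 1", call. = FALSE)
  if (l2_penalty < 0) stop("l2_penalty must be >= 0", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 activation = "relu", loss = "mse",
                 l2_penalty = l2_penalty, cv_folds = as.integer(cv_folds),
                 epochs = as.integer(epochs), learn_rate = learn_rate,
                 gpr_noise = gpr_noise,
                 gpr_restarts = as.integer(gpr_restarts),
                 seed = seed),
            class = "surrogate_config")
}

#' Encode formulations as surrogate features
#'
#' Each component is min-max scaled to `[0, 1]` by its design bounds
#' (degenerate bounds map to 0), and the water filler fraction — one minus
#' the summed volume fractions of the liquid (percent v/v) components — is
#' appended as the final input, giving 12 inputs for the 11-component
#' space.
#'
#' @param f a `formulation`, `population` or concentration matrix.
#' @param space a `formulation_space`.
#' @return numeric feature matrix, one row per formulation.
#' @export
featurize <- function(f, space = extender_space()) {
  X <- as_conc_matrix(f, space)
  Z <- normalize_columns(X, space)
  vv <- space$components$unit == "percent_vv"
  water <- 1 - rowSums(X[, vv, drop = FALSE]) / 100
  cbind(Z, water_fraction = pmax(water, 0))
}

#' Invert the feature encoding
#'
#' Recovers concentrations from scaled features (the water column is
#' dropped; degenerate-bound components return their frozen value), so that
#' `defeaturize(featurize(f))` round-trips active components to numerical
#' precision.
#'
#' @param Z feature matrix from [featurize()].
#' @param space a `formulation_space`.
#' @return concentration matrix in space units.
#' @export
defeaturize <- function(Z, space = extender_space()) {
  comp <- space$components
  Z <- as.matrix(Z)[, seq_len(n_components(space)), drop = FALSE]
  X <- Z
  for (j in seq_len(ncol(Z))) {
    rng <- comp$upper[j] - comp$lower[j]
    X[, j] <- if (rng > 0) comp$lower[j] + Z[, j] * rng else comp$reference[j]
  }
  colnames(X) <- comp$name
  X
}

# ---- feed-forward network -------------------------------------------------

relu <- function(x) pmax(x, 0)

#' Fit the feed-forward motility network
#'
#' Single-hidden-layer rectified-linear network (input `d`, hidden
#' `hidden_units`, one linear output) trained on standardized targets by
#' full-batch Adam under mean-squared-error loss with L2 penalty. He-scaled
#' initialization is seeded, so refits are bit-reproducible; training stops
#' at the epoch cap or when the loss plateaus.
#'
#' @param X feature matrix (rows = training pairs).
#' @param y motility targets \%.
#' @param cfg a `surrogate_config`.
#' @return a `surrogate_ann`; `predict()` returns mean motility,
#'   `topology()` reports the layer sizes, and `$history` the training-loss
#'   trace.
#' @export
fit_ann <- function(X, y, cfg = surrogate_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("no training pairs supplied", call. = FALSE)
  if (nrow(X) != length(y)) stop("features and targets must align",
                                 call. = FALSE)
  set.seed(cfg$seed)
  d <- ncol(X); h <- cfg$hidden_units; n <- nrow(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  yt <- matrix((y - mu) / sdy, ncol = 1)
  params <- list(W1 = matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h),
                 b1 = rep(0, h),
                 W2 = matrix(stats::rnorm(h, 0, sqrt(2 / h)), h, 1),
                 b2 = 0)
  m1 <- v1 <- lapply(params, function(p) p * 0)
  b1adam <- 0.9; b2adam <- 0.999; epsadam <- 1e-8
  lam <- cfg$l2_penalty
  history <- numeric(cfg$epochs)
  best <- Inf; stale <- 0L
  for (ep in seq_len(cfg$epochs)) {
    Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
    H <- relu(Z1)
    yhat <- H %*% params$W2 + params$b2
    r <- yhat - yt
    loss <- mean(r^2) + lam * (sum(params$W1^2) + sum(params$W2^2))
    history[ep] <- loss
    dyhat <- 2 * r / n
    grads <- list(
      W1 = crossprod(X, (dyhat %*% t(params$W2)) * (Z1 > 0)) +
        2 * lam * params$W1,
      b1 = colSums((dyhat %*% t(params$W2)) * (Z1 > 0)),
      W2 = crossprod(H, dyhat) + 2 * lam * params$W2,
      b2 = sum(dyhat))
    for (k in names(params)) {
      m1[[k]] <- b1adam * m1[[k]] + (1 - b1adam) * grads[[k]]
      v1[[k]] <- b2adam * v1[[k]] + (1 - b2adam) * grads[[k]]^2
      mh <- m1[[k]] / (1 - b1adam^ep)
      vh <- v1[[k]] / (1 - b2adam^ep)
      params[[k]] <- params[[k]] - cfg$learn_rate * mh / (sqrt(vh) + epsadam)
    }
    if (loss < best - 1e-9) { best <- loss; stale <- 0L } else {
      stale <- stale + 1L
      if (stale >= 200L) { history <- history[seq_len(ep)]; break }
    }
  }
  structure(list(params = params, mu = mu, sdy = sdy,
                 history = history, input_dim = d,
                 hidden_units = h, cfg = cfg, model_tag = "ann"),
            class = c("surrogate_ann", "surrogate_model"))
}

#' @export
predict.surrogate_ann <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Z1 <- sweep(X %*% object$params$W1, 2, object$params$b1, "+")
  yhat <- relu(Z1) %*% object$params$W2 + object$params$b2
  as.numeric(object$mu + object$sdy * yhat)
}

#' Report a network's layer topology
#'
#' @param model a fitted `surrogate_ann`.
#' @return integer vector `(inputs, hidden, outputs)`.
#' @export
topology <- function(model) {
  c(model$input_dim, model$hidden_units, 1L)
}

# ---- Gaussian process regression ------------------------------------------

sqexp_kernel <- function(X1, X2, ell, sf2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  D <- matrix(0, n1, n2)
  for (j in seq_len(ncol(X1))) {
    D <- D + (outer(X1[, j], X2[, j], "-") / ell[j])^2
  }
  sf2 * exp(-0.5 * D)
}

#' Fit the Gaussian-process motility surrogate
#'
#' Squared-exponential kernel with a length-scale per feature plus an
#' additive observation-noise term, on standardized targets. Hyperparameters
#' maximize the log marginal likelihood (analytic gradients, L-BFGS-B,
#' seeded restarts). Duplicate feature rows — replicate bulls measured on
#' the same formulation — are pooled by averaging their targets before
#' fitting. Unlike the network, the GP exposes a predictive standard
#' deviation: near the observation-noise level inside dense data, larger far
#' from the training hull.
#'
#' @param X feature matrix (>= 2 rows).
#' @param y motility targets \%.
#' @param cfg a `surrogate_config`; set `cfg$gpr_noise` to pin the noise SD
#'   (e.g. near 0 for an interpolating fit).
#' @return a `surrogate_gpr`; `predict()` takes `se.fit = TRUE` for
#'   predictive SDs.
#' @export
fit_gpr <- function(X, y, cfg = surrogate_config()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("features and targets must align",
                                 call. = FALSE)
  key <- apply(round(X, 10), 1, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    y <- as.numeric(tapply(y, key, mean)[unique(key)])
    X <- X[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 distinct training pairs", call. = FALSE)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  yt <- (y - mu) / sdy
  D2 <- lapply(seq_len(d), function(j) outer(X[, j], X[, j], "-")^2)
  fixed_noise <- cfg$gpr_noise
  n_par <- d + 1L + as.integer(is.null(fixed_noise))
  nll_grad <- function(theta) {
    ell <- exp(theta[seq_len(d)])
    sf2 <- exp(2 * theta[d + 1L])
    sn2 <- if (is.null(fixed_noise)) exp(2 * theta[d + 2L])
           else fixed_noise^2
    S <- Reduce(`+`, Map(function(D, l) D / l^2, D2, as.list(ell)))
    R <- exp(-0.5 * S)
    K <- sf2 * R + diag(sn2 + 1e-10, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(list(value = 1e10, grad = rep(0, n_par)))
    alpha <- backsolve(L, forwardsolve(t(L), yt))
    nll <- 0.5 * sum(yt * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(L)
    G <- tcrossprod(alpha) - Kinv       # d logL / dK = G / 2
    grad <- numeric(n_par)
    for (j in seq_len(d)) {
      dK <- sf2 * R * (D2[[j]] / ell[j]^2)
      grad[j] <- -0.5 * sum(G * dK)
    }
    grad[d + 1L] <- -0.5 * sum(G * (2 * sf2 * R))
    if (is.null(fixed_noise)) grad[d + 2L] <- -sum(diag(G)) * sn2
    list(value = nll, grad = grad)
  }
  set.seed(cfg$seed)
  inits <- list(c(rep(log(0.5), d), log(1), log(0.3)))
  if (cfg$gpr_restarts > 1) {
    for (r in seq_len(cfg$gpr_restarts - 1)) {
      inits[[r + 1]] <- c(stats::runif(d, log(0.1), log(2)),
                          stats::runif(1, log(0.5), log(2)),
                          stats::runif(1, log(0.05), log(1)))
    }
  }
  if (!is.null(fixed_noise)) inits <- lapply(inits, function(i) i[1:(d + 1)])
  best <- NULL
  for (init in inits) {
    fit <- stats::optim(init,
                        fn = function(t) nll_grad(t)$value,
                        gr = function(t) nll_grad(t)$grad,
                        method = "L-BFGS-B",
                        lower = rep(log(1e-3), n_par),
                        upper = rep(log(1e3), n_par),
                        control = list(maxit = 80))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(2 * theta[d + 1L])
  sn2 <- if (is.null(fixed_noise)) exp(2 * theta[d + 2L]) else fixed_noise^2
  K <- sqexp_kernel(X, X, ell, sf2) + diag(sn2 + 1e-10, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yt))
  structure(list(X = X, alpha = alpha, L = L, ell = ell, sf2 = sf2,
                 sn2 = sn2, mu = mu, sdy = sdy, nll = best$value,
                 cfg = cfg, model_tag = "gpr"),
            class = c("surrogate_gpr", "surrogate_model"))
}

#' @export
predict.surrogate_gpr <- function(object, newdata, se.fit = FALSE, ...) {
  Xn <- as.matrix(newdata)
  Ks <- sqexp_kernel(object$X, Xn, object$ell, object$sf2)
  mean_t <- crossprod(Ks, object$alpha)
  mean_y <- as.numeric(object$mu + object$sdy * mean_t)
  if (!se.fit) return(mean_y)
  V <- forwardsolve(t(object$L), Ks)
  var_lat <- pmax(object$sf2 - colSums(V^2), 0)
  sd_y <- object$sdy * sqrt(var_lat + object$sn2)
  list(fit = mean_y, se.fit = as.numeric(sd_y))
}

#' Predictive standard deviation
#'
#' Defined for the Gaussian-process surrogate; the network returns `NA`
#' (it carries no predictive-uncertainty estimate).
#'
#' @param model a fitted surrogate.
#' @param newdata feature matrix.
#' @return numeric vector of predictive SDs.
#' @export
predict_sd <- function(model, newdata) {
  if (inherits(model, "surrogate_gpr")) {
    predict(model, newdata, se.fit = TRUE)$se.fit
  } else {
    rep(NA_real_, nrow(as.matrix(newdata)))
  }
}

# ---- cross-validation and model selection ---------------------------------

#' K-fold cross-validation of a surrogate
#'
#' Seeded assignment into `cv_folds` disjoint folds covering every pair;
#' `model_factory(X, y)` fits on the training folds and is scored by
#' mean-squared error on the held-out fold; the fold MSEs are averaged. A
#' smaller average MSE indicates better model fitness.
#'
#' @param model_factory function of `(X, y)` returning a fitted model with a
#'   `predict` method.
#' @param X,y training pairs.
#' @param cfg a `surrogate_config` (supplies `cv_folds` and the fold seed).
#' @param model_tag label stored on the result.
#' @return a `cv_result`: `fold_mse` (length `cv_folds`), `mean_mse`,
#'   `model_tag`, and the fold assignment.
#' @export
kfold_cv <- function(model_factory, X, y, cfg = surrogate_config(),
                     model_tag = "model") {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- cfg$cv_folds
  if (k > n) stop("more folds than training pairs", call. = FALSE)
  set.seed(substream_seed(cfg$seed, 0L, "folds"))
  folds <- sample(rep_len(seq_len(k), n))
  fold_mse <- numeric(k)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- model_factory(X[!hold, , drop = FALSE], y[!hold])
    pred <- predict(model, X[hold, , drop = FALSE])
    fold_mse[f] <- mean((pred - y[hold])^2)
  }
  structure(list(fold_mse = fold_mse, mean_mse = mean(fold_mse),
                 model_tag = model_tag, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV [%s]: mean MSE = %.3f\n", length(x$fold_mse),
              x$model_tag, x$mean_mse))
  invisible(x)
}

#' Compare surrogate predictions against experimental motility
#'
#' Runs the evaluation battery on three aligned samples (two models'
#' predictions and the experimental motilities): Kruskal-Wallis omnibus,
#' pairwise Dunn post-hoc, per-model Fligner-Killeen spread comparison
#' against the experimental values, and per-model Mann-Whitney equivalence.
#' Selection rule: among models not significantly different in location
#' from the experiment (Dunn, unadjusted p >= alpha; all models if none
#' qualify), prefer the single model whose spread is homoscedastic with the
#' experiment (Fligner p >= alpha); otherwise fall back to the lower
#' cross-validated mean MSE when CV results are supplied. The rule is
#' symmetric under relabeling of the two models; with no signal at all the
#' selection is `NA`.
#'
#' @param preds_a,preds_b the two models' predictions (aligned).
#' @param experimental experimental motilities (same length).
#' @param tags length-2 labels for the two models.
#' @param cv optional named list of `cv_result`s (names matching `tags`).
#' @param eq_cfg an `equivalence_config` for the equivalence tests.
#' @param alpha level for the location/spread screens.
#' @return a `model_selection` report with every test and `selected`.
#' @export
compare_models <- function(preds_a, preds_b, experimental,
                           tags = c("ann", "gpr"), cv = NULL,
                           eq_cfg = equivalence_config(), alpha = 0.05) {
  if (length(preds_a) != length(experimental) ||
      length(preds_b) != length(experimental)) {
    stop("prediction and experimental samples must be aligned", call. = FALSE)
  }
  groups <- stats::setNames(list(experimental, preds_a, preds_b),
                            c("experimental", tags))
  omnibus <- kruskal_wallis(groups)
  dunn <- dunn_posthoc(groups)
  fligner <- stats::setNames(
    list(fligner_killeen(experimental, preds_a),
         fligner_killeen(experimental, preds_b)), tags)
  equivalence <- stats::setNames(
    list(mann_whitney_equivalence(experimental, preds_a, eq_cfg),
         mann_whitney_equivalence(experimental, preds_b, eq_cfg)), tags)
  loc_p <- vapply(tags, function(tg) {
    row <- (dunn$group1 == "experimental" & dunn$group2 == tg) |
      (dunn$group2 == "experimental" & dunn$group1 == tg)
    dunn$p_value[row]
  }, numeric(1))
  candidates <- tags[loc_p >= alpha]
  if (length(candidates) == 0) candidates <- tags
  flig_p <- vapply(tags, function(tg) fligner[[tg]]$p_value, numeric(1))
  homo <- candidates[flig_p[candidates] >= alpha]
  selected <- NA_character_
  reason <- "indeterminate"
  if (length(homo) == 1L) {
    selected <- homo
    reason <- "homoscedastic with experimental results"
  } else {
    pool <- if (length(homo) >= 2L) homo else candidates
    if (!is.null(cv) && all(pool %in% names(cv))) {
      mses <- vapply(pool, function(tg) cv[[tg]]$mean_mse, numeric(1))
      if (length(unique(mses)) > 1L || length(pool) == 1L) {
        selected <- pool[which.min(mses)]
        reason <- "lower cross-validated mean MSE"
      }
    } else if (length(unique(flig_p[pool])) == length(pool)) {
      selected <- pool[which.max(flig_p[pool])]
      reason <- "largest spread-homogeneity p-value"
    }
  }
  structure(list(omnibus = omnibus, dunn = dunn, fligner = fligner,
                 equivalence = equivalence, cv = cv, alpha = alpha,
                 selected = selected, reason = reason),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Surrogate model selection\n")
  print(x$omnibus)
  for (tg in names(x$fligner)) {
    cat(sprintf("  %s vs experimental: Fligner-Killeen p = %.4g, W+ = %.3f\n",
                tg, x$fligner[[tg]]$p_value, x$equivalence[[tg]]$W_plus))
  }
  cat("selected:", x$selected, "-", x$reason, "\n")
  invisible(x)
}

#' Screen trial candidates with a surrogate
#'
#' Keeps the `k` candidates with the highest predicted motility (greedy
#' mean acquisition); rank order is deterministic, ties broken by
#' formulation id. This is how the surrogate couples to the optimizer while
#' leaving the experimental budget at one batch per generation.
#'
#' @param model a fitted surrogate.
#' @param candidates a `population` of trial formulations.
#' @param k batch size to keep (`k <= length(candidates)`).
#' @param space a `formulation_space` (for featurization).
#' @return the screened `population`, with predictions in attribute
#'   `"predicted"` (and `"predicted_sd"` when the model provides one).
#' @export
screen_candidates <- function(model, candidates, k,
                              space = extender_space()) {
  if (!inherits(model, "surrogate_model")) {
    stop("model must be a fitted surrogate", call. = FALSE)
  }
  if (length(candidates) < k) {
    stop("fewer candidates than the requested batch size", call. = FALSE)
  }
  feats <- featurize(candidates, space)
  pred <- predict(model, feats)
  ord <- order(-pred, candidates$id)
  keep <- ord[seq_len(k)]
  out <- population(candidates$X[keep, , drop = FALSE],
                    generation = candidates$generation,
                    id = candidates$id[keep],
                    provenance = candidates$provenance[keep])
  attr(out, "predicted") <- pred[keep]
  attr(out, "predicted_sd") <- predict_sd(model, feats[keep, , drop = FALSE])
  out
}
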