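#' Relative total motility
#'
#' Per-sample ratio of a treatment extender's total motility over the
#' split-sample control's total motility, the metric that controls for
#' individual bull variability.
#'
#' @param treatment treatment motility \% (vectorized).
#' @param control matching control motility \% (> 0).
#' @return dimensionless ratio(s).
#' @export
relative_total_motility <- function(treatment, control) {
  if (any(control <= 0)) {
    stop("relative total motility undefined: control motility <= 0",
         call. = FALSE)
  }
  treatment / control
}

#' Equivalence-test configuration
#'
#' The campaign's conservative symmetrical margin is `(-0.15, 0.15)` on the
#' `P(X > Y) - 1/2` scale at `alpha = 0.05`.
#'
#' @param alpha significance level in (0, 1).
#' @param eps1,eps2 lower/upper equivalence margins, each in (0, 0.5).
#' @return an object of class `equivalence_config`.
#' @export
equivalence_config <- function(alpha = 0.05, eps1 = 0.15, eps2 = 0.15) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (eps1 <= 0 || eps1 >= 0.5 || eps2 <= 0 || eps2 >= 0.5) {
    stop("equivalence margins must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(alpha = alpha, eps1 = eps1, eps2 = eps2),
            class = "equivalence_config")
}

#' Mann-Whitney test for equivalence (Wellek)
#'
#' Two-sample nonparametric equivalence test whose null hypothesis is
#' NON-equivalence. `W+` estimates `P(X > Y)` (ties weighted 1/2); its
#' asymptotic standard error `sigma_hat` comes from the U-statistic variance
#' with the shared-X and shared-Y second-order terms; the critical bound is
#' `CRIT = sqrt(q_chisq(alpha; df = 1, ncp = (eps_bar / sigma_hat)^2))` with
#' `eps_bar = (eps1 + eps2) / 2`, and non-equivalence is rejected
#' (`REJ = 1`, equivalence established) when
#' `|W+ - center| / sigma_hat < CRIT`, `center = 1/2 + (eps2 - eps1) / 2`.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param cfg an [equivalence_config()].
#' @return an `equivalence_result` with fields `W_plus`, `sigma_hat`,
#'   `CRIT`, `REJ`, `m`, `n` and the config echo.
#' @export
mann_whitney_equivalence <- function(x, y, cfg = equivalence_config()) {
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  w <- mean(cmp)
  s_i <- rowSums(cmp); q_i <- rowSums(cmp^2)     # shared-X pairs
  pi_xyy <- sum(s_i^2 - q_i) / (m * n * (n - 1))
  s_j <- colSums(cmp); q_j <- colSums(cmp^2)     # shared-Y pairs
  pi_xxy <- sum(s_j^2 - q_j) / (n * m * (m - 1))
  # first term is E[h^2] - W^2; identical to W(1 - W) for tie-free samples
  var_w <- (mean(cmp^2) - w^2 + (n - 1) * (pi_xyy - w^2) +
              (m - 1) * (pi_xxy - w^2)) / (m * n)
  sigma_hat <- sqrt(max(var_w, 0))
  center <- 0.5 + (cfg$eps2 - cfg$eps1) / 2
  eps_bar <- (cfg$eps1 + cfg$eps2) / 2
  if (sigma_hat == 0) {
    if (abs(w - center) < 1e-12) {
      stop("degenerate samples: the U-statistic variance estimate is zero",
           call. = FALSE)
    }
    # e.g. complete separation: the estimate is pinned away from the
    # equivalence center, so non-equivalence cannot be rejected
    crit <- Inf
    rej <- 0L
  } else {
    crit <- sqrt(stats::qchisq(cfg$alpha, df = 1,
                               ncp = (eps_bar / sigma_hat)^2))
    rej <- as.integer(abs(w - center) / sigma_hat < crit)
  }
  structure(list(W_plus = w, sigma_hat = sigma_hat, CRIT = crit, REJ = rej,
                 m = m, n = n, config = cfg),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney equivalence test: m = %d, n = %d, eps = (-%g, %g)\n",
    x$m, x$n, x$config$eps1, x$config$eps2))
  cat(sprintf("  W+ = %.4f, sigma_hat = %.4f, CRIT = %.4f, REJ = %d (%s)\n",
              x$W_plus, x$sigma_hat, x$CRIT, x$REJ,
              if (x$REJ == 1) "equivalence established"
              else "non-equivalence not rejected"))
  invisible(x)
}

#' The equivalence decision rule on reported summary statistics
#'
#' Applies the decision rule `REJ = 1` iff `|W+ - 1/2| / sigma_hat < CRIT`
#' to an already-computed (W+, sigma_hat, CRIT) summary, as printed in
#' statistical reports (symmetric margins).
#'
#' @param w_plus estimated `P(X > Y)`.
#' @param sigma_hat its standard-error estimate.
#' @param crit critical bound.
#' @return integer decision flag (1 = equivalence established).
#' @export
equivalence_decision <- function(w_plus, sigma_hat, crit) {
  as.integer(abs(w_plus - 0.5) / sigma_hat < crit)
}

rank_test_result <- function(statistic, df, p_value, test_tag,
                             groups = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_tag = test_tag,
                 groups = groups),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_tag,
              x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' Kruskal-Wallis omnibus rank test
#'
#' Tie-corrected rank-sum H statistic compared to a chi-square with
#' `length(groups) - 1` degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return a `rank_test` with `test_tag = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  rank_test_result(kt$statistic, kt$parameter, kt$p.value, "kruskal_wallis")
}

#' Dunn post-hoc pairwise rank test
#'
#' Pairwise z tests on mean ranks with the standard tie correction,
#' following a Kruskal-Wallis omnibus. Both unadjusted and Holm-adjusted
#' p-values are reported; the Holm column is the one used for decisions.
#'
#' @param groups named list of >= 2 non-empty numeric samples.
#' @return data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value` (unadjusted) and `p_holm`.
#' @export
dunn_posthoc <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  g <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(g))
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1L
  mean_ranks <- vapply(seq_len(g), function(i) {
    mean(r[idx_start[i]:idx_end[i]])
  }, numeric(1))
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  res <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    z = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[i] + 1 / sizes[j]))
    z <- (mean_ranks[i] - mean_ranks[j]) / se
    res$z[k] <- z
    res$p_value[k] <- 2 * stats::pnorm(-abs(z))
  }
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  res
}

#' Fligner-Killeen variance-homogeneity test
#'
#' Median-centered normal-scores test of equal spread between two samples
#' (df = 1); delegates to [stats::fligner.test()]. Used to ask whether a
#' surrogate model's predictions are homoscedastic with the experimental
#' motilities.
#'
#' @param x,y numeric samples, each of size >= 2 and not constant together.
#' @return a `rank_test` with `test_tag = "fligner_killeen"`.
#' @export
fligner_killeen <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  if (length(unique(c(x - stats::median(x), y - stats::median(y)))) == 1L) {
    stop("degenerate constant samples: spread test undefined", call. = FALSE)
  }
  ft <- stats::fligner.test(list(x, y))
  rank_test_result(ft$statistic, ft$parameter, ft$p.value,
                   "fligner_killeen")
}

#' Per-generation medians and standard deviations
#'
#' Summarizes motility records generation by generation: per-bull pooled
#' values of the active metric (total motility, or the relative ratio),
#' then median and SD per generation — the generational-trajectory table.
#'
#' @param records motility record data frame with columns `generation`,
#'   `formulation_id`, `bull_id`, `total_motility`, `control_motility`.
#' @param metric `"total"` or `"relative"`.
#' @param include_control include the control extender's own records.
#' @return data frame with `generation`, `n`, `median`, `sd`.
#' @export
generation_summary <- function(records, metric = c("total", "relative"),
                               include_control = FALSE) {
  metric <- match.arg(metric)
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  if (!include_control) {
    records <- records[records$formulation_id != "control", , drop = FALSE]
  }
  vals <- pooled_metric_values(records, metric)
  gens <- sort(unique(vals$generation))
  out <- data.frame(generation = gens, n = NA_integer_,
                    median = NA_real_, sd = NA_real_)
  for (k in seq_along(gens)) {
    v <- vals$value[vals$generation == gens[k]]
    out$n[k] <- length(v)
    out$median[k] <- stats::median(v)
    out$sd[k] <- if (length(v) > 1) stats::sd(v) else 0
  }
  out
}

# Pool straw replicates to one value per (generation, formulation, bull):
# mean motility per bull; the relative metric divides by the same bull's
# pooled control motility.
pooled_metric_values <- function(records, metric = c("total", "relative")) {
  metric <- match.arg(metric)
  key <- interaction(records$generation, records$formulation_id,
                     records$bull_id, drop = TRUE)
  t_mean <- tapply(records$total_motility, key, mean)
  c_mean <- tapply(records$control_motility, key, mean)
  parts <- do.call(rbind, strsplit(names(t_mean), ".", fixed = TRUE))
  value <- if (metric == "total") as.numeric(t_mean)
           else relative_total_motility(as.numeric(t_mean),
                                        as.numeric(c_mean))
  data.frame(generation = as.integer(parts[, 1]),
             formulation_id = parts[, 2], bull_id = parts[, 3],
             value = value, stringsAsFactors = FALSE, row.names = NULL)
}
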