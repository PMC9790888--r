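# Shared fixtures, built in code.

# A small 3-component space: two active ranged components and one frozen.
small_space <- function() {
  formulation_space(data.frame(
    name = c("glycerol", "trehalose", "glutathione"),
    unit = c("percent_vv", "mM", "mM"),
    lower = c(0, 0, 0.5), upper = c(7, 100, 0.5),
    reference = c(7, 100, 0.5),
    active = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE), version_tag = "small")
}

# Two-component fully active space used for DE oracle replays.
plain_space <- function(d = 2, upper = 10) {
  formulation_space(data.frame(
    name = paste0("c", seq_len(d)),
    unit = "mM",
    lower = 0, upper = upper, reference = upper,
    stringsAsFactors = FALSE), version_tag = "plain")
}

# A tiny smooth surface over small_space() with a known interior optimum.
small_surface <- function() {
  response_surface(
    baseline = 30,
    effects = data.frame(name = c("glycerol", "trehalose"),
                         optimum = c(5, 40), width = c(2, 30),
                         amplitude = c(30, 10), stringsAsFactors = FALSE))
}

# All (W+, sigma_hat, CRIT) summary tuples printed in the campaign's
# statistical reports; equivalence was never established in any of them.
reported_equivalence_tuples <- function() {
  data.frame(
    comparison = c("gen6 experimental vs ann", "gen6 experimental vs gpr",
                   "gen6 ann vs gpr", "gen17 vs control",
                   "gen21 vs control", "gen19 vs gen20", "gen20 vs gen21",
                   "gen19 vs gen21", "total vs relative metric"),
    w_plus = c(0.56, 0.63, 0.61, 0.30, 0.73, 0.44, 0.43, 0.34, 0.60),
    sigma_hat = c(0.08, 0.07, 0.08, 0.15, 0.07, 0.07, 0.07, 0.07, 0.07),
    crit = c(0.31, 0.57, 0.31, 0.10, 0.44, 0.52, 0.51, 0.63, 0.10),
    stringsAsFactors = FALSE)
}

# Independent brute-force Wellek machinery: explicit triple loops, no
# vectorized sharing with the implementation.
brute_w_plus <- function(x, y) {
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

brute_sigma_hat <- function(x, y) {
  m <- length(x); n <- length(y)
  h <- function(a, b) (a > b) + 0.5 * (a == b)
  w <- brute_w_plus(x, y)
  pi_xyy <- 0
  for (i in 1:m) for (j1 in 1:n) for (j2 in 1:n) {
    if (j1 != j2) pi_xyy <- pi_xyy + h(x[i], y[j1]) * h(x[i], y[j2])
  }
  pi_xyy <- pi_xyy / (m * n * (n - 1))
  pi_xxy <- 0
  for (i1 in 1:m) for (i2 in 1:m) for (j in 1:n) {
    if (i1 != i2) pi_xxy <- pi_xxy + h(x[i1], y[j]) * h(x[i2], y[j])
  }
  pi_xxy <- pi_xxy / (m * (m - 1) * n)
  eh2 <- 0
  for (xi in x) for (yj in y) eh2 <- eh2 + h(xi, yj)^2
  eh2 <- eh2 / (m * n)
  sqrt((eh2 - w^2 + (n - 1) * (pi_xyy - w^2) +
          (m - 1) * (pi_xxy - w^2)) / (m * n))
}

# Independent Kruskal-Wallis: textbook tie-corrected H from scratch.
brute_kruskal <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      sum(r[starts[i]:ends[i]])^2 / sizes[i]
    }, numeric(1))) - 3 * (N + 1)
  tie_tab <- table(values)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  H <- H / C
  list(statistic = H, df = length(groups) - 1,
       p_value = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Independent Fligner-Killeen for k groups: median-centered normal scores.
brute_fligner <- function(groups) {
  a_all <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  r <- rank(a_all)
  N <- length(a_all)
  a <- stats::qnorm(0.5 + r / (2 * (N + 1)))
  abar <- mean(a)
  v <- sum((a - abar)^2) / (N - 1)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  stat <- sum(vapply(seq_along(groups), function(i) {
    sizes[i] * (mean(a[starts[i]:ends[i]]) - abar)^2
  }, numeric(1))) / v
  list(statistic = stat, df = length(groups) - 1,
       p_value = stats::pchisq(stat, length(groups) - 1,
                               lower.tail = FALSE))
}

# Independent Dunn z and p for one pair of groups out of a named list.
brute_dunn <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  mean_ranks <- vapply(seq_along(groups), function(i) {
    mean(r[starts[i]:ends[i]])
  }, numeric(1))
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  out <- NULL
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) *
                   (1 / sizes[i] + 1 / sizes[j]))
      z <- (mean_ranks[i] - mean_ranks[j]) / se
      out <- rbind(out, data.frame(i = i, j = j, z = z,
                                   p = 2 * stats::pnorm(-abs(z))))
    }
  }
  out
}

# Brute-force DE oracle: replays the identical RNG stream with scalar
# arithmetic, independently of the vectorized implementation.
oracle_trials <- function(X, cfg, space, generation) {
  comp <- space$components
  act <- which(comp$active)
  da <- length(act)
  np <- nrow(X)
  jitter_on <- generation > cfg$jitter_after_generation
  out <- X
  for (i in seq_len(np)) {
    donors <- sample(setdiff(seq_len(np), i), 3L)
    j_rand <- sample.int(da, 1L)
    u <- stats::runif(da)
    jit <- if (jitter_on) stats::runif(da, -cfg$jitter_fraction,
                                       cfg$jitter_fraction) else numeric(da)
    for (k in seq_len(da)) {
      j <- act[k]
      if (u[k] <= cfg$CR || k == j_rand) {
        v <- X[donors[3], j] + cfg$F * (X[donors[1], j] - X[donors[2], j])
        if (jitter_on) v <- v + comp$reference[j] * jit[k]
        v <- min(max(v, comp$lower[j]), comp$upper[j])
        out[i, j] <- v
      }
    }
  }
  out
}
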