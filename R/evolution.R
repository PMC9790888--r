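#' Differential-evolution configuration
#'
#' Settings for the DE/rand/1/bin optimizer: population size 8 (one
#' generation's batch of extenders), mutation factor `F = 0.9`, crossover
#' rate `CR = 0.5`, and — after generation 10 — an extra per-coordinate
#' jitter of the component's reference value times a uniform draw in
#' +/- `jitter_fraction`.
#'
#' @param population_size formulations per generation (>= 4: three distinct
#'   donors plus the target are required).
#' @param F mutation factor (> 0).
#' @param CR crossover rate in (0, 1].
#' @param jitter_after_generation reference jitter activates for
#'   generations strictly greater than this.
#' @param jitter_fraction maximum relative jitter.
#' @param seed optional seed used by [init_population()].
#' @param candidate_oversampling trial batches proposed per generation when
#'   a surrogate screens candidates (>= 1).
#' @param selection `"pooled"` (top-N over parents and trials pooled, as the
#'   campaign uses) or `"pairwise"` (classic per-index DE replacement).
#' @return an object of class `de_config`.
#' @export
de_config <- function(population_size = 8, F = 0.9, CR = 0.5,
                      jitter_after_generation = 10, jitter_fraction = 0.10,
                      seed = NULL, candidate_oversampling = 4,
                      selection = c("pooled", "pairwise")) {
  selection <- match.arg(selection)
  if (population_size < 4) {
    stop("population_size must be at least 4 (three donors plus target)",
         call. = FALSE)
  }
  if (F <= 0) stop("mutation factor F must be positive", call. = FALSE)
  if (CR <= 0 || CR > 1) stop("CR must lie in (0, 1]", call. = FALSE)
  if (candidate_oversampling < 1) {
    stop("candidate_oversampling must be >= 1", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size), F = F,
                 CR = CR,
                 jitter_after_generation = as.integer(jitter_after_generation),
                 jitter_fraction = jitter_fraction, seed = seed,
                 candidate_oversampling = as.integer(candidate_oversampling),
                 selection = selection),
            class = "de_config")
}

#' Initialize a space-filling population
#'
#' Latin-hypercube stratification per active component: with population size
#' N, each component's N values fall one in each of N equal slices of its
#' range, guaranteeing coverage of an 11-dimensional space at N = 8.
#' Inactive components carry their frozen value exactly. Uses `cfg$seed`
#' when set, otherwise the current RNG stream.
#'
#' @param space a `formulation_space`.
#' @param cfg a `de_config`.
#' @param generation generation label (default 0).
#' @return a `population` of valid formulations.
#' @export
init_population <- function(space, cfg = de_config(), generation = 0L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  comp <- space$components
  n <- cfg$population_size
  act <- which(comp$active & comp$upper > comp$lower)
  U <- lhs::randomLHS(n, length(act))
  X <- matrix(rep(reference_values(space), each = n), nrow = n)
  colnames(X) <- comp$name
  for (k in seq_along(act)) {
    i <- act[k]
    X[, i] <- comp$lower[i] + U[, k] * (comp$upper[i] - comp$lower[i])
  }
  inact <- !comp$active
  X[, inact] <- matrix(rep(comp$reference[inact], each = n), nrow = n)
  population(X, generation = generation, provenance = "initial")
}

#' Reference-value jitter
#'
#' The post-generation-10 modification: adds
#' `ref * U(-jitter_fraction, +jitter_fraction)` to each value, so the
#' offset never exceeds `jitter_fraction * ref` in magnitude. Vectorized;
#' draws come from the current RNG stream.
#'
#' @param values numeric vector of trial coordinates.
#' @param refs reference values aligned to `values`.
#' @param cfg a `de_config` (supplies `jitter_fraction`).
#' @return jittered values.
#' @export
apply_reference_jitter <- function(values, refs, cfg = de_config()) {
  jf <- cfg$jitter_fraction
  values + refs * stats::runif(length(values), -jf, jf)
}

#' DE/rand/1/bin trial generation
#'
#' For each target member, three mutually distinct donors r1, r2, r3 (all
#' different from the target) are drawn; each active coordinate takes the
#' mutant value `r3 + F * (r1 - r2)` with probability `CR` — plus one forced
#' coordinate per trial so no trial equals its target — and the target's
#' value otherwise. For generations past `jitter_after_generation` every
#' mutated coordinate additionally receives the reference jitter. Trials
#' are clipped to bounds; inactive components are untouched.
#'
#' Draw order per target (from the current RNG stream): donor triple, forced
#' coordinate, one uniform per active coordinate for crossover, then — when
#' jitter is on — one uniform per active coordinate for the jitter.
#'
#' @param pop scored or unscored parent `population` (size >= 4).
#' @param cfg a `de_config`.
#' @param space a `formulation_space`.
#' @param generation generation the trials are proposed for (controls
#'   jitter); defaults to the parents' generation + 1.
#' @param batch integer tag used to keep trial ids unique when several
#'   batches are proposed for surrogate screening.
#' @return a `population` of trial formulations (provenance `"mutant"`).
#' @export
mutate_rand_1_bin <- function(pop, cfg, space,
                              generation = pop$generation + 1L,
                              batch = 1L) {
  np <- length(pop)
  if (np < 4) {
    stop("DE/rand/1/bin needs a population of at least 4", call. = FALSE)
  }
  comp <- space$components
  act <- which(comp$active)
  da <- length(act)
  refs <- comp$reference[act]
  jitter_on <- generation > cfg$jitter_after_generation
  Xt <- pop$X
  for (i in seq_len(np)) {
    donors <- sample(setdiff(seq_len(np), i), 3L)
    j_rand <- sample.int(da, 1L)
    u <- stats::runif(da)
    cross <- u <= cfg$CR
    cross[j_rand] <- TRUE
    mut <- pop$X[donors[3L], act] +
      cfg$F * (pop$X[donors[1L], act] - pop$X[donors[2L], act])
    if (jitter_on) {
      mut <- apply_reference_jitter(mut, refs, cfg)
    }
    row <- pop$X[i, act]
    row[cross] <- mut[cross]
    Xt[i, act] <- row
  }
  Xt <- clip_matrix(Xt, space)
  population(Xt, generation = generation,
             id = sprintf("g%02d_t%02d", generation,
                          (batch - 1L) * np + seq_len(np)),
             provenance = "mutant")
}

#' Pooled top-N survivor selection
#'
#' Selects the `k` highest-scoring formulations from the union of parents
#' and trials (greedy elitism over both populations, as the campaign's
#' selection step is described). Ties are broken in favour of trial vectors,
#' then by formulation id.
#'
#' @param parents scored parent `population`.
#' @param trials scored trial `population`.
#' @param k number of survivors.
#' @return a `population` of `k` survivors labelled with the trials'
#'   generation.
#' @export
select_top <- function(parents, trials, k) {
  for (p in list(parents, trials)) {
    if (is.null(p$scores) || anyNA(p$scores)) {
      stop("both populations must be fully scored before selection",
           call. = FALSE)
    }
  }
  pooled <- bind_populations(parents, trials,
                             generation = trials$generation)
  is_trial <- c(rep(FALSE, length(parents)), rep(TRUE, length(trials)))
  ord <- order(-pooled$scores, !is_trial, pooled$id)
  keep <- ord[seq_len(min(k, length(pooled)))]
  population(pooled$X[keep, , drop = FALSE],
             generation = trials$generation,
             id = pooled$id[keep], provenance = pooled$provenance[keep],
             scores = pooled$scores[keep])
}

#' Plateau-based convergence check
#'
#' The campaign is converged when the Kruskal-Wallis omnibus test across the
#' last few generations' motility values finds no difference
#' (p >= `alpha`): the score trajectory has plateaued. Degenerate inputs
#' where every value is identical count as converged.
#'
#' @param groups list of numeric vectors, one per generation (>= 2 groups).
#' @param alpha significance level for the omnibus test.
#' @return logical flag; the underlying `rank_test` is attached as attribute
#'   `"test"` (`NULL` in the all-identical degenerate case).
#' @export
check_convergence <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) {
    stop("convergence check needs at least 2 generations", call. = FALSE)
  }
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    return(structure(TRUE, test = NULL))
  }
  kt <- kruskal_wallis(groups)
  structure(kt$p_value >= alpha, test = kt)
}
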