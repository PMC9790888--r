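#' Synthetic ground-truth motility response surface
#'
#' The virtual lab replaces all wet-lab measurement with a configurable
#' ground-truth surface: post-thaw total motility (\%) as a function of the
#' formulation, modelled as a baseline plus concave Gaussian-bump main
#' effects, signed pairwise interaction products on bound-normalized
#' concentrations, and linear monotone penalties, truncated to
#' `[floor, ceiling]`. This is the simplest family that encodes the
#' campaign's qualitative biology — a permeating-cryoprotectant optimum,
#' glycerol/ethylene-glycol redundancy with ethylene glycol harmful,
#' fructose dispensable, NGF detrimental — while keeping the global optimum
#' computable and exposable.
#'
#' @param baseline motility \% with every component absent.
#' @param effects data frame `name, optimum, width, amplitude`: concave
#'   single-component bumps `amplitude * exp(-((c-optimum)/width)^2 / 2)`.
#' @param interactions data frame `comp1, comp2, coefficient`: adds
#'   `coefficient * z1 * z2` with `z` the bound-normalized concentration.
#' @param penalties data frame `name, slope`: adds `slope * c` (negative
#'   slope = detrimental component).
#' @param floor,ceiling truncation limits in motility \%.
#' @return an object of class `response_surface`.
#' @export
response_surface <- function(baseline,
                             effects = NULL,
                             interactions = NULL,
                             penalties = NULL,
                             floor = 0, ceiling = 100) {
  if (baseline < floor || baseline > ceiling) {
    stop("baseline must lie in [floor, ceiling]", call. = FALSE)
  }
  if (!is.null(effects) && any(effects$width <= 0)) {
    stop("effect widths must be positive", call. = FALSE)
  }
  structure(list(baseline = baseline, effects = effects,
                 interactions = interactions, penalties = penalties,
                 floor = floor, ceiling = ceiling),
            class = "response_surface")
}

#' Default benchmark surface for the extender space
#'
#' Calibrated so the commercial control extender scores in the observed
#' 60-70\% band, early random formulations score far lower, and the global
#' optimum (~91\%) requires glycerol near 6\% v/v, zero ethylene glycol and
#' zero NGF.
#'
#' @param space the extender `formulation_space`.
#' @return a `response_surface`.
#' @export
benchmark_surface <- function(space = extender_space()) {
  effects <- data.frame(
    name      = c("tris", "egg_yolk", "milk", "fructose", "glycerol",
                  "trehalose", "clc", "melatonin"),
    optimum   = c(25,     16,        5,      0.6,        6,
                  45,          0.7,   2.5),
    width     = c(15,     8,         6,      0.8,        2.5,
                  35,          0.4,   0.6),
    amplitude = c(14,     16,        4,      2,          22,
                  8,           4,     3),
    stringsAsFactors = FALSE)
  penalties <- data.frame(
    name  = c("ethylene_glycol", "ngf"),
    slope = c(-2.2, -16),
    stringsAsFactors = FALSE)
  interactions <- data.frame(
    comp1 = "glycerol", comp2 = "ethylene_glycol", coefficient = -6,
    stringsAsFactors = FALSE)
  response_surface(baseline = 18, effects = effects,
                   interactions = interactions, penalties = penalties)
}

normalize_columns <- function(X, space) {
  comp <- space$components
  Z <- X
  for (j in seq_len(ncol(X))) {
    i <- match(colnames(X)[j], comp$name)
    rng <- comp$upper[i] - comp$lower[i]
    Z[, j] <- if (rng > 0) (X[, j] - comp$lower[i]) / rng else 0
  }
  Z
}

as_conc_matrix <- function(f, space) {
  if (inherits(f, "population")) {
    X <- f$X
  } else if (inherits(f, "formulation")) {
    X <- matrix(f$concentrations, nrow = 1)
  } else if (is.matrix(f)) {
    X <- f
  } else {
    X <- matrix(as.numeric(f), nrow = 1)
  }
  colnames(X) <- component_names(space)
  X
}

#' Evaluate the noiseless response surface
#'
#' @param f a `formulation`, `population` or concentration matrix.
#' @param surface a `response_surface`.
#' @param space the `formulation_space` the concentrations align to.
#' @return numeric vector of true motility \%, one per formulation.
#' @export
true_motility <- function(f, surface, space = extender_space()) {
  X <- as_conc_matrix(f, space)
  val <- rep(surface$baseline, nrow(X))
  eff <- surface$effects
  if (!is.null(eff)) {
    for (k in seq_len(nrow(eff))) {
      c_k <- X[, eff$name[k]]
      val <- val + eff$amplitude[k] *
        exp(-0.5 * ((c_k - eff$optimum[k]) / eff$width[k])^2)
    }
  }
  pen <- surface$penalties
  if (!is.null(pen)) {
    for (k in seq_len(nrow(pen))) {
      val <- val + pen$slope[k] * X[, pen$name[k]]
    }
  }
  inter <- surface$interactions
  if (!is.null(inter)) {
    Z <- normalize_columns(X, space)
    for (k in seq_len(nrow(inter))) {
      val <- val + inter$coefficient[k] *
        Z[, inter$comp1[k]] * Z[, inter$comp2[k]]
    }
  }
  unname(pmin(pmax(val, surface$floor), surface$ceiling))
}

#' Argmax of the noiseless surface
#'
#' Computed by cyclic coordinate ascent over dense per-component grids
#' (including interaction terms), started from the separable per-component
#' optimum. Exact for the benchmark family, where every interaction involves
#' a component whose optimum sits at an interaction zero.
#'
#' @param surface a `response_surface`.
#' @param space a `formulation_space`.
#' @param grid_points grid density per coordinate sweep.
#' @return list with `formulation` (the arg-max) and `value`.
#' @export
surface_argmax <- function(surface, space = extender_space(),
                           grid_points = 2001L) {
  comp <- space$components
  conc <- reference_values(space)
  conc[comp$active] <- comp$lower[comp$active]
  # start each bumped component at its (clipped) bump optimum
  if (!is.null(surface$effects)) {
    for (k in seq_len(nrow(surface$effects))) {
      nm <- surface$effects$name[k]
      i <- match(nm, comp$name)
      if (comp$active[i]) {
        conc[nm] <- min(max(surface$effects$optimum[k], comp$lower[i]),
                        comp$upper[i])
      }
    }
  }
  repeat {
    changed <- FALSE
    for (i in which(comp$active)) {
      if (comp$upper[i] == comp$lower[i]) next
      grid <- seq(comp$lower[i], comp$upper[i], length.out = grid_points)
      Xg <- matrix(rep(conc, each = grid_points), nrow = grid_points)
      colnames(Xg) <- comp$name
      Xg[, i] <- grid
      vals <- true_motility(Xg, surface, space)
      best <- grid[which.max(vals)]
      if (abs(best - conc[i]) > 1e-9) changed <- TRUE
      conc[i] <- best
    }
    if (!changed) break
  }
  f <- formulation(conc, id = "surface_argmax", provenance = "manual")
  list(formulation = f,
       value = true_motility(f, surface, space))
}

#' Bull-variability noise model
#'
#' Additive among-bull effects shared between a bull's treatment and control
#' straws (which is what makes the relative-motility metric
#' variance-reducing), plus homoscedastic per-straw noise; simulated
#' motilities are clamped to `[0, 100]` last.
#'
#' @param sd_bull among-bull standard deviation, motility \%.
#' @param sd_within per-straw (replicate) standard deviation, motility \%.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sd_bull = 8, sd_within = 5) {
  if (sd_bull < 0 || sd_within < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(sd_bull = sd_bull, sd_within = sd_within),
            class = "noise_model")
}

#' Draw a panel of bulls
#'
#' Draws per-bull additive motility effects from the current RNG stream.
#'
#' @param n number of bulls.
#' @param noise a `noise_model`.
#' @param ids optional bull identifiers.
#' @return data frame with `bull_id` and `effect`.
#' @export
make_bulls <- function(n, noise = noise_model(), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("b%02d", seq_len(n))
  data.frame(bull_id = ids,
             effect = stats::rnorm(n, 0, noise$sd_bull),
             stringsAsFactors = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 100)

#' Simulate a split-sample motility assay
#'
#' One record per (formulation, bull, replicate), plus records for the
#' control extender itself (`formulation_id = "control"`). The bull effect
#' is shared between a bull's treatment and control straws; per-straw noise
#' is independent; truncation to `[0, 100]` is applied last. Treatment rows
#' carry the replicate-matched control motility in `control_motility`.
#' Draws come from the current RNG stream: per bull, first the control
#' replicates, then each formulation's replicates in population order.
#'
#' @param formulations a `population` (or single `formulation`).
#' @param bulls data frame from [make_bulls()].
#' @param replicates straws per (formulation, bull).
#' @param surface a `response_surface`.
#' @param space a `formulation_space`.
#' @param noise a `noise_model`.
#' @param generation generation label written to the records.
#' @param control the control `formulation` ([control_extender()] by
#'   default).
#' @return data frame of motility records.
#' @export
simulate_assay <- function(formulations, bulls, replicates = 3,
                           surface, space = extender_space(),
                           noise = noise_model(), generation = 0L,
                           control = control_extender(space)) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (inherits(formulations, "formulation")) {
    formulations <- population(matrix(formulations$concentrations, nrow = 1,
                                      dimnames = list(NULL,
                                                      component_names(space))),
                               generation = generation,
                               id = formulations$id,
                               provenance = formulations$provenance)
  }
  mu_f <- true_motility(formulations, surface, space)
  mu_c <- true_motility(control, surface, space)
  nf <- length(formulations)
  out <- vector("list", nrow(bulls))
  for (b in seq_len(nrow(bulls))) {
    eff <- bulls$effect[b]
    ctrl <- clamp01(mu_c + eff + stats::rnorm(replicates, 0, noise$sd_within))
    rows <- vector("list", nf + 1L)
    rows[[1L]] <- data.frame(
      generation = generation, formulation_id = "control",
      bull_id = bulls$bull_id[b], replicate = seq_len(replicates),
      total_motility = ctrl, control_motility = ctrl,
      stringsAsFactors = FALSE)
    for (k in seq_len(nf)) {
      trt <- clamp01(mu_f[k] + eff + stats::rnorm(replicates, 0,
                                                  noise$sd_within))
      rows[[k + 1L]] <- data.frame(
        generation = generation, formulation_id = formulations$id[k],
        bull_id = bulls$bull_id[b], replicate = seq_len(replicates),
        total_motility = trt, control_motility = ctrl,
        stringsAsFactors = FALSE)
    }
    out[[b]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Generate a study-shaped synthetic campaign fixture
#'
#' Emits formulation and motility ledgers with the study's per-generation
#' design — by default 8 formulations x 4 bulls x 3 straw replicates plus a
#' split-sample control — from Latin-hypercube formulations, for testing
#' downstream stages without running the optimizer.
#'
#' @param n_generations number of generations to simulate.
#' @param formulations_per_gen,bulls_per_gen,replicates per-generation
#'   design.
#' @param surface a `response_surface` ([benchmark_surface()] by default).
#' @param space a `formulation_space`.
#' @param noise a `noise_model`.
#' @param seed integer seed; all draws go through deterministic substreams.
#' @return list with data frames `formulations` and `motility`.
#' @export
make_study_fixture <- function(n_generations,
                               formulations_per_gen = 8,
                               bulls_per_gen = 4,
                               replicates = 3,
                               surface = benchmark_surface(space),
                               space = extender_space(),
                               noise = noise_model(),
                               seed = 1L) {
  forms <- list()
  motil <- list()
  cfg <- de_config(population_size = max(formulations_per_gen, 4),
                   seed = NULL)
  for (g in seq_len(n_generations)) {
    set.seed(substream_seed(seed, g, "propose"))
    pop <- init_population(space, cfg, generation = g)
    pop$id <- sprintf("g%02d_f%02d", g, seq_len(formulations_per_gen))
    pop$X <- pop$X[seq_len(formulations_per_gen), , drop = FALSE]
    pop$provenance <- rep("manual", formulations_per_gen)
    set.seed(substream_seed(seed, g, "bulls"))
    bulls <- make_bulls(bulls_per_gen, noise,
                        ids = sprintf("g%02d_b%d", g,
                                      seq_len(bulls_per_gen)))
    set.seed(substream_seed(seed, g, "assay"))
    motil[[g]] <- simulate_assay(pop, bulls, replicates, surface, space,
                                 noise, generation = g)
    forms[[g]] <- population_ledger(pop)
  }
  empty_forms <- data.frame(generation = integer(0),
                            formulation_id = character(0),
                            provenance = character(0))
  for (nm in component_names(space)) empty_forms[[nm]] <- numeric(0)
  empty_motil <- data.frame(generation = integer(0),
                            formulation_id = character(0),
                            bull_id = character(0), replicate = integer(0),
                            total_motility = numeric(0),
                            control_motility = numeric(0))
  list(
    formulations = if (n_generations > 0) do.call(rbind, forms)
                   else empty_forms,
    motility = if (n_generations > 0) do.call(rbind, motil) else empty_motil
  )
}
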