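#' Campaign configuration
#'
#' Everything one closed-loop optimization campaign needs: the formulation
#' space, optimizer/surrogate/equivalence settings, the per-generation assay
#' design (8 formulations x 4 bulls x 3 straws plus the split-sample
#' control), the metric schedule (total motility through generation 17,
#' relative total motility from 18), surrogate coupling from generation 7,
#' scheduled component removals (NGF at generation 19), the lab backend
#' (virtual simulator or external CSV ingest) and the campaign seed.
#'
#' @param space a `formulation_space` or path to a space CSV.
#' @param de a [de_config()].
#' @param surrogate a [surrogate_config()].
#' @param equivalence an [equivalence_config()].
#' @param metric_relative_from first generation scored on relative total
#'   motility.
#' @param surrogate_start first generation whose candidates are screened by
#'   the selected surrogate (model selection happens then, trained on all
#'   earlier generations and tested on the most recent one).
#' @param removals named list: generation -> component names to freeze at 0.
#' @param bulls_per_gen,replicates assay design per generation.
#' @param max_generations generation cap.
#' @param convergence_window,convergence_alpha,convergence_check_from
#'   plateau detection: from generation `convergence_check_from` onward the
#'   Kruskal-Wallis omnibus across the last `convergence_window`
#'   generations' motilities declares convergence at p >= alpha.
#' @param check_convergence disable to always run to the cap.
#' @param lab list: `mode = "virtual"` with optional `surface`
#'   (`benchmark_surface()` by default) and `noise` ([noise_model()]), or
#'   `mode = "external"` (scores supplied to [run_generation()]).
#' @param seed campaign seed; all randomness derives from it.
#' @return an object of class `campaign_config`.
#' @export
campaign_config <- function(space = extender_space(),
                            de = de_config(),
                            surrogate = surrogate_config(),
                            equivalence = equivalence_config(),
                            metric_relative_from = 18,
                            surrogate_start = 7,
                            removals = list("19" = "ngf"),
                            bulls_per_gen = 4, replicates = 3,
                            max_generations = 21,
                            convergence_window = 3,
                            convergence_alpha = 0.05,
                            convergence_check_from = 21,
                            check_convergence = TRUE,
                            lab = list(mode = "virtual"),
                            seed = 1L) {
  if (is.character(space)) space <- load_space(space)
  lab$mode <- match.arg(lab$mode %||% "virtual", c("virtual", "external"))
  if (lab$mode == "virtual") {
    lab$surface <- lab$surface %||% benchmark_surface(space)
    lab$noise <- lab$noise %||% noise_model()
  }
  structure(list(space = space, de = de, surrogate = surrogate,
                 equivalence = equivalence,
                 metric_relative_from = as.integer(metric_relative_from),
                 surrogate_start = as.integer(surrogate_start),
                 removals = removals,
                 bulls_per_gen = as.integer(bulls_per_gen),
                 replicates = as.integer(replicates),
                 max_generations = as.integer(max_generations),
                 convergence_window = as.integer(convergence_window),
                 convergence_alpha = convergence_alpha,
                 convergence_check_from = as.integer(convergence_check_from),
                 check_convergence = isTRUE(check_convergence),
                 lab = lab, seed = as.integer(seed)),
            class = "campaign_config")
}

active_metric <- function(cfg, generation) {
  if (generation >= cfg$metric_relative_from) "relative" else "total"
}

score_ids <- function(records, ids, metric) {
  records <- records[records$formulation_id %in% ids, , drop = FALSE]
  vals <- pooled_metric_values(records, metric)
  vapply(ids, function(id) {
    stats::median(vals$value[vals$formulation_id == id])
  }, numeric(1))
}

control_ledger_row <- function(space, generation, control) {
  df <- data.frame(generation = generation, formulation_id = control$id,
                   provenance = control$provenance,
                   matrix(control$concentrations, nrow = 1,
                          dimnames = list(NULL, component_names(space))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df
}

evaluate_virtual <- function(state, pop, generation) {
  cfg <- state$cfg
  set.seed(substream_seed(cfg$seed, generation, "bulls"))
  bulls <- make_bulls(cfg$bulls_per_gen, cfg$lab$noise,
                      ids = sprintf("g%02d_b%d", generation,
                                    seq_len(cfg$bulls_per_gen)))
  set.seed(substream_seed(cfg$seed, generation, "assay"))
  simulate_assay(pop, bulls, cfg$replicates, cfg$lab$surface, state$space,
                 cfg$lab$noise, generation = generation,
                 control = state$control)
}

summary_row <- function(state, generation, metric) {
  recs <- state$motility[state$motility$generation == generation, ,
                         drop = FALSE]
  trt <- recs[recs$formulation_id != "control", , drop = FALSE]
  ctl <- recs[recs$formulation_id == "control", , drop = FALSE]
  vals <- pooled_metric_values(trt, metric)
  ctl_vals <- pooled_metric_values(ctl, "total")
  data.frame(generation = generation, metric = metric,
             n_pairs = nrow(vals),
             median = stats::median(vals$value),
             sd = stats::sd(vals$value),
             control_median = stats::median(ctl_vals$value),
             best_score = max(state$pop$scores),
             model_tag = state$model_tag %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Initialize a campaign
#'
#' Builds generation 0: a Latin-hypercube initial population spanning the
#' space, evaluated (in virtual mode) on a fresh bull panel with the
#' split-sample control, scored, and written to the ledgers.
#'
#' @param cfg a [campaign_config()].
#' @return a `campaign_state`.
#' @export
init_campaign <- function(cfg) {
  state <- structure(list(cfg = cfg, space = cfg$space,
                          control = control_extender(cfg$space),
                          generation = 0L, model = NULL,
                          model_tag = NULL, selection_report = NULL,
                          formulations = NULL, motility = NULL,
                          predictions = data.frame(
                            generation = integer(0),
                            formulation_id = character(0),
                            model_tag = character(0),
                            predicted_motility = numeric(0),
                            predicted_sd = numeric(0)),
                          summary = NULL, converged = FALSE),
                     class = "campaign_state")
  set.seed(substream_seed(cfg$seed, 0L, "init"))
  pop <- init_population(state$space, cfg$de, generation = 0L)
  if (cfg$lab$mode == "virtual") {
    records <- evaluate_virtual(state, pop, 0L)
  } else {
    stop("external mode: initialize with init_campaign_external()/ingest",
         call. = FALSE)
  }
  state$motility <- records
  pop$scores <- score_ids(records, pop$id, active_metric(cfg, 0L))
  state$pop <- pop
  state$formulations <- rbind(population_ledger(pop),
                              control_ledger_row(state$space, 0L,
                                                 state$control))
  state$summary <- summary_row(state, 0L, active_metric(cfg, 0L))
  state
}

#' @export
print.campaign_state <- function(x, ...) {
  cat("Campaign state: generation", x$generation, "\n")
  cat("  metric:", active_metric(x$cfg, x$generation),
      "| surrogate:", x$model_tag %||% "(not yet selected)",
      "| converged:", x$converged, "\n")
  cat("  best score:", signif(max(x$pop$scores), 4), "\n")
  invisible(x)
}

training_pairs <- function(state) {
  recs <- state$motility[state$motility$formulation_id != "control", ,
                         drop = FALSE]
  vals <- pooled_metric_values(recs, "total")
  forms <- state$formulations
  comp <- component_names(state$space)
  idx <- match(vals$formulation_id, forms$formulation_id)
  X <- as.matrix(forms[idx, comp, drop = FALSE])
  list(X = featurize(X, state$space), y = vals$value,
       generation = vals$generation)
}

fit_surrogate <- function(tag, X, y, scfg) {
  if (tag == "ann") fit_ann(X, y, scfg) else fit_gpr(X, y, scfg)
}

select_surrogate <- function(state, generation) {
  cfg <- state$cfg
  pairs <- training_pairs(state)
  test <- pairs$generation == generation - 1L
  if (!any(test) || sum(!test) < cfg$surrogate$cv_folds) {
    stop("not enough completed generations to select a surrogate",
         call. = FALSE)
  }
  Xtr <- pairs$X[!test, , drop = FALSE]; ytr <- pairs$y[!test]
  Xte <- pairs$X[test, , drop = FALSE]; yte <- pairs$y[test]
  ann <- fit_ann(Xtr, ytr, cfg$surrogate)
  gpr <- fit_gpr(Xtr, ytr, cfg$surrogate)
  cv <- list(
    ann = kfold_cv(function(X, y) fit_ann(X, y, cfg$surrogate),
                   Xtr, ytr, cfg$surrogate, model_tag = "ann"),
    gpr = kfold_cv(function(X, y) fit_gpr(X, y, cfg$surrogate),
                   Xtr, ytr, cfg$surrogate, model_tag = "gpr"))
  report <- compare_models(predict(ann, Xte), predict(gpr, Xte), yte,
                           tags = c("ann", "gpr"), cv = cv,
                           eq_cfg = cfg$equivalence)
  tag <- report$selected
  if (is.na(tag)) {
    tag <- names(which.min(vapply(cv, `[[`, numeric(1), "mean_mse")))
  }
  state$model_tag <- tag
  state$selection_report <- report
  state
}

#' Advance a campaign by one generation
#'
#' Proposes DE trial vectors from the current population (several
#' oversampled batches once the surrogate is active, screened down to the
#' generation's batch size), obtains motility records from the configured
#' lab, scores both parents and trials under the scheduled metric, applies
#' pooled top-N selection, and appends to the ledgers. Scheduled component
#' removals are applied before proposing.
#'
#' @param state a `campaign_state`.
#' @param records external-lab motility records for the proposed batch
#'   (required in external mode; ignored in virtual mode).
#' @return the advanced `campaign_state`.
#' @export
run_generation <- function(state, records = NULL) {
  cfg <- state$cfg
  gen <- state$generation + 1L
  removed <- cfg$removals[[as.character(gen)]]
  if (!is.null(removed)) {
    for (nm in removed) {
      state$space <- deactivate_component(state$space, nm, 0)
      state$pop$X[, nm] <- 0
    }
  }
  metric <- active_metric(cfg, gen)
  surrogate_on <- gen >= cfg$surrogate_start
  set.seed(substream_seed(cfg$seed, gen, "propose"))
  n_batches <- if (surrogate_on) cfg$de$candidate_oversampling else 1L
  batches <- lapply(seq_len(n_batches), function(b) {
    mutate_rand_1_bin(state$pop, cfg$de, state$space,
                      generation = gen, batch = b)
  })
  trials <- if (n_batches == 1L) batches[[1L]] else
    do.call(bind_populations, c(batches, list(generation = gen)))
  if (surrogate_on) {
    if (is.null(state$model_tag)) state <- select_surrogate(state, gen)
    pairs <- training_pairs(state)
    set.seed(substream_seed(cfg$seed, gen, "surrogate"))
    state$model <- fit_surrogate(state$model_tag, pairs$X, pairs$y,
                                 cfg$surrogate)
    set.seed(substream_seed(cfg$seed, gen, "screen"))
    trials <- screen_candidates(state$model, trials,
                                cfg$de$population_size, state$space)
    state$predictions <- rbind(state$predictions, data.frame(
      generation = gen, formulation_id = trials$id,
      model_tag = state$model_tag,
      predicted_motility = attr(trials, "predicted"),
      predicted_sd = attr(trials, "predicted_sd"),
      stringsAsFactors = FALSE))
  }
  if (cfg$lab$mode == "virtual") {
    records <- evaluate_virtual(state, trials, gen)
  } else {
    records <- ingest_external(records, trials, generation = gen)
  }
  state$motility <- rbind(state$motility, records)
  trials$scores <- score_ids(records, trials$id, metric)
  state$pop$scores <- score_ids(state$motility, state$pop$id, metric)
  state$pop <- if (cfg$de$selection == "pairwise" && !surrogate_on) {
    take <- trials$scores >= state$pop$scores
    sel <- state$pop
    sel$X[take, ] <- trials$X[take, ]
    sel$id[take] <- trials$id[take]
    sel$provenance[take] <- trials$provenance[take]
    sel$scores[take] <- trials$scores[take]
    sel$generation <- gen
    sel
  } else {
    select_top(state$pop, trials, cfg$de$population_size)
  }
  state$generation <- gen
  state$formulations <- rbind(state$formulations,
                              population_ledger(trials),
                              control_ledger_row(state$space, gen,
                                                 state$control))
  state$summary <- rbind(state$summary, summary_row(state, gen, metric))
  if (cfg$check_convergence && gen >= cfg$convergence_check_from &&
      gen >= cfg$convergence_window) {
    gens <- (gen - cfg$convergence_window + 1L):gen
    groups <- lapply(gens, function(g) {
      recs <- state$motility[state$motility$generation == g &
                               state$motility$formulation_id != "control", ,
                             drop = FALSE]
      pooled_metric_values(recs, "total")$value
    })
    state$converged <- isTRUE(check_convergence(groups,
                                                cfg$convergence_alpha))
  }
  state
}

#' Validate externally supplied motility records
#'
#' Checks an external lab's results against the proposed batch: schema,
#' motility range `[0, 100]` (violations reported with row numbers),
#' coverage of every proposed formulation, and presence of control records
#' for every bull (the relative metric is undefined without them).
#'
#' @param records data frame in the motility-record schema.
#' @param proposals the proposed `population` (or character ids).
#' @param generation generation stamp the records must carry.
#' @return the validated records, invisibly usable downstream.
#' @export
ingest_external <- function(records, proposals, generation = NULL) {
  needed <- c("formulation_id", "bull_id", "replicate", "total_motility",
              "control_motility")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("ingest error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$generation)) records$generation <- generation %||% NA
  bad <- which(records$total_motility < 0 | records$total_motility > 100 |
                 records$control_motility < 0 |
                 records$control_motility > 100)
  if (length(bad) > 0) {
    stop("ingest error: motility outside [0, 100] in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids <- if (inherits(proposals, "population")) proposals$id
         else as.character(proposals)
  missing_ids <- setdiff(ids, records$formulation_id)
  if (length(missing_ids) > 0) {
    stop("ingest error: no motility for proposed formulation(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  bulls <- unique(records$bull_id)
  ctrl_bulls <- unique(records$bull_id[records$formulation_id == "control"])
  no_ctrl <- setdiff(bulls, ctrl_bulls)
  if (length(no_ctrl) > 0) {
    stop("ingest error: missing control records for bull(s): ",
         paste(no_ctrl, collapse = ", "),
         " (relative metric undefined)", call. = FALSE)
  }
  records
}

#' Run a campaign end to end
#'
#' Loops [run_generation()] from a fresh [init_campaign()] until the plateau
#' convergence criterion fires or the generation cap is reached, then
#' assembles the final report: the generational median +/- SD trajectory,
#' the top-5 media ranked by relative motility, and the equivalence
#' comparison of the final generation against the control.
#'
#' @param cfg a [campaign_config()].
#' @param max_generations optional override of the cap.
#' @return a `campaign_report` list with `state`, `summary`, `top_media`,
#'   `control_comparison` and `converged`.
#' @export
run_campaign <- function(cfg, max_generations = cfg$max_generations) {
  state <- init_campaign(cfg)
  while (state$generation < max_generations && !state$converged) {
    state <- run_generation(state)
  }
  campaign_report(state)
}

#' Continue a campaign from a saved state
#'
#' Because every stage reseeds from `(seed, generation, stage)`, resuming
#' reproduces exactly the ledgers an uninterrupted run would have written.
#'
#' @param state a `campaign_state`.
#' @param max_generations generation cap to run to.
#' @return a `campaign_report`.
#' @export
resume_campaign <- function(state,
                            max_generations = state$cfg$max_generations) {
  while (state$generation < max_generations && !state$converged) {
    state <- run_generation(state)
  }
  campaign_report(state)
}

campaign_report <- function(state) {
  top <- rank_top_media(state, k = 5)
  final_gen <- state$generation
  recs <- state$motility[state$motility$generation == final_gen, ,
                         drop = FALSE]
  trt <- pooled_metric_values(
    recs[recs$formulation_id != "control", , drop = FALSE], "total")$value
  ctl <- pooled_metric_values(
    recs[recs$formulation_id == "control", , drop = FALSE], "total")$value
  control_comparison <- tryCatch(
    mann_whitney_equivalence(trt, ctl, state$cfg$equivalence),
    error = function(e) NULL)
  structure(list(state = state, summary = state$summary,
                 top_media = top, control_comparison = control_comparison,
                 converged = state$converged,
                 selection_report = state$selection_report),
            class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("Campaign finished at generation", x$state$generation,
      if (x$converged) "(converged)\n" else "(generation cap)\n")
  print(x$summary, row.names = FALSE)
  cat("\nTop media (by mean relative total motility):\n")
  print(x$top_media$summary, row.names = FALSE)
  cat(sprintf("\nTop-5 vs control: %.1f%% vs %.1f%% (%.1f%% improvement)\n",
              x$top_media$mean_treatment, x$top_media$mean_control,
              x$top_media$improvement_pct))
  if (!is.null(x$control_comparison)) print(x$control_comparison)
  invisible(x)
}

#' Rank the campaign's top media
#'
#' Ranks every tested formulation by its mean relative total motility across
#' its tested bulls and returns the top `k`, with per-formulation mean
#' treatment and control motility and the overall percent improvement of
#' the top set over its matched controls.
#'
#' @param state a `campaign_state` or `campaign_report`, or a motility
#'   record data frame.
#' @param k media to keep (a warning is issued and the full pool returned
#'   when fewer exist).
#' @return list with `summary` (one row per top formulation),
#'   `formulations` (their concentration rows, when available),
#'   `mean_treatment`, `mean_control` and `improvement_pct`.
#' @export
rank_top_media <- function(state, k = 5) {
  if (inherits(state, "campaign_report")) state <- state$state
  records <- if (is.data.frame(state)) state else state$motility
  forms <- if (is.data.frame(state)) NULL else state$formulations
  records <- records[records$formulation_id != "control", , drop = FALSE]
  t_vals <- pooled_metric_values(records, "total")
  r_vals <- pooled_metric_values(records, "relative")
  key <- t_vals$formulation_id
  per_form <- data.frame(
    formulation_id = unique(key), stringsAsFactors = FALSE)
  per_form$mean_relative <- vapply(per_form$formulation_id, function(id) {
    mean(r_vals$value[key == id])
  }, numeric(1))
  per_form$mean_total <- vapply(per_form$formulation_id, function(id) {
    mean(t_vals$value[key == id])
  }, numeric(1))
  per_form$mean_control <- vapply(per_form$formulation_id, function(id) {
    rows <- records$formulation_id == id
    mean(tapply(records$control_motility[rows],
                paste(records$generation[rows], records$bull_id[rows]),
                mean))
  }, numeric(1))
  if (nrow(per_form) < k) {
    warning("only ", nrow(per_form), " scored formulations available; ",
            "returning all of them")
    k <- nrow(per_form)
  }
  ord <- order(-per_form$mean_relative, per_form$formulation_id)
  top <- per_form[ord[seq_len(k)], , drop = FALSE]
  rownames(top) <- NULL
  mean_t <- mean(top$mean_total)
  mean_c <- mean(top$mean_control)
  top_forms <- NULL
  if (!is.null(forms)) {
    top_forms <- forms[match(top$formulation_id, forms$formulation_id), ,
                       drop = FALSE]
    rownames(top_forms) <- NULL
  }
  list(summary = top, formulations = top_forms,
       mean_treatment = mean_t, mean_control = mean_c,
       improvement_pct = percent_improvement(mean_t, mean_c))
}

#' Percent improvement of a treatment mean over a control mean
#'
#' `100 * (treatment / control - 1)`.
#'
#' @param treatment_mean,control_mean mean motilities \%.
#' @return percent improvement.
#' @export
percent_improvement <- function(treatment_mean, control_mean) {
  100 * (treatment_mean / control_mean - 1)
}

#' Write campaign ledgers to CSV
#'
#' Writes `formulations.csv`, `motility.csv`, `predictions.csv` and
#' `summary.csv`. Under a fixed seed, re-running a campaign (or resuming it
#' from any prefix) reproduces these files byte for byte.
#'
#' @param state a `campaign_state` or `campaign_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ledgers <- function(state, dir) {
  if (inherits(state, "campaign_report")) state <- state$state
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(state$formulations, file.path(dir, "formulations.csv"),
                   row.names = FALSE)
  utils::write.csv(state$motility, file.path(dir, "motility.csv"),
                   row.names = FALSE)
  utils::write.csv(state$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(state$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a campaign configuration from YAML
#'
#' Reads a flat YAML file with optional blocks `de`, `surrogate`,
#' `equivalence`, `noise` and top-level campaign fields (`seed`,
#' `max_generations`, `metric_relative_from`, `surrogate_start`,
#' `bulls_per_gen`, `replicates`, `space_file`, ...).
#'
#' @param path YAML file path.
#' @return a `campaign_config`.
#' @export
load_campaign_config <- function(path) {
  y <- yaml::read_yaml(path)
  space <- if (!is.null(y$space_file)) load_space(y$space_file)
           else extender_space()
  de <- do.call(de_config, y$de %||% list())
  surrogate <- do.call(surrogate_config, y$surrogate %||% list())
  equivalence <- do.call(equivalence_config, y$equivalence %||% list())
  lab <- list(mode = y$lab_mode %||% "virtual")
  if (!is.null(y$noise)) lab$noise <- do.call(noise_model, y$noise)
  args <- y[intersect(names(y),
                      c("metric_relative_from", "surrogate_start",
                        "bulls_per_gen", "replicates", "max_generations",
                        "convergence_window", "convergence_alpha",
                        "convergence_check_from", "check_convergence",
                        "seed"))]
  do.call(campaign_config,
          c(list(space = space, de = de, surrogate = surrogate,
                 equivalence = equivalence, lab = lab), args))
}
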