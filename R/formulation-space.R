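#' Formulation spaces for extender media design
#'
#' A formulation space is the ordered set of media components being optimized,
#' each with a unit, lower/upper concentration bounds, a scalar reference
#' value (used e.g. by the late-campaign jitter) and an `active` flag.
#' Inactive ("frozen") components keep their column in every ledger; their
#' frozen value is the `reference` field (0 for components removed
#' mid-campaign).
#'
#' @param components data frame with columns `name`, `unit`, `lower`,
#'   `upper`, `reference` and optionally `active` (default `TRUE`).
#' @param version_tag free-text tag carried through serialization.
#' @return an object of class `formulation_space`.
#' @export
formulation_space <- function(components, version_tag = "v1") {
  required <- c("name", "unit", "lower", "upper", "reference")
  missing_cols <- setdiff(required, names(components))
  if (length(missing_cols) > 0L) {
    stop("space table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  if (nrow(components) < 1L) {
    stop("a formulation space needs at least one component", call. = FALSE)
  }
  if (!"active" %in% names(components)) components$active <- TRUE
  components <- components[, c(required, "active")]
  components$name <- as.character(components$name)
  components$unit <- as.character(components$unit)
  for (col in c("lower", "upper", "reference")) {
    components[[col]] <- as.numeric(components[[col]])
  }
  components$active <- as.logical(components$active)
  dup <- components$name[duplicated(components$name)]
  if (length(dup) > 0L) {
    stop("duplicate component name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(components$unit))) {
    stop("every component needs a non-empty unit", call. = FALSE)
  }
  bad <- components$lower > components$upper
  if (any(bad)) {
    stop("lower bound exceeds upper bound for: ",
         paste(components$name[bad], collapse = ", "), call. = FALSE)
  }
  bad_ref <- components$reference < components$lower |
    components$reference > components$upper
  if (any(bad_ref)) {
    stop("reference value outside bounds for: ",
         paste(components$name[bad_ref], collapse = ", "), call. = FALSE)
  }
  rownames(components) <- NULL
  structure(list(components = components, version_tag = version_tag),
            class = "formulation_space")
}

#' Load a formulation space from a delimited text table
#'
#' @param path CSV file with columns `name,unit,lower,upper,reference`
#'   and optionally `active`.
#' @param version_tag tag recorded on the loaded space.
#' @return a `formulation_space`.
#' @export
load_space <- function(path, version_tag = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  formulation_space(tab, version_tag = version_tag)
}

#' Write a formulation space back to CSV
#'
#' Round-trips exactly: `load_space(write_space(s, f))` reproduces bounds,
#' order and units.
#'
#' @param space a `formulation_space`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path) {
  utils::write.csv(space$components, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The eleven-component extender design space
#'
#' Loads the packaged design-space table: Tris, egg yolk, milk, fructose,
#' glycerol, ethylene glycol, trehalose, cholesterol-loaded cyclodextrin
#' (CLC), glutathione (frozen at 0.5 mM), melatonin and nerve growth factor
#' (NGF), with the published concentration ranges.
#'
#' @return a `formulation_space` with 11 components.
#' @export
extender_space <- function() {
  load_space(system.file("extdata", "extender_design_space.csv",
                         package = "cryoevolve"),
             version_tag = "extender-design-space")
}

#' @export
print.formulation_space <- function(x, ...) {
  cat("Formulation space [", x$version_tag, "]: ",
      nrow(x$components), " components (",
      sum(x$components$active), " active)\n", sep = "")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' @rdname formulation_space
#' @param space a `formulation_space`.
#' @export
component_names <- function(space) space$components$name

n_components <- function(space) nrow(space$components)

active_mask <- function(space) space$components$active

lower_bounds <- function(space) {
  stats::setNames(space$components$lower, space$components$name)
}

upper_bounds <- function(space) {
  stats::setNames(space$components$upper, space$components$name)
}

reference_values <- function(space) {
  stats::setNames(space$components$reference, space$components$name)
}

#' Freeze a component out of the optimization
#'
#' Deactivates a component (e.g. NGF removed mid-campaign). The component
#' keeps its column in all ledgers; its frozen value becomes `value`
#' (default 0).
#'
#' @param space a `formulation_space`.
#' @param name component name.
#' @param value frozen concentration carried by all subsequent formulations.
#' @return the modified space.
#' @export
deactivate_component <- function(space, name, value = 0) {
  i <- match(name, space$components$name)
  if (is.na(i)) stop("unknown component: ", name, call. = FALSE)
  space$components$active[i] <- FALSE
  space$components$reference[i] <- value
  space$components$lower[i] <- min(space$components$lower[i], value)
  space$components$upper[i] <- max(space$components$upper[i], value)
  space
}

#' Construct a single candidate extender formulation
#'
#' @param concentrations numeric vector aligned to the space's component
#'   order (names, if present, are checked against the space on validation).
#' @param id formulation identifier.
#' @param provenance one of `"initial"`, `"mutant"`, `"manual"`, `"control"`.
#' @return an object of class `formulation`.
#' @export
formulation <- function(concentrations, id = "f0",
                        provenance = c("initial", "mutant", "manual",
                                       "control")) {
  provenance <- match.arg(provenance)
  structure(list(id = as.character(id),
                 concentrations = as.numeric(concentrations),
                 names = names(concentrations),
                 provenance = provenance),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat("Formulation ", x$id, " (", x$provenance, ")\n", sep = "")
  v <- x$concentrations
  names(v) <- x$names
  print(v)
  invisible(x)
}

concentrations_of <- function(f) {
  if (inherits(f, "formulation")) f$concentrations else as.numeric(f)
}

check_alignment <- function(f, space) {
  conc <- concentrations_of(f)
  if (length(conc) != n_components(space)) {
    stop("formulation has ", length(conc), " concentrations but the space has ",
         n_components(space), " components", call. = FALSE)
  }
  nm <- if (inherits(f, "formulation")) f$names else names(f)
  if (!is.null(nm) && !identical(nm, component_names(space))) {
    stop("formulation component names do not match the space order",
         call. = FALSE)
  }
  conc
}

#' Validate a formulation against a space
#'
#' Returns a character vector of violations (empty when valid). Active
#' components must lie within their bounds; inactive components must carry
#' their frozen value exactly. A concentration of exactly 0 is always
#' accepted: it denotes an absent component (the split-sample control omits
#' several optimized components, and components removed mid-campaign keep a
#' zero column).
#'
#' @param f a `formulation` (or bare numeric vector in space order).
#' @param space a `formulation_space`.
#' @return character vector of violation messages.
#' @export
validate_formulation <- function(f, space) {
  conc <- check_alignment(f, space)
  comp <- space$components
  violations <- character(0)
  for (i in seq_len(nrow(comp))) {
    ci <- conc[i]
    if (ci == 0) next
    if (comp$active[i]) {
      if (ci < comp$lower[i] || ci > comp$upper[i]) {
        violations <- c(violations, sprintf(
          "%s = %g outside [%g, %g] %s",
          comp$name[i], ci, comp$lower[i], comp$upper[i], comp$unit[i]))
      }
    } else if (ci != comp$reference[i]) {
      violations <- c(violations, sprintf(
        "%s = %g but component is frozen at %g %s",
        comp$name[i], ci, comp$reference[i], comp$unit[i]))
    }
  }
  violations
}

#' Project a formulation onto the space bounds
#'
#' Coordinates of active components are clipped into `[lower, upper]`;
#' interior values are unchanged; inactive components are reset to their
#' frozen value unless already 0 (absent). Idempotent, and
#' `validate_formulation(clip_to_bounds(f, s), s)` is always empty.
#'
#' @inheritParams validate_formulation
#' @return a `formulation` with clipped concentrations.
#' @export
clip_to_bounds <- function(f, space) {
  conc <- check_alignment(f, space)
  comp <- space$components
  act <- comp$active
  conc[act] <- pmin(pmax(conc[act], comp$lower[act]), comp$upper[act])
  fix <- !act & conc != 0
  conc[fix] <- comp$reference[fix]
  if (inherits(f, "formulation")) {
    f$concentrations <- conc
    f
  } else {
    names(conc) <- comp$name
    formulation(conc, id = "clipped", provenance = "manual")
  }
}

# matrix variant used by the optimizer (rows = formulations, active cols only)
clip_matrix <- function(X, space) {
  comp <- space$components
  for (j in seq_len(ncol(X))) {
    i <- match(colnames(X)[j], comp$name)
    X[, j] <- pmin(pmax(X[, j], comp$lower[i]), comp$upper[i])
  }
  X
}

#' Default dispensing-unit conversions
#'
#' Conversion assumptions used by [to_recipe()]: percent v/v components are
#' dispensed in mL, percent w/v and mg/mL components in mg, mM components in
#' mg via molar mass or in microlitres of a concentrated stock, and NGF in
#' ng. Stock concentrations and molar masses are configurable data, not
#' hard-coded chemistry.
#'
#' @return a named list of per-component conversion settings.
#' @export
default_conversions <- function() {
  list(
    trehalose   = list(mw = 342.30),       # dihydrate-free molar mass, g/mol
    glutathione = list(stock_mM = 1000),   # dispensed as uL of 1 M stock
    melatonin   = list(stock_mM = 2500),   # dispensed as uL of 2.5 M stock
    ngf         = list(dispense = "ng")    # dispensed by mass in ng
  )
}

#' Convert a formulation to a batch recipe
#'
#' Maps per-component concentrations to dispensed amounts for a batch of
#' `batch_volume_ml` millilitres, and computes the water filler volume as the
#' batch volume minus all liquid volumes.
#'
#' @param f a `formulation`.
#' @param batch_volume_ml batch volume in mL (must be positive).
#' @param space a `formulation_space`.
#' @param conversions see [default_conversions()].
#' @return a `batch_recipe`: data frame of amounts plus water volume.
#' @export
to_recipe <- function(f, batch_volume_ml, space,
                      conversions = default_conversions()) {
  if (batch_volume_ml <= 0) stop("batch volume must be positive", call. = FALSE)
  conc <- check_alignment(f, space)
  comp <- space$components
  amount <- numeric(nrow(comp))
  unit <- character(nrow(comp))
  liquid_ml <- 0
  for (i in seq_len(nrow(comp))) {
    cv <- conversions[[comp$name[i]]]
    ci <- conc[i]
    u <- comp$unit[i]
    if (!is.null(cv$dispense) && cv$dispense == "ng" && u == "mg_per_ml") {
      amount[i] <- ci * batch_volume_ml * 1e6
      unit[i] <- "ng"
    } else if (u == "percent_vv") {
      amount[i] <- ci / 100 * batch_volume_ml
      unit[i] <- "mL"
      liquid_ml <- liquid_ml + amount[i]
    } else if (u == "percent_wv") {
      amount[i] <- ci * 10 * batch_volume_ml  # g/100mL -> mg per batch
      unit[i] <- "mg"
    } else if (u == "mM" && !is.null(cv$stock_mM)) {
      amount[i] <- ci * batch_volume_ml / cv$stock_mM * 1000
      unit[i] <- "uL"
      liquid_ml <- liquid_ml + amount[i] / 1000
    } else if (u == "mM") {
      if (is.null(cv$mw)) {
        stop("no molar mass configured for ", comp$name[i], call. = FALSE)
      }
      amount[i] <- ci * cv$mw * batch_volume_ml / 1000
      unit[i] <- "mg"
    } else if (u == "mg_per_ml") {
      amount[i] <- ci * batch_volume_ml
      unit[i] <- "mg"
    } else {
      stop("no conversion rule for unit ", u, " (", comp$name[i], ")",
           call. = FALSE)
    }
  }
  water_ml <- batch_volume_ml - liquid_ml
  if (water_ml < -1e-9) {
    stop("infeasible recipe: liquid volumes (", signif(liquid_ml, 4),
         " mL) exceed the batch volume (", batch_volume_ml, " mL)",
         call. = FALSE)
  }
  structure(list(
    batch_volume_ml = batch_volume_ml,
    amounts = data.frame(name = comp$name, amount = amount, unit = unit,
                         stringsAsFactors = FALSE),
    water_ml = max(water_ml, 0)
  ), class = "batch_recipe")
}

#' @export
print.batch_recipe <- function(x, ...) {
  cat("Batch recipe for", x$batch_volume_ml, "mL\n")
  print(x$amounts, row.names = FALSE)
  cat("water:", signif(x$water_ml, 6), "mL\n")
  invisible(x)
}

#' The commercial control extender
#'
#' The split-sample control: a standard tris-citrate-fructose egg-yolk
#' extender (200 mM Tris, 66.7 mM citric acid, 55.5 mM fructose, 200 mL/L
#' egg yolk) with 6\% v/v glycerol, the industry-standard permeating
#' cryoprotectant level. Expressed in design-space units (fructose 55.5 mM
#' is 1.0\% w/v via its molar mass of 180.16 g/mol); the mM recipe is kept in
#' the `"recipe_mM"` attribute. The control carries provenance `"control"`
#' and is never mutated by the optimizer.
#'
#' @param space a `formulation_space` (the packaged space by default).
#' @return a `formulation` with provenance `"control"`.
#' @export
control_extender <- function(space = extender_space()) {
  recipe_mM <- c(tris = 200, citric_acid = 66.7, fructose = 55.5)
  conc <- stats::setNames(numeric(n_components(space)),
                          component_names(space))
  conc["tris"] <- 200 * 121.14 / 1e4      # mM -> % w/v equivalent
  conc["egg_yolk"] <- 20                  # 200 mL per 1 L
  conc["fructose"] <- 55.5 * 180.16 / 1e4 # = 0.99989 % w/v
  conc["glycerol"] <- 6
  f <- formulation(conc, id = "control", provenance = "control")
  attr(f, "recipe_mM") <- recipe_mM
  attr(f, "egg_yolk_ml_per_l") <- 200
  f
}

#' Size of the equivalent full-factorial design
#'
#' Number of treatment combinations a factorial screen with `levels` levels
#' per component would need over this space, the combinatorial burden the
#' evolutionary campaign avoids.
#'
#' @param levels number of levels per component (e.g. 3: zero, low, high).
#' @param space a `formulation_space`, or an integer number of components.
#' @return the number of combinations `levels ^ n_components`.
#' @export
design_space_size <- function(levels = 3, space = extender_space()) {
  n <- if (inherits(space, "formulation_space")) n_components(space)
       else as.integer(space)
  levels ^ n
}

#' Published top-five extender batch recipes
#'
#' The dispensed amounts (per roughly 10 mL batch) of the five best
#' campaign extenders, shipped as a read-only fixture.
#'
#' @return a data frame, one row per extender.
#' @export
top_extender_recipes <- function() {
  utils::read.csv(system.file("extdata", "top_extender_recipes.csv",
                              package = "cryoevolve"),
                  stringsAsFactors = FALSE)
}
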