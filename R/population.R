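#' Populations of candidate formulations
#'
#' A population is one generation's set of candidate extenders, stored as a
#' numeric matrix (rows = formulations, columns = components in space order)
#' with identifiers, provenance and optional per-formulation scores.
#'
#' @param X numeric matrix, one row per formulation, columns named by
#'   component.
#' @param generation integer generation number.
#' @param id character vector of formulation ids (defaults generated).
#' @param provenance per-row provenance label.
#' @param scores optional numeric scores aligned to rows.
#' @return an object of class `population`.
#' @export
population <- function(X, generation = 0L, id = NULL,
                       provenance = "initial", scores = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(id)) id <- sprintf("g%02d_f%02d", generation, seq_len(n))
  provenance <- rep_len(provenance, n)
  if (!is.null(scores) && length(scores) != n) {
    stop("scores must align 1:1 with members", call. = FALSE)
  }
  structure(list(generation = as.integer(generation), X = X,
                 id = as.character(id), provenance = provenance,
                 scores = scores),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population, generation ", x$generation, ": ", nrow(x$X),
      " formulations\n", sep = "")
  df <- data.frame(id = x$id, provenance = x$provenance, x$X,
                   check.names = FALSE)
  if (!is.null(x$scores)) df$score <- x$scores
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' @export
length.population <- function(x) nrow(x$X)

#' Extract one member of a population as a formulation
#'
#' @param pop a `population`.
#' @param i row index.
#' @return a `formulation`.
#' @export
member <- function(pop, i) {
  conc <- pop$X[i, ]
  formulation(conc, id = pop$id[i],
              provenance = match.arg(pop$provenance[i],
                                     c("initial", "mutant", "manual",
                                       "control")))
}

#' Bind populations row-wise
#'
#' @param ... populations sharing a component layout.
#' @param generation generation label of the result.
#' @return a `population`.
#' @export
bind_populations <- function(..., generation = NULL) {
  pops <- list(...)
  generation <- generation %||% pops[[1]]$generation
  scores <- lapply(pops, `[[`, "scores")
  have_scores <- all(!vapply(scores, is.null, logical(1)))
  population(do.call(rbind, lapply(pops, `[[`, "X")),
             generation = generation,
             id = unlist(lapply(pops, `[[`, "id")),
             provenance = unlist(lapply(pops, `[[`, "provenance")),
             scores = if (have_scores) unlist(scores) else NULL)
}

#' Convert a population to a ledger data frame
#'
#' @param pop a `population`.
#' @return data frame with `generation`, `formulation_id`, `provenance` and
#'   one column per component.
#' @export
population_ledger <- function(pop) {
  data.frame(generation = pop$generation, formulation_id = pop$id,
             provenance = pop$provenance, pop$X,
             check.names = FALSE, stringsAsFactors = FALSE)
}
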