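#' Reaction path of stationary points
#'
#' An ordered sequence of stationary points for one surface reaction case
#' (reactant complex, transition state(s), intermediate(s), product complex),
#' with a declared zero-energy reference node. Elementary steps are the
#' minimum -> TS -> minimum triples; a junction between two adjacent minima
#' with no TS in between must be flagged barrierless.
#'
#' @param case_label Case identifier, e.g. `"(120)BC"`.
#' @param nodes List of [species()] in path order.
#' @param reference_index 1-based index of the zero-energy reference node.
#' @param step_labels Optional character vector naming each elementary step
#'   (e.g. `"dept"`, `"CC"`); length = number of steps.
#' @param barrierless Optional logical vector, one entry per adjacent
#'   minimum/minimum junction, flagging steps with no located TS.
#' @return An object of class `reaction_path`.
#' @export
reaction_path <- function(case_label, nodes, reference_index = 1L,
                          step_labels = NULL, barrierless = NULL) {
  if (length(nodes) < 2L) stop("reaction_path: need at least 2 nodes")
  lapply(nodes, validate_species)
  n <- length(nodes)
  if (reference_index < 1L || reference_index > n)
    stop("reaction_path: reference_index out of range")
  roles <- vapply(nodes, function(s) s$role, "")
  is_ts <- roles == "transition_state"
  if (is_ts[1] || is_ts[n])
    stop("reaction_path: transition states cannot be first or last node")
  if (any(is_ts & c(FALSE, is_ts[-n])))
    stop("reaction_path: two adjacent transition states")
  # adjacent minima must be explicitly barrierless
  min_pairs <- which(!is_ts[-n] & !is_ts[-1])
  if (length(min_pairs) > 0 && is.null(barrierless))
    stop("reaction_path: adjacent minima at positions ",
         paste(min_pairs, collapse = ","),
         " require a 'barrierless' flag")
  n_steps <- sum(is_ts) + length(min_pairs)
  if (!is.null(step_labels) && length(step_labels) != n_steps)
    stop("reaction_path: expected ", n_steps, " step labels")
  structure(
    list(case_label = case_label, nodes = nodes,
         reference_index = as.integer(reference_index),
         step_labels = step_labels, barrierless = barrierless),
    class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  roles <- vapply(x$nodes, function(s) s$role, "")
  labs <- vapply(x$nodes, function(s) s$label, "")
  cat("<reaction_path> ", x$case_label, ": ",
      paste(labs, collapse = " -> "), "\n", sep = "")
  cat("  reference: node ", x$reference_index,
      " (", labs[x$reference_index], ")\n", sep = "")
  invisible(x)
}

#' Elementary steps of a reaction path
#'
#' Decomposes a path into elementary steps. Each step is a list with the
#' indices of the pre-reaction minimum (`from`), the transition state (`ts`,
#' `NA` for barrierless steps), and the following minimum (`to`), plus the
#' step label.
#'
#' @param path A [reaction_path()].
#' @return List of step descriptors in path order.
#' @export
path_steps <- function(path) {
  roles <- vapply(path$nodes, function(s) s$role, "")
  is_ts <- roles == "transition_state"
  mins <- which(!is_ts)
  steps <- list()
  k <- 0L
  for (i in seq_len(length(mins) - 1L)) {
    a <- mins[i]; b <- mins[i + 1L]
    k <- k + 1L
    steps[[k]] <- list(
      from = a,
      ts = if (b - a == 2L) a + 1L else NA_integer_,
      to = b,
      label = if (!is.null(path$step_labels)) path$step_labels[k]
              else paste0("step", k))
  }
  steps
}
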