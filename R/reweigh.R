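# Pre-processing bias mitigation: (intersectional) reweighing ----------------
#
# Each (subgroup, outcome) cell receives the weight
#     w(s, y) = P(s) * P(y) / P(s, y)
# computed from empirical frequencies, which makes subgroup membership and
# outcome independent under the weighted distribution and hence drives the
# weighted statistical parity difference to exactly zero. With one sensitive
# attribute this is classical group-fairness reweighing; with several, the
# attribute tuple is treated as a single compound subgroup, which also zeroes
# the weighted SPD of every attribute marginal.

interaction_key <- function(cohort, attributes) {
  cols <- lapply(attributes, function(a) {
    col <- cohort[[a]]
    if (is.null(col)) stop("sensitive attribute '", a, "' not in cohort")
    as.character(col)
  })
  do.call(paste, c(cols, sep = ":"))
}

#' Statistical parity difference
#'
#' The (optionally weighted) difference in positive-outcome probability
#' between the two levels of a sensitive attribute; 0 indicates parity.
#' By default the levels are ordered by ascending frequency (minority level
#' first), so the value is P(outcome = 1 | minority) - P(outcome = 1 |
#' majority); pass `levels` to fix another ordering.
#'
#' @param cohort a data.frame with the attribute and an `outcome` column.
#' @param attr name of a binary sensitive attribute.
#' @param weights optional non-negative row weights; unweighted when absent.
#' @param levels optional length-2 character vector fixing the (A, B) order
#'   of the difference P(pos | A) - P(pos | B).
#' @return A single number in [-1, 1].
#' @export
statistical_parity_difference <- function(cohort, attr, weights = NULL,
                                          levels = NULL) {
  g <- as.character(cohort[[attr]])
  if (is.null(cohort[[attr]])) stop("attribute '", attr, "' not in cohort")
  obs <- unique(g)
  if (length(obs) != 2) {
    stop("attribute '", attr, "' must have exactly 2 observed levels")
  }
  if (is.null(levels)) {
    counts <- table(g)
    levels <- names(sort(counts))  # ascending frequency: minority first
  } else {
    stopifnot(length(levels) == 2, all(levels %in% obs))
  }
  if (is.null(weights)) weights <- rep(1, nrow(cohort))
  stopifnot(length(weights) == nrow(cohort), all(weights >= 0))
  y <- cohort$outcome
  rate <- function(lev) {
    sel <- g == lev
    if (!any(sel)) stop("attribute level '", lev, "' has no rows")
    sum(weights[sel] * y[sel]) / sum(weights[sel])
  }
  rate(levels[1]) - rate(levels[2])
}

#' Reweigh a cohort for (intersectional) statistical parity
#'
#' Computes the per-(subgroup, outcome) weight coefficients
#' `w(s, y) = P(s) P(y) / P(s, y)` over the Cartesian product of the given
#' sensitive attributes and expands them to a per-row weight vector. With
#' `attributes = "race"` this is single-attribute group reweighing; with
#' `attributes = c("race", "gender")` the race-gender intersections are the
#' subgroups, guarding against fairness gerrymandering on the intersections.
#'
#' Every observed (subgroup, outcome) cell must be non-empty: an empty cell
#' would require an infinite weight and raises an error naming the cell
#' rather than smoothing silently.
#'
#' @param cohort a data.frame with the attributes and an `outcome` column.
#' @param attributes character vector of sensitive attribute names (the
#'   order only affects cell labels).
#' @return An object of class `reweigh_result`: `cell_weights` (data.frame
#'   of subgroup, outcome, weight), `row_weights` (mean 1 by construction),
#'   and per-attribute `spd_before` / `spd_after`.
#' @export
reweigh <- function(cohort, attributes) {
  stopifnot(length(attributes) >= 1)
  n <- nrow(cohort)
  s <- interaction_key(cohort, attributes)
  y <- cohort$outcome
  stopifnot(all(y %in% c(0L, 1L)))
  p_s <- table(s) / n
  p_y <- table(y) / n
  cells <- expand.grid(subgroup = names(p_s), outcome = names(p_y),
                       stringsAsFactors = FALSE)
  key <- paste(s, y, sep = "|")
  n_cell <- table(key)
  cell_key <- paste(cells$subgroup, cells$outcome, sep = "|")
  missing <- cell_key[!cell_key %in% names(n_cell)]
  if (length(missing)) {
    stop("empty (subgroup, outcome) cell(s): ",
         paste(missing, collapse = ", "),
         "; coarsen the sensitive specification instead of smoothing")
  }
  p_sy <- as.numeric(n_cell[cell_key]) / n
  cells$weight <- as.numeric(p_s[cells$subgroup]) *
    as.numeric(p_y[cells$outcome]) / p_sy
  row_weights <- cells$weight[match(key, cell_key)]
  spd_before <- vapply(attributes, function(a)
    statistical_parity_difference(cohort, a), numeric(1))
  spd_after <- vapply(attributes, function(a)
    statistical_parity_difference(cohort, a, weights = row_weights),
    numeric(1))
  structure(list(attributes = attributes,
                 cell_weights = cells,
                 row_weights = row_weights,
                 spd_before = spd_before,
                 spd_after = spd_after),
            class = "reweigh_result")
}

#' @export
print.reweigh_result <- function(x, ...) {
  cat("Reweighing over", paste(x$attributes, collapse = " x "), "\n")
  print(x$cell_weights, row.names = FALSE)
  cat("SPD before:", format(x$spd_before, digits = 4),
      " after:", format(x$spd_after, digits = 4), "\n")
  invisible(x)
}

#' Attach reweighing weights to a cohort
#'
#' Adds (or replaces) a `.weight` column holding each row's cell weight.
#' Idempotent; the input cohort is not modified in place.
#'
#' @param cohort the cohort the weights were computed on.
#' @param result a `reweigh_result` (or a bare numeric vector of weights).
#' @return The cohort with a `.weight` column.
#' @export
apply_weights <- function(cohort, result) {
  w <- if (inherits(result, "reweigh_result")) result$row_weights else result
  if (length(w) != nrow(cohort)) {
    stop("weight vector length ", length(w), " does not match cohort rows ",
         nrow(cohort))
  }
  cohort$.weight <- w
  cohort
}

#' Serialize a reweighing result to JSON
#' @param result a `reweigh_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reweigh_result <- function(result, path) {
  jsonlite::write_json(list(attributes = result$attributes,
                            cell_weights = result$cell_weights,
                            spd_before = as.list(result$spd_before),
                            spd_after = as.list(result$spd_after)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
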