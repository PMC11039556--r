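#' Momentary symptom series for one participant
#'
#' Holds one participant's T x p matrix of momentary symptom composites on
#' the fixed beep grid, with missing beeps as all-`NA` rows. Rows are indexed
#' by the global beep index t = 1..max_assessments; `day` and `beep` locate
#' each row on the calendar grid.
#'
#' @param id Participant identifier.
#' @param values T x p numeric matrix (missing beeps = `NA` rows).
#' @param design A [study_design()]; `nrow(values)` must equal
#'   `design$max_assessments`.
#' @param variables Optional character vector of variable names; defaults to
#'   the six depressive symptom composites when p = 6.
#' @return An object of class `symptom_series` with fields `id`, `values`,
#'   `day`, `beep`, `t`, `design`, `variables` and `n_completed` (number of
#'   beeps with at least one observed value).
#' @export
symptom_series <- function(id, values, design = study_design(),
                           variables = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != design$max_assessments)
    stop(sprintf("series must have %d rows (one per beep), got %d",
                 design$max_assessments, nrow(values)))
  p <- ncol(values)
  if (is.null(variables)) {
    variables <- if (p == 6L) symptom_names() else paste0("v", seq_len(p))
  }
  if (length(variables) != p) stop("variables must name every column")
  colnames(values) <- variables
  t_idx <- seq_len(nrow(values))
  structure(
    list(
      id = id,
      values = values,
      day = ((t_idx - 1L) %/% design$beeps_per_day) + 1L,
      beep = ((t_idx - 1L) %% design$beeps_per_day) + 1L,
      t = t_idx,
      design = design,
      variables = variables,
      n_completed = sum(rowSums(!is.na(values)) > 0L)
    ),
    class = "symptom_series"
  )
}

#' The six depressive symptom composites
#'
#' Node order used throughout: anhedonia, depressed mood, appetite change,
#' restlessness, irritability, lethargy.
#' @return Character vector of length 6.
#' @export
symptom_names <- function() {
  c("anhedonia", "depressed_mood", "appetite_change",
    "restlessness", "irritability", "lethargy")
}

#' @export
print.symptom_series <- function(x, ...) {
  cat(sprintf("symptom_series '%s': %d beeps, %d completed, %d variables\n",
              as.character(x$id), nrow(x$values), x$n_completed,
              ncol(x$values)))
  invisible(x)
}

#' Extract the observation matrix from a series-like object
#'
#' Accepts a `symptom_series`, `detrended_series` or plain matrix and returns
#' the T x p numeric matrix with `NA` for missing values.
#' @param x Series-like object.
#' @return Numeric matrix.
#' @keywords internal
series_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, c("symptom_series", "detrended_series"))) return(x$values)
  stop("expected a symptom_series, detrended_series or matrix")
}

#' Detrended symptom series
#'
#' As [symptom_series()], but on the residual scale after removal of
#' per-variable cubic polynomial trends; carries the fitted trend
#' coefficients and, once screened, the per-variable stationarity verdicts.
#' Created by [detrend()].
#'
#' @name detrended_series
NULL

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("detrended_series '%s': %d beeps, %d completed, %d variables\n",
              as.character(x$id), nrow(x$values), x$n_completed,
              ncol(x$values)))
  if (!is.null(x$stationarity))
    cat(sprintf("  stationarity screen: %s\n",
                if (isTRUE(x$stationarity$pass)) "pass" else "FAIL"))
  invisible(x)
}
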