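#' Remove polynomial time trends from a symptom series
#'
#' Fits, for each variable, an ordinary least-squares cubic polynomial in
#' the global beep index (orthogonal polynomial basis, i.e. centered and
#' scaled, for numerical stability) over the observed beeps only, and
#' replaces values by the residuals. Trends are always removed — the lag-1
#' network model assumes a stationary mean, and removing a null trend is
#' harmless (the fitted coefficients are reported as diagnostics). Missing
#' beeps stay missing; the beep grid (including missing slots) is the time
#' axis.
#'
#' @param series A [symptom_series()] (or `detrended_series`; detrending is
#'   idempotent up to numerical tolerance).
#' @param degree Polynomial degree (default 3: linear, quadratic, cubic).
#' @param min_obs Minimum observed points per variable (default 8, enough
#'   for a cubic fit with residual degrees of freedom).
#' @return A `detrended_series`: as the input but with residual-scale
#'   values, plus `trend` (per-variable coefficient matrix on the raw
#'   polynomial basis, intercept first) and `trend_fitted`.
#' @export
detrend <- function(series, degree = 3L, min_obs = 8L) {
  Y <- series_matrix(series)
  p <- ncol(Y)
  t_idx <- seq_len(nrow(Y))
  res <- Y
  coefs <- matrix(NA_real_, p, degree + 1L,
                  dimnames = list(colnames(Y),
                                  c("intercept", paste0("t^", seq_len(degree)))))
  for (j in seq_len(p)) {
    obs <- which(!is.na(Y[, j]))
    if (length(obs) < min_obs)
      stop(sprintf("variable %d has %d observed points; need >= %d for a degree-%d fit",
                   j, length(obs), min_obs, degree))
    # raw-polynomial fit on a centered/scaled index is numerically fine at T<=140
    tt <- (t_idx[obs] - mean(t_idx)) / stats::sd(t_idx)
    X <- stats::poly(tt, degree, raw = TRUE)
    fit <- stats::lm.fit(cbind(1, X), Y[obs, j])
    res[obs, j] <- fit$residuals
    coefs[j, ] <- fit$coefficients
  }
  out <- list(
    id = if (is.matrix(series)) "series" else series$id,
    values = res,
    day = if (is.matrix(series)) NULL else series$day,
    beep = if (is.matrix(series)) NULL else series$beep,
    t = t_idx,
    design = if (is.matrix(series)) NULL else series$design,
    variables = colnames(Y),
    n_completed = sum(rowSums(!is.na(res)) > 0L),
    trend = coefs,
    degree = degree,
    stationarity = if (is.matrix(series)) NULL else series$stationarity
  )
  class(out) <- "detrended_series"
  out
}

#' Dickey-Fuller unit-root test statistic (constant, no trend)
#'
#' Regression of the first difference on the lagged level plus `lags` lagged
#' differences and an intercept, using only time points whose required lags
#' are all observed ("listwise lag pairing" across gaps). The 5%/1%/10%
#' critical values use the MacKinnon (2010) finite-sample response surface
#' for the constant-only case.
#'
#' @param y Numeric vector on an equally spaced grid, `NA` for missing.
#' @param lags Number of augmentation lags (default 0: plain Dickey-Fuller).
#' @param alpha Significance level (0.01, 0.05 or 0.10).
#' @return List with `statistic`, `critical`, `reject` (TRUE = unit root
#'   rejected, i.e. evidence of stationarity), `n_used`.
#' @export
adf_statistic <- function(y, lags = 0L, alpha = 0.05) {
  surf <- switch(as.character(alpha),
    "0.01" = c(-3.43035, -6.5393, -16.786, -79.433),
    "0.05" = c(-2.86154, -2.8903, -4.234, -40.04),
    "0.1"  = c(-2.56677, -1.5384, -2.809, 0),
    stop("alpha must be 0.01, 0.05 or 0.10"))
  n <- length(y)
  t_all <- (lags + 2L):n
  ok <- vapply(t_all, function(t) {
    all(!is.na(y[(t - lags - 1L):t]))
  }, logical(1))
  t_use <- t_all[ok]
  if (length(t_use) < 10L + lags)
    return(list(statistic = NA_real_, critical = NA_real_, reject = FALSE,
                n_used = length(t_use), reason = "too few paired observations"))
  dy <- y[t_use] - y[t_use - 1L]
  ylag <- y[t_use - 1L]
  X <- cbind(1, ylag)
  if (lags > 0L)
    for (j in seq_len(lags)) X <- cbind(X, y[t_use - j] - y[t_use - j - 1L])
  if (stats::sd(ylag) < 1e-12)
    return(list(statistic = NA_real_, critical = NA_real_, reject = FALSE,
                n_used = length(t_use), reason = "zero variance"))
  fit <- stats::lm.fit(X, dy)
  rss <- sum(fit$residuals^2)
  df <- length(dy) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[2L, 2L])
  stat <- fit$coefficients[2L] / se
  Tn <- length(dy)
  crit <- surf[1] + surf[2] / Tn + surf[3] / Tn^2 + surf[4] / Tn^3
  list(statistic = unname(stat), critical = crit,
       reject = unname(stat < crit), n_used = Tn)
}

#' Screen a detrended series for stationarity
#'
#' Applies the Dickey-Fuller test to every variable; a variable passes when
#' the unit-root null is rejected at level `alpha`. The participant passes
#' only if every variable passes; constant (zero-variance) variables fail
#' with an explicit reason. Failing participants are meant to be flagged for
#' exclusion by the caller, never silently dropped.
#'
#' @param series A `detrended_series` (see [detrend()]).
#' @param alpha Significance level (default 0.05).
#' @param lags Augmentation lags for [adf_statistic()].
#' @return The input with a `stationarity` field: list with per-variable
#'   `table` (statistic, critical, reject, reason) and overall `pass`.
#' @export
stationarity_screen <- function(series, alpha = 0.05, lags = 0L) {
  if (!inherits(series, "detrended_series"))
    stop("stationarity_screen expects a detrended series")
  Y <- series$values
  rows <- lapply(seq_len(ncol(Y)), function(j) {
    r <- adf_statistic(Y[, j], lags = lags, alpha = alpha)
    data.frame(variable = colnames(Y)[j], statistic = r$statistic,
               critical = r$critical, pass = r$reject,
               reason = if (is.null(r$reason)) "" else r$reason,
               n_used = r$n_used, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  series$stationarity <- list(table = tab, pass = all(tab$pass),
                              alpha = alpha)
  series
}
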