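#' Sampling design of an EMA study
#'
#' Describes the fixed beep grid of an ecological momentary assessment (EMA)
#' study: `beeps_per_day` prompts per day at `inter_beep_hours` intervals over
#' `n_days` days. The default mirrors a 28-day protocol with 5 beeps per day
#' every 3 hours, i.e. a maximum of 140 assessments per participant.
#'
#' @param n_days Number of study days (default 28).
#' @param beeps_per_day Number of beeps per day (default 5).
#' @param inter_beep_hours Hours between consecutive beeps within a day
#'   (default 3); metadata only, the model operates on the beep index.
#' @return An object of class `study_design` with fields `n_days`,
#'   `beeps_per_day`, `inter_beep_hours` and the derived `max_assessments`.
#' @examples
#' d <- study_design()
#' d$max_assessments  # 140
#' @export
study_design <- function(n_days = 28L, beeps_per_day = 5L, inter_beep_hours = 3) {
  n_days <- as.integer(n_days)
  beeps_per_day <- as.integer(beeps_per_day)
  if (n_days < 1L || beeps_per_day < 1L)
    stop("n_days and beeps_per_day must be >= 1")
  if (!is.finite(inter_beep_hours) || inter_beep_hours <= 0)
    stop("inter_beep_hours must be positive")
  structure(
    list(
      n_days = n_days,
      beeps_per_day = beeps_per_day,
      inter_beep_hours = inter_beep_hours,
      max_assessments = n_days * beeps_per_day
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "EMA study design: %d days x %d beeps/day (every %g h) = %d max assessments\n",
    x$n_days, x$beeps_per_day, x$inter_beep_hours, x$max_assessments
  ))
  invisible(x)
}

#' Missingness specification for simulated beeps
#'
#' Whole-beep missing-completely-at-random: each beep is missing (all
#' variables at once, as when a questionnaire link expires unanswered) with
#' probability `beep_missing_prob`, independently across beeps. The default
#' 0.18 reproduces the mean completion of roughly 115 of 140 beeps observed
#' in 28-day, 5-beep protocols.
#'
#' @param beep_missing_prob Probability in \[0, 1\] that a beep is missing.
#' @param mechanism Missingness mechanism; only `"MCAR"` is supported.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(beep_missing_prob = 0.18, mechanism = "MCAR") {
  mechanism <- match.arg(mechanism, "MCAR")
  if (!is.numeric(beep_missing_prob) || length(beep_missing_prob) != 1L ||
      is.na(beep_missing_prob) || beep_missing_prob < 0 || beep_missing_prob > 1)
    stop("beep_missing_prob must be a single probability in [0, 1]")
  structure(
    list(beep_missing_prob = beep_missing_prob, mechanism = mechanism),
    class = "missingness_spec"
  )
}

#' Polynomial trend specification
#'
#' Deterministic per-variable trends in the global beep index t, added on top
#' of the stationary GVAR process: `mu_v(t) = linear*t + quadratic*t^2 +
#' cubic*t^3`. All-zero coefficients (the default) give a trend-free series.
#'
#' @param p Number of variables.
#' @param linear,quadratic,cubic Numeric vectors of length 1 or `p` giving
#'   the per-variable coefficients (VAS units per beep-index power).
#' @return An object of class `trend_spec`: a `p` x 3 coefficient matrix.
#' @export
trend_spec <- function(p = 6L, linear = 0, quadratic = 0, cubic = 0) {
  co <- cbind(
    linear = rep_len(linear, p),
    quadratic = rep_len(quadratic, p),
    cubic = rep_len(cubic, p)
  )
  if (!all(is.finite(co))) stop("trend coefficients must be finite")
  structure(co, class = c("trend_spec", class(co)))
}

#' Evaluate a trend specification on a beep-index grid
#' @param trend A [trend_spec()].
#' @param t Integer vector of beep indices.
#' @return A `length(t)` x `p` matrix of trend values.
#' @keywords internal
trend_values <- function(trend, t) {
  X <- cbind(t, t^2, t^3)
  X %*% t(unclass(trend))
}

#' Ground-truth person-specific GVAR model
#'
#' Container for the data-generating process of one person: mean vector
#' `mu`, lag-1 temporal coefficient matrix `B` (entry \eqn{b_{ij}} = effect
#' of variable j at t-1 on variable i at t) and residual precision matrix
#' `K`. Validates stationarity (spectral radius of `B` strictly below 1) and
#' positive definiteness of `K`.
#'
#' @param mu Mean vector (length p).
#' @param B p x p temporal coefficient matrix with spectral radius < 1.
#' @param K p x p symmetric positive definite residual precision matrix.
#' @return An object of class `true_gvar`.
#' @export
true_gvar <- function(mu, B, K) {
  mu <- as.numeric(mu)
  B <- as.matrix(B)
  K <- as.matrix(K)
  p <- length(mu)
  if (!all(dim(B) == p) || !all(dim(K) == p))
    stop("mu, B and K must have matching dimension")
  sr <- spectral_radius(B)
  if (sr >= 1)
    stop(sprintf("temporal matrix is non-stationary (spectral radius %.3f >= 1)", sr))
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("K must be positive definite")
  structure(list(mu = mu, B = B, K = K, p = p), class = "true_gvar")
}

#' Spectral radius of a square matrix
#' @param B A square numeric matrix.
#' @return The largest eigenvalue modulus.
#' @export
spectral_radius <- function(B) {
  if (length(B) == 0L) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}
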