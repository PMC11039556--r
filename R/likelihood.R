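# Likelihood kernel for the lag-1 GVAR chain with whole-beep missingness.
#
# The observed beeps split the 140-slot grid into consecutive observed pairs
# separated by gaps of g >= 0 missing beeps. Under the VAR(1) recursion
# y_t = c + B y_{t-1} + e_t, e_t ~ N(0, Sigma), the distribution of an
# observed beep given the previous observed beep across a gap of g is
#   y_right | y_left ~ N( sum_{j=0}^{g} B^j c + B^{g+1} y_left, V_{g+1} ),
#   V_k = sum_{j=0}^{k-1} B^j Sigma B^j',
# so missing beeps are marginalized exactly (full-information likelihood:
# every observed value contributes, nothing is deleted).

#' @keywords internal
gvar_chain <- function(Y, warn_partial = TRUE) {
  Y <- as.matrix(Y)
  n_miss <- rowSums(is.na(Y))
  partial <- n_miss > 0L & n_miss < ncol(Y)
  if (any(partial)) {
    if (warn_partial)
      warning(sprintf("%d beep(s) with partially missing composites treated as fully missing",
                      sum(partial)))
    Y[partial, ] <- NA_real_
  }
  obs <- which(rowSums(is.na(Y)) == 0L)
  if (length(obs) < 2L) stop("need at least two observed beeps")
  gaps <- diff(obs) - 1L
  list(Y = Y, obs = obs, left = obs[-length(obs)], right = obs[-1L],
       gap = gaps, gmax = max(gaps), n_obs = length(obs),
       n_trans = obs[length(obs)] - obs[1L], p = ncol(Y))
}

# Precompute B powers, innovation covariances V_k and intercept partial sums
# up to the maximum gap in the chain.
#' @keywords internal
gvar_pre <- function(cvec, B, Sigma, gmax) {
  p <- nrow(B)
  K <- gmax + 1L
  Bpow <- vector("list", K + 1L)   # Bpow[[k+1]] = B^k
  V <- vector("list", K)           # V[[k]] = sum_{j<k} B^j Sigma B^j'
  cs <- vector("list", K)          # cs[[k]] = sum_{j<k} B^j c
  Bpow[[1L]] <- diag(p)
  acc_V <- Sigma
  acc_c <- cvec
  V[[1L]] <- acc_V
  cs[[1L]] <- acc_c
  for (k in seq_len(K)) {
    Bpow[[k + 1L]] <- Bpow[[k]] %*% B
    if (k < K) {
      Bk <- Bpow[[k + 1L]]
      acc_V <- acc_V + Bk %*% Sigma %*% t(Bk)
      acc_c <- acc_c + Bk %*% cvec
      V[[k + 1L]] <- acc_V
      cs[[k + 1L]] <- acc_c
    }
  }
  list(Bpow = Bpow, V = V, cs = cs, p = p)
}

# Conditional log-likelihood of the observed beeps given the first observed
# beep, grouped by gap length so each class shares one Cholesky factor.
#' @keywords internal
gvar_loglik_chain <- function(chain, cvec, B, Sigma) {
  pre <- gvar_pre(cvec, B, Sigma, chain$gmax)
  p <- chain$p
  ll <- 0
  for (g in sort(unique(chain$gap))) {
    sel <- chain$gap == g
    L <- chain$Y[chain$left[sel], , drop = FALSE]
    R <- chain$Y[chain$right[sel], , drop = FALSE]
    coef <- pre$Bpow[[g + 2L]]
    Vg <- pre$V[[g + 1L]]
    cg <- pre$cs[[g + 1L]]
    ch <- tryCatch(chol(Vg), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    E <- R - L %*% t(coef)
    E <- sweep(E, 2L, as.numeric(cg))
    Z <- E %*% backsolve(ch, diag(p))
    ng <- nrow(E)
    ll <- ll - ng * (0.5 * p * log(2 * pi) + sum(log(diag(ch)))) -
      0.5 * sum(Z^2)
  }
  ll
}

#' Exact Gaussian log-likelihood of a GVAR model on a series
#'
#' Evaluates the log-density of the observed beeps under the lag-1 GVAR
#' implied by (mu, B, K), with missing beeps marginalized exactly. With
#' `initial = "stationary"` (the default) the first observed beep
#' contributes its stationary marginal N(mu, S), S the solution of
#' S = B S B' + K^-1 — the exact joint density of everything observed. With
#' `initial = "conditional"` the chain is anchored at the first observed
#' beep (the convention maximized by [fit_gvar_ml()]).
#'
#' @param model A `gvar_model` or [true_gvar()] (fields mu, B, K).
#' @param series A series-like object (matrix, [symptom_series()] or
#'   detrended series); rows with any missing value are treated as missing
#'   beeps.
#' @param initial `"stationary"` or `"conditional"`.
#' @return Log-likelihood (scalar). Deterministic.
#' @export
loglik_gvar <- function(model, series, initial = c("stationary", "conditional")) {
  initial <- match.arg(initial)
  B <- model$B
  K <- model$K
  mu <- as.numeric(model$mu)
  p <- length(mu)
  Y <- series_matrix(series)
  if (ncol(Y) != p) stop("model and series dimensions differ")
  Sigma <- chol2inv(chol(K))
  cvec <- as.numeric((diag(p) - B) %*% mu)
  obs <- which(rowSums(is.na(Y)) == 0L)
  if (length(obs) < 1L) stop("no fully observed beeps")
  ll <- 0
  if (initial == "stationary") {
    if (spectral_radius(B) >= 1)
      stop("non-stationary model has no stationary initial distribution")
    Sinf <- stationary_covariance(B, Sigma)
    ch <- chol(Sinf)
    z <- backsolve(ch, Y[obs[1L], ] - mu, transpose = TRUE)
    ll <- -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  }
  if (length(obs) >= 2L) {
    chain <- gvar_chain(Y, warn_partial = FALSE)
    ll <- ll + gvar_loglik_chain(chain, cvec, B, Sigma)
  }
  ll
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation S = B S B' + Sigma via the
#' vectorized linear system (I - B (x) B) vec(S) = vec(Sigma).
#'
#' @param B Temporal coefficient matrix with spectral radius < 1.
#' @param Sigma Innovation covariance.
#' @return The stationary covariance matrix.
#' @export
stationary_covariance <- function(B, Sigma) {
  p <- nrow(B)
  if (spectral_radius(B) >= 1) stop("spectral radius must be < 1")
  vecS <- solve(diag(p^2) - kronecker(B, B), as.numeric(Sigma))
  S <- matrix(vecS, p, p)
  (S + t(S)) / 2
}

#' Partial correlations from a precision matrix
#'
#' The contemporaneous network: off-diagonal entries are
#' \eqn{\omega_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\kappa_{jj}}}, the
#' partial correlation of variables i and j given all others; the diagonal
#' is 1. Invariant to positive rescaling of K.
#'
#' @param K Symmetric positive definite precision matrix.
#' @return Partial-correlation matrix with unit diagonal.
#' @export
pcc_from_precision <- function(K) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  d <- diag(K)
  if (any(d <= 0)) stop("K must be positive definite")
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("K must be positive definite")
  Omega <- -K / sqrt(outer(d, d))
  diag(Omega) <- 1
  Omega
}
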