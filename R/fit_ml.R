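# Unregularized maximum-likelihood estimation of the person-specific GVAR
# model by EM. The complete-data model is the full lag-1 chain over the beep
# grid between the first and last observed beep; the E-step computes exact
# conditional moments of each missing block given its two observed endpoints
# (the chain is Markov, so the endpoints are sufficient), and the M-step is
# a closed-form multivariate regression on the expected sufficient
# statistics. EM ascent guarantees a monotone likelihood path; with no
# missing beeps it converges in one step to the complete-data conditional
# ML solution (lag-pair regression + residual covariance MLE).

# Expected sufficient statistics of the transitions, given observations and
# current parameters: S1 = sum E[y_t], S0 = sum E[y_{t-1}],
# S11/S00/S10 the matching second moments, n = number of transitions.
#' @keywords internal
gvar_estep <- function(chain, cvec, B, Sigma) {
  p <- chain$p
  Y <- chain$Y
  pre <- gvar_pre(cvec, B, Sigma, chain$gmax)
  S1 <- numeric(p); S0 <- numeric(p)
  S11 <- matrix(0, p, p); S00 <- matrix(0, p, p); S10 <- matrix(0, p, p)
  n <- 0L

  # adjacent observed pairs: fully vectorized
  sel <- chain$gap == 0L
  if (any(sel)) {
    Y0 <- Y[chain$left[sel], , drop = FALSE]
    Y1 <- Y[chain$right[sel], , drop = FALSE]
    S1 <- S1 + colSums(Y1); S0 <- S0 + colSums(Y0)
    S11 <- S11 + crossprod(Y1); S00 <- S00 + crossprod(Y0)
    S10 <- S10 + crossprod(Y1, Y0)
    n <- n + nrow(Y1)
  }

  # gapped pairs: conditional moments of the missing block between the two
  # observed endpoints; the gain and conditional covariance depend only on
  # the gap length, so compute them once per class
  for (g in sort(unique(chain$gap[chain$gap > 0L]))) {
    idx <- which(chain$gap == g)
    blk <- seq_len(g)
    Sxx <- matrix(0, g * p, g * p)
    Sxr <- matrix(0, g * p, p)
    for (i in blk) {
      ri <- (i - 1L) * p + seq_len(p)
      for (l in i:g) {
        cl <- (l - 1L) * p + seq_len(p)
        Cil <- pre$V[[i]] %*% t(pre$Bpow[[l - i + 1L]])
        Sxx[ri, cl] <- Cil
        if (l > i) Sxx[cl, ri] <- t(Cil)
      }
      Sxr[ri, ] <- pre$V[[i]] %*% t(pre$Bpow[[g + 1L - i + 1L]])
    }
    Srr <- pre$V[[g + 1L]]
    G <- Sxr %*% chol2inv(chol(Srr))
    Sc <- Sxx - G %*% t(Sxr)          # conditional covariance of the block
    for (jj in idx) {
      ya <- Y[chain$left[jj], ]
      yb <- Y[chain$right[jj], ]
      m <- numeric((g + 1L) * p)
      for (i in seq_len(g + 1L))
        m[(i - 1L) * p + seq_len(p)] <- pre$cs[[i]] + pre$Bpow[[i + 1L]] %*% ya
      mb <- m[seq_len(g * p)]
      mr <- m[g * p + seq_len(p)]
      mu_c <- mb + as.numeric(G %*% (yb - mr))
      MU <- matrix(mu_c, p, g)        # column i = conditional mean of slot i
      S1 <- S1 + rowSums(MU) + yb
      S0 <- S0 + ya + rowSums(MU)
      sec <- matrix(0, p, p)          # sum_i E[y_i y_i'] over the block
      for (i in blk) {
        ri <- (i - 1L) * p + seq_len(p)
        sec <- sec + Sc[ri, ri] + tcrossprod(MU[, i])
      }
      S11 <- S11 + sec + tcrossprod(yb)
      S00 <- S00 + tcrossprod(ya) + sec
      cross <- tcrossprod(MU[, 1L], ya) + tcrossprod(yb, MU[, g])
      if (g > 1L) for (i in 2:g) {
        ri <- (i - 1L) * p + seq_len(p)
        rim1 <- (i - 2L) * p + seq_len(p)
        cross <- cross + Sc[ri, rim1] + tcrossprod(MU[, i], MU[, i - 1L])
      }
      S10 <- S10 + cross
      n <- n + g + 1L
    }
  }
  list(S1 = S1, S0 = S0, S11 = S11, S00 = S00, S10 = S10, n = n)
}

# Closed-form M-step: multivariate regression of y_t on (1, y_{t-1}).
#' @keywords internal
gvar_mstep <- function(st, ridge = 0) {
  p <- length(st$S1)
  G <- rbind(c(st$n, st$S0), cbind(st$S0, st$S00))
  if (ridge > 0) G <- G + diag(c(0, rep(ridge, p)))
  Cm <- cbind(st$S1, st$S10)          # p x (1+p)
  Theta <- t(solve(G, t(Cm)))
  Sigma <- (st$S11 - Cm %*% t(Theta)) / st$n
  Sigma <- (Sigma + t(Sigma)) / 2
  list(cvec = Theta[, 1L], B = Theta[, -1L, drop = FALSE], Sigma = Sigma)
}

#' Fit a person-specific GVAR model by maximum likelihood
#'
#' Estimates means, the 6 x 6 lag-1 temporal coefficient matrix and the
#' residual precision matrix of one participant's graphical VAR by
#' full-information maximum likelihood: missing beeps are marginalized
#' exactly, every observed value contributes, nothing is listwise-deleted.
#' The likelihood is conditional on the first observed beep; estimation is
#' by EM with a closed-form M-step, so the likelihood ascends monotonically
#' and the fit is deterministic. The contemporaneous partial-correlation
#' network is derived from the precision matrix via
#' [pcc_from_precision()].
#'
#' @param series A detrended series, [symptom_series()] or plain T x p
#'   matrix with `NA` rows for missing beeps.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param min_obs Hard minimum of completed beeps (default 30; refuse
#'   below); fewer than `warn_obs` (default 75) only warns, matching the
#'   simulation-based design recommendation of 75-100 time points.
#' @param warn_obs See `min_obs`.
#' @return A `gvar_model`: list with `mu`, `intercept`, `B`, `Sigma`, `K`,
#'   `Omega` (partial correlations), `loglik` (maximized conditional
#'   log-likelihood), `n_params`, `n_obs` (completed beeps), `n_trans`,
#'   `convergence` (converged flag, iterations, last relative change) and
#'   `variables`.
#' @export
fit_gvar_ml <- function(series, tol = 1e-8, max_iter = 500L,
                        min_obs = 30L, warn_obs = 75L) {
  Y <- series_matrix(series)
  p <- ncol(Y)
  chain <- gvar_chain(Y)
  if (chain$n_obs < min_obs)
    stop(sprintf("only %d completed beeps; need >= %d for a stable fit",
                 chain$n_obs, min_obs))
  if (chain$n_obs < warn_obs)
    warning(sprintf("%d completed beeps is below the recommended minimum of %d",
                    chain$n_obs, warn_obs))
  v <- apply(chain$Y[chain$obs, , drop = FALSE], 2L, stats::var)
  if (any(v < 1e-10))
    stop("singular information: constant variable(s) ",
         paste(which(v < 1e-10), collapse = ", "))

  # initialize from available-case adjacent lag pairs
  sel <- chain$gap == 0L
  if (sum(sel) >= p + 2L) {
    st0 <- list(
      S1 = colSums(chain$Y[chain$right[sel], , drop = FALSE]),
      S0 = colSums(chain$Y[chain$left[sel], , drop = FALSE]),
      S11 = crossprod(chain$Y[chain$right[sel], , drop = FALSE]),
      S00 = crossprod(chain$Y[chain$left[sel], , drop = FALSE]),
      S10 = crossprod(chain$Y[chain$right[sel], , drop = FALSE],
                      chain$Y[chain$left[sel], , drop = FALSE]),
      n = sum(sel)
    )
    par <- tryCatch(gvar_mstep(st0, ridge = 1e-8), error = function(e) NULL)
  } else par <- NULL
  if (is.null(par) || min(eigen(par$Sigma, symmetric = TRUE,
                                only.values = TRUE)$values) <= 1e-10) {
    mu0 <- colMeans(chain$Y[chain$obs, , drop = FALSE])
    par <- list(cvec = mu0, B = matrix(0, p, p),
                Sigma = diag(apply(chain$Y[chain$obs, , drop = FALSE],
                                   2L, stats::var)))
  }

  ll_old <- gvar_loglik_chain(chain, par$cvec, par$B, par$Sigma)
  converged <- FALSE
  delta <- NA_real_
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    st <- gvar_estep(chain, par$cvec, par$B, par$Sigma)
    par_new <- gvar_mstep(st)
    ev <- min(eigen(par_new$Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(ev) || ev <= 1e-12) {
      warning("residual covariance became singular; stopping at last stable iterate")
      break
    }
    par <- par_new
    ll <- gvar_loglik_chain(chain, par$cvec, par$B, par$Sigma)
    delta <- abs(ll - ll_old) / (abs(ll_old) + 1e-10)
    ll_old <- ll
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && iter == max_iter)
    warning(sprintf("EM did not converge in %d iterations (last rel. change %.2e)",
                    max_iter, delta))
  finalize_gvar_model(par, chain, ll_old, converged, iter, delta,
                      colnames(Y),
                      id = if (is.matrix(series)) NA_character_ else series$id)
}

#' @keywords internal
finalize_gvar_model <- function(par, chain, loglik, converged, iter, delta,
                                variables, id = NA_character_) {
  p <- length(par$cvec)
  B <- par$B
  sr <- spectral_radius(B)
  if (sr >= 1) {
    warning(sprintf("estimated temporal matrix has spectral radius %.3f >= 1", sr))
    mu <- colMeans(chain$Y[chain$obs, , drop = FALSE])
  } else {
    mu <- as.numeric(solve(diag(p) - B, par$cvec))
  }
  K <- chol2inv(chol(par$Sigma))
  dimnames(B) <- list(variables, variables)
  dimnames(K) <- list(variables, variables)
  structure(
    list(
      id = id,
      mu = stats::setNames(mu, variables),
      intercept = stats::setNames(as.numeric(par$cvec), variables),
      B = B,
      Sigma = par$Sigma,
      K = K,
      Omega = pcc_from_precision(K),
      loglik = loglik,
      n_params = as.integer(p + p^2 + p * (p + 1L) / 2L),
      n_obs = chain$n_obs,
      n_trans = chain$n_trans,
      convergence = list(converged = converged, iterations = iter,
                         rel_change = delta),
      variables = variables
    ),
    class = "gvar_model"
  )
}

#' @export
print.gvar_model <- function(x, digits = 3, ...) {
  cat(sprintf("GVAR model (%d variables, %d completed beeps)\n",
              length(x$mu), x$n_obs))
  cat(sprintf("  logLik %.2f on %d parameters (AIC %.2f)\n",
              x$loglik, x$n_params, 2 * x$n_params - 2 * x$loglik))
  cat(sprintf("  temporal edges: spectral radius %.3f; converged: %s (%d iter)\n",
              spectral_radius(x$B), x$convergence$converged,
              x$convergence$iterations))
  invisible(x)
}

#' @export
logLik.gvar_model <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}
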