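# Individual Network Invariance Test (INIT): within a group of participants
# matched on symptom severity, compare the heterogeneous model (every
# member's temporal and contemporaneous edges freely estimated) against the
# homogeneous model (all edges constrained equal across members, means
# person-specific) by AIC. Lower AIC wins; exact ties resolve to
# homogeneous, keeping the test conservative.

#' A severity-matched group of participants
#'
#' @param severity Shared IDS-SR total score (integer).
#' @param series Named list (>= 2) of member series (detrended).
#' @param id Optional group label (defaults to the severity total).
#' @return An object of class `severity_group`.
#' @export
severity_group <- function(severity, series, id = NULL) {
  if (length(series) < 2L)
    stop("a severity group needs at least 2 members (matching requires a partner)")
  if (is.null(names(series))) names(series) <- paste0("m", seq_along(series))
  structure(
    list(id = if (is.null(id)) as.character(severity) else id,
         severity = as.integer(severity), series = series,
         size = length(series)),
    class = "severity_group"
  )
}

#' Fit the heterogeneous (free) group model
#'
#' Every member's GVAR is estimated independently; the pooled log-likelihood
#' is the sum of member log-likelihoods and the parameter count the sum of
#' member counts (p + p^2 + p(p+1)/2 each).
#'
#' @param group A [severity_group()].
#' @param ... Passed to [fit_gvar_ml()].
#' @return List with `models` (per member), `loglik`, `n_params`.
#' @export
fit_group_free <- function(group, ...) {
  models <- lapply(names(group$series), function(id) {
    tryCatch(fit_gvar_ml(group$series[[id]], ...),
             error = function(e) stop(sprintf("member '%s': %s", id,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  names(models) <- names(group$series)
  list(models = models,
       loglik = sum(vapply(models, `[[`, numeric(1), "loglik")),
       n_params = sum(vapply(models, `[[`, integer(1), "n_params")))
}

#' Fit the homogeneous (edge-constrained) group model
#'
#' One temporal matrix B and one residual precision K shared by all
#' members — all temporal and contemporaneous edges, including
#' autoregressive and variance entries, are constrained equal — while each
#' member keeps a free mean vector (the networks encode deviations from
#' person-specific means). The pooled full-information likelihood is
#' maximized jointly by EM: member-wise E-steps and a pooled M-step in
#' which B is the within-member-centered regression estimate and the
#' intercepts are profiled out per member.
#'
#' @param group A [severity_group()].
#' @param free_fit Optional result of [fit_group_free()] used for
#'   initialization (averaged member estimates); computed if missing.
#' @param tol,max_iter EM controls.
#' @return List with `B`, `Sigma`, `K`, `Omega`, `mu` (per-member matrix),
#'   `loglik`, `n_params` (= p^2 + p(p+1)/2 + m p) and `convergence`.
#' @export
fit_group_constrained <- function(group, free_fit = NULL, tol = 1e-8,
                                  max_iter = 500L) {
  chains <- lapply(group$series, function(s) gvar_chain(series_matrix(s)))
  p <- chains[[1L]]$p
  m <- length(chains)
  if (is.null(free_fit)) free_fit <- fit_group_free(group)
  B <- Reduce(`+`, lapply(free_fit$models, `[[`, "B")) / m
  Sigma <- Reduce(`+`, lapply(free_fit$models, `[[`, "Sigma")) / m
  cvecs <- lapply(free_fit$models, function(f)
    as.numeric((diag(p) - B) %*% f$mu))

  pooled_ll <- function(cvecs, B, Sigma)
    sum(vapply(seq_len(m), function(i)
      gvar_loglik_chain(chains[[i]], cvecs[[i]], B, Sigma), numeric(1)))

  ll_old <- pooled_ll(cvecs, B, Sigma)
  converged <- FALSE; delta <- NA_real_; iter <- 0L
  for (iter in seq_len(max_iter)) {
    stats_i <- lapply(seq_len(m), function(i)
      gvar_estep(chains[[i]], cvecs[[i]], B, Sigma))
    Wxy <- matrix(0, p, p); Wxx <- matrix(0, p, p)
    for (st in stats_i) {
      Wxy <- Wxy + st$S10 - tcrossprod(st$S1, st$S0) / st$n
      Wxx <- Wxx + st$S00 - tcrossprod(st$S0) / st$n
    }
    B_new <- t(solve(Wxx, t(Wxy)))
    cvecs_new <- lapply(stats_i, function(st)
      as.numeric(st$S1 - B_new %*% st$S0) / st$n)
    RSS <- matrix(0, p, p); n_tot <- 0L
    for (i in seq_len(m)) {
      st <- stats_i[[i]]
      Theta <- cbind(cvecs_new[[i]], B_new)
      G <- rbind(c(st$n, st$S0), cbind(st$S0, st$S00))
      Cm <- cbind(st$S1, st$S10)
      RSS <- RSS + st$S11 - Theta %*% t(Cm) - Cm %*% t(Theta) +
        Theta %*% G %*% t(Theta)
      n_tot <- n_tot + st$n
    }
    Sigma_new <- (RSS + t(RSS)) / (2 * n_tot)
    ev <- min(eigen(Sigma_new, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(ev) || ev <= 1e-12) {
      warning("pooled residual covariance became singular; stopping early")
      break
    }
    B <- B_new; Sigma <- Sigma_new; cvecs <- cvecs_new
    ll <- pooled_ll(cvecs, B, Sigma)
    delta <- abs(ll - ll_old) / (abs(ll_old) + 1e-10)
    ll_old <- ll
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && iter == max_iter)
    warning(sprintf("constrained EM did not converge in %d iterations", max_iter))
  K <- chol2inv(chol(Sigma))
  mu <- vapply(cvecs, function(cv) {
    if (spectral_radius(B) < 1) as.numeric(solve(diag(p) - B, cv)) else rep(NA_real_, p)
  }, numeric(p))
  list(B = B, Sigma = Sigma, K = K, Omega = pcc_from_precision(K),
       mu = mu, intercepts = cvecs, loglik = ll_old,
       n_params = as.integer(p^2 + p * (p + 1L) / 2L + m * p),
       convergence = list(converged = converged, iterations = iter,
                          rel_change = delta))
}

#' Individual network invariance test for one severity group
#'
#' Compares, by AIC, the heterogeneous model (all member networks free)
#' against the homogeneous model (all temporal and contemporaneous edges
#' equal across members, means free): `AIC = 2 k - 2 logLik` for each, and
#' the group is flagged heterogeneous iff `aic_het < aic_hom`. Exact ties
#' resolve to homogeneous — the test deliberately favours type II over type
#' I errors. Because the homogeneous model is nested in the heterogeneous
#' one, `loglik_hom <= loglik_free` must hold; if a constrained optimum
#' ever exceeded a member's free optimum, the free member fits are restarted
#' from the shared solution and the better likelihood kept.
#'
#' @param group A [severity_group()] (>= 2 members).
#' @param keep_models Keep the fitted member/shared models in the result
#'   (default TRUE).
#' @param ... Passed to [fit_gvar_ml()].
#' @return An `init_result`: group id, severity, size, `loglik_free`,
#'   `loglik_hom`, `n_params_free`, `n_params_hom`, `aic_het`, `aic_hom`,
#'   `heterogeneous` flag, and (optionally) the fitted models.
#' @export
init_test <- function(group, keep_models = TRUE, ...) {
  if (!inherits(group, "severity_group")) stop("expected a severity_group")
  free <- fit_group_free(group, ...)
  hom <- fit_group_constrained(group, free_fit = free)
  if (hom$loglik > free$loglik + 1e-6) {
    # nesting violated: a member's free EM stopped short; restart each
    # member from the shared solution and keep the better optimum
    p <- length(free$models[[1L]]$mu)
    for (id in names(group$series)) {
      chain <- gvar_chain(series_matrix(group$series[[id]]))
      refit <- em_from_start(chain, cvec = hom$intercepts[[which(names(group$series) == id)]],
                             B = hom$B, Sigma = hom$Sigma, ...)
      if (refit$loglik > free$models[[id]]$loglik) free$models[[id]] <- refit
    }
    free$loglik <- sum(vapply(free$models, `[[`, numeric(1), "loglik"))
  }
  aic_het <- 2 * free$n_params - 2 * free$loglik
  aic_hom <- 2 * hom$n_params - 2 * hom$loglik
  structure(
    list(
      id = group$id, severity = group$severity, size = group$size,
      loglik_free = free$loglik, loglik_hom = hom$loglik,
      n_params_free = free$n_params, n_params_hom = hom$n_params,
      aic_het = aic_het, aic_hom = aic_hom,
      heterogeneous = aic_het < aic_hom,
      models = if (keep_models) list(free = free, constrained = hom) else NULL
    ),
    class = "init_result"
  )
}

# EM restart of a single-member fit from given parameters (used by the
# nesting safeguard in init_test)
#' @keywords internal
em_from_start <- function(chain, cvec, B, Sigma, tol = 1e-8,
                          max_iter = 500L, ...) {
  par <- list(cvec = cvec, B = B, Sigma = Sigma)
  ll_old <- gvar_loglik_chain(chain, par$cvec, par$B, par$Sigma)
  converged <- FALSE; delta <- NA_real_; iter <- 0L
  for (iter in seq_len(max_iter)) {
    st <- gvar_estep(chain, par$cvec, par$B, par$Sigma)
    par <- gvar_mstep(st)
    ll <- gvar_loglik_chain(chain, par$cvec, par$B, par$Sigma)
    delta <- abs(ll - ll_old) / (abs(ll_old) + 1e-10)
    ll_old <- ll
    if (delta < tol) { converged <- TRUE; break }
  }
  finalize_gvar_model(par, chain, ll_old, converged, iter, delta,
                      colnames(chain$Y))
}

#' @export
print.init_result <- function(x, ...) {
  cat(sprintf(
    "INIT group %s (severity %d, %d members): AIC free %.1f vs constrained %.1f -> %s\n",
    x$id, x$severity, x$size, x$aic_het, x$aic_hom,
    if (x$heterogeneous) "heterogeneous" else "homogeneous"))
  invisible(x)
}

#' Tabulate INIT results
#'
#' One row per group: severity, size, pooled log-likelihoods, parameter
#' counts, AICs and the heterogeneity flag — the INIT report.
#'
#' @param results List of `init_result` objects.
#' @return A data frame.
#' @export
init_report <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(group = r$id, severity = r$severity, size = r$size,
               loglik_free = r$loglik_free, loglik_hom = r$loglik_hom,
               n_params_free = r$n_params_free, n_params_hom = r$n_params_hom,
               aic_het = r$aic_het, aic_hom = r$aic_hom,
               heterogeneous = r$heterogeneous, stringsAsFactors = FALSE)))
}
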