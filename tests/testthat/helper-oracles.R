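# Independent oracles used across the suite. Each implements the target
# quantity by a different route than the package (closed form, brute-force
# enumeration, or full joint assembly) so agreement is a real check.

# multivariate normal log-density via Cholesky
mvn_logdens <- function(x, mean, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# complete-data conditional ML oracle: multivariate regression of y_t on
# (1, y_{t-1}) plus residual covariance MLE, and the resulting loglik
oracle_complete_ml <- function(Y) {
  Y0 <- Y[-nrow(Y), , drop = FALSE]
  Y1 <- Y[-1L, , drop = FALSE]
  X <- cbind(1, Y0)
  beta <- solve(crossprod(X), crossprod(X, Y1))
  res <- Y1 - X %*% beta
  Sigma <- crossprod(res) / nrow(Y1)
  ll <- sum(vapply(seq_len(nrow(Y1)), function(i)
    mvn_logdens(Y1[i, ], as.numeric(t(beta) %*% c(1, Y0[i, ])), Sigma),
    numeric(1)))
  list(intercept = beta[1L, ], B = t(beta[-1L, , drop = FALSE]),
       Sigma = Sigma, loglik = ll)
}

# brute-force exact joint Gaussian log-likelihood: assemble the full T*p
# stationary covariance (Cov(y_t, y_s) = B^{t-s} S_inf for t >= s) and
# evaluate the marginal density of the observed entries directly
oracle_joint_loglik <- function(mu, B, K, Y) {
  p <- length(mu)
  Tn <- nrow(Y)
  Sinf <- stationary_covariance(B, solve(K))
  Bp <- vector("list", Tn + 1L)
  Bp[[1L]] <- diag(p)
  for (k in seq_len(Tn)) Bp[[k + 1L]] <- Bp[[k]] %*% B
  bigS <- matrix(0, Tn * p, Tn * p)
  for (t in seq_len(Tn)) for (s in seq_len(Tn)) {
    blk <- if (t >= s) Bp[[t - s + 1L]] %*% Sinf else Sinf %*% t(Bp[[s - t + 1L]])
    bigS[(t - 1L) * p + seq_len(p), (s - 1L) * p + seq_len(p)] <- blk
  }
  obs <- which(rowSums(is.na(Y)) == 0L)
  oidx <- as.vector(vapply(obs, function(t) (t - 1L) * p + seq_len(p),
                           integer(p)))
  mvn_logdens(as.vector(t(Y[obs, , drop = FALSE])), rep(mu, length(obs)),
              bigS[oidx, oidx])
}

# exact distribution of the group-bootstrap proportion by enumerating all
# ordered resamples of G groups
oracle_bootstrap_enum <- function(sizes, flags) {
  G <- length(sizes)
  grids <- rep(list(seq_len(G)), G)
  combos <- do.call(expand.grid, grids)
  props <- apply(combos, 1L, function(ix)
    sum(sizes[ix] * flags[ix]) / sum(sizes[ix]))
  tab <- table(props) / length(props)
  data.frame(proportion = as.numeric(names(tab)),
             probability = as.numeric(tab))
}

# quick simulated participant on the default study grid
sim_person <- function(model, miss = 0.18, seed = NULL, id = "p") {
  simulate_series(model, study_design(), missing = missingness_spec(miss),
                  seed = seed, id = id)
}

# a fixed sparse stable reference model used by several tests
ref_model <- function(seed = 404) {
  set.seed(seed)
  B <- generate_stable_temporal_matrix(6, 0.3, 0.4)
  K <- generate_precision_matrix(6, 0.3)
  true_gvar(runif(6, 30, 70), B, K)
}

# study-condition random person model (sparse stable B, SPD K)
random_true_gvar_test <- function() {
  B <- generate_stable_temporal_matrix(6, 0.3, 0.4)
  K <- generate_precision_matrix(6, 0.3)
  true_gvar(runif(6, 30, 70), B, K)
}
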