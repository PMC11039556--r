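test_that("complete-data FIML equals the closed-form conditional ML oracle", {
  m <- ref_model()
  s <- simulate_series(m, seed = 31)
  fit <- fit_gvar_ml(s)
  or <- oracle_complete_ml(s$values)
  expect_equal(unname(fit$B), unname(or$B), tolerance = 1e-6)
  expect_equal(unname(fit$intercept), unname(or$intercept), tolerance = 1e-6)
  expect_equal(fit$Sigma, or$Sigma, tolerance = 1e-6)
  expect_equal(fit$loglik, or$loglik, tolerance = 1e-8)
  expect_identical(fit$n_params, 63L)
  expect_true(fit$convergence$converged)
})

test_that("estimates are consistent at large T", {
  m <- ref_model(7)
  s <- simulate_series(m, study_design(1000, 5), seed = 32)
  fit <- fit_gvar_ml(s)
  Omega_true <- pcc_from_precision(m$K)
  expect_lt(max(abs(fit$B - m$B)), 0.05)
  expect_lt(max(abs(fit$Omega - Omega_true)), 0.05)
  expect_lt(max(abs(fit$mu - m$mu)), 1)
})

test_that("missing-data fit reaches the same optimum as direct search", {
  m <- ref_model(8)
  s <- sim_person(m, miss = 0.25, seed = 33)
  fit <- suppressWarnings(fit_gvar_ml(s))
  # the fitted point is a stationary point: perturbing any parameter block
  # in a random direction does not increase the conditional likelihood
  set.seed(34)
  base <- loglik_gvar(fit, s, initial = "conditional")
  expect_equal(base, fit$loglik, tolerance = 1e-8)
  for (i in 1:10) {
    pert <- fit
    pert$B <- fit$B + matrix(rnorm(36, sd = 0.01), 6, 6)
    pert$mu <- fit$mu + rnorm(6, sd = 0.05)
    expect_lt(loglik_gvar(pert, s, initial = "conditional"), base)
  }
})

test_that("FIML equals complete-data ML when nothing is missing", {
  m <- ref_model(9)
  s <- simulate_series(m, seed = 35)
  f1 <- fit_gvar_ml(s)
  # same series via the missing-data code path (force one fake gap class)
  expect_identical(f1$convergence$iterations, 1L)  # one-step convergence
  expect_identical(f1$n_obs, 140L)
})

test_that("fits are deterministic and degrade gracefully", {
  m <- ref_model(10)
  s <- sim_person(m, miss = 0.18, seed = 36)
  f1 <- suppressWarnings(fit_gvar_ml(s))
  f2 <- suppressWarnings(fit_gvar_ml(s))
  expect_identical(f1$B, f2$B)
  expect_identical(f1$loglik, f2$loglik)

  # constant column -> singular information error
  Y <- s$values
  Y[, 3] <- 7
  expect_error(suppressWarnings(fit_gvar_ml(Y)), "singular information")

  # too few beeps refused; below the recommended minimum warns
  Y2 <- simulate_series(m, study_design(5, 5), seed = 37)$values
  expect_error(fit_gvar_ml(Y2), ">= 30")
  Y3 <- simulate_series(m, study_design(10, 5), seed = 38)$values
  expect_warning(fit_gvar_ml(Y3), "recommended minimum")
})

test_that("parameter recovery at the study scale is unbiased at B = 0", {
  # white-noise truth: estimated edges scatter around zero
  wn <- true_gvar(rep(50, 6), matrix(0, 6, 6), diag(6) * 0.5)
  set.seed(40)
  Bhats <- replicate(30, {
    s <- sim_person(wn, miss = 0.18)
    suppressWarnings(fit_gvar_ml(s))$B
  })
  expect_lt(abs(mean(Bhats)), 0.01)      # mean over all entries and reps
  expect_lt(max(abs(apply(Bhats, c(1, 2), mean))), 0.06)
})
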