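make_null_group <- function(m, n_members, seeds, severity = 31L,
                            miss = 0.18) {
  ser <- lapply(seq_len(n_members), function(i)
    detrend(sim_person(m, miss = miss, seed = seeds[i],
                       id = paste0("p", i))))
  names(ser) <- paste0("p", seq_len(n_members))
  severity_group(severity, ser)
}

test_that("free group fit pools member fits additively", {
  m <- ref_model(20)
  g <- make_null_group(m, 2, seeds = c(61, 62))
  free <- suppressWarnings(fit_group_free(g, warn_obs = 0))
  s1 <- suppressWarnings(fit_gvar_ml(g$series[[1]], warn_obs = 0))
  s2 <- suppressWarnings(fit_gvar_ml(g$series[[2]], warn_obs = 0))
  expect_equal(free$loglik, s1$loglik + s2$loglik, tolerance = 1e-10)
  expect_identical(free$n_params, 126L)  # 63 per member of 6 variables

  # permuting member order leaves the pooled loglik unchanged
  g_rev <- severity_group(31L, rev(g$series))
  free_rev <- suppressWarnings(fit_group_free(g_rev, warn_obs = 0))
  expect_equal(free_rev$loglik, free$loglik, tolerance = 1e-10)
})

test_that("constrained fit is nested and shares edges, not means", {
  m <- ref_model(21)
  for (seed_pair in list(c(63, 64), c(65, 66), c(67, 68))) {
    g <- make_null_group(m, 2, seeds = seed_pair)
    free <- suppressWarnings(fit_group_free(g, warn_obs = 0))
    hom <- fit_group_constrained(g, free_fit = free)
    # nesting: constrained optimum cannot exceed the free optimum
    expect_lte(hom$loglik, free$loglik + 1e-6)
    expect_identical(hom$n_params, 36L + 21L + 2L * 6L)
    # means stay person-specific
    expect_false(isTRUE(all.equal(hom$mu[, 1], hom$mu[, 2])))
  }
})

test_that("a group of identical copies is judged homogeneous", {
  m <- ref_model(22)
  d <- detrend(sim_person(m, miss = 0.1, seed = 70))
  g <- severity_group(40L, list(a = d, b = d, c = d))
  r <- suppressWarnings(init_test(g, warn_obs = 0))
  expect_false(r$heterogeneous)
  # free model gains no fit: member logliks identical, shared fit equals
  # the single fit and the pooled loglik is m times the single one
  single <- suppressWarnings(fit_gvar_ml(d, warn_obs = 0))
  expect_equal(r$loglik_free, 3 * single$loglik, tolerance = 1e-6)
  expect_equal(r$loglik_hom, 3 * single$loglik, tolerance = 1e-4)
  expect_equal(unname(r$models$constrained$B), unname(single$B),
               tolerance = 1e-2)
})

test_that("parameter accounting matches the 57-per-extra-member rule", {
  m <- ref_model(23)
  for (n_mem in 2:4) {
    g <- make_null_group(m, n_mem, seeds = 80 + seq_len(n_mem))
    r <- suppressWarnings(init_test(g, keep_models = FALSE, warn_obs = 0))
    expect_identical(r$n_params_free, 63L * n_mem)
    expect_identical(r$n_params_hom, 57L + 6L * n_mem)
    expect_identical(r$n_params_free - r$n_params_hom, (n_mem - 1L) * 57L)
    expect_equal(r$aic_het, 2 * r$n_params_free - 2 * r$loglik_free)
    expect_equal(r$aic_hom, 2 * r$n_params_hom - 2 * r$loglik_hom)
  }
})

test_that("the INIT decision is invariant to member ordering", {
  m <- ref_model(24)
  g <- make_null_group(m, 3, seeds = c(91, 92, 93))
  r1 <- suppressWarnings(init_test(g, keep_models = FALSE, warn_obs = 0))
  g_rev <- severity_group(g$severity, rev(g$series))
  r2 <- suppressWarnings(init_test(g_rev, keep_models = FALSE, warn_obs = 0))
  expect_identical(r1$heterogeneous, r2$heterogeneous)
  expect_equal(r1$aic_het, r2$aic_het, tolerance = 1e-8)
  expect_equal(r1$aic_hom, r2$aic_hom, tolerance = 1e-6)
})

test_that("shared estimates are consistent under a true null at large T", {
  m <- ref_model(25)
  des <- study_design(500, 5)
  ser <- lapply(1:2, function(i)
    simulate_series(m, des, seed = 100 + i, id = paste0("p", i)))
  names(ser) <- c("p1", "p2")
  g <- severity_group(20L, ser)
  hom <- fit_group_constrained(g)
  expect_lt(max(abs(hom$B - m$B)), 0.05)
  expect_lt(max(abs(pcc_from_precision(hom$K) - pcc_from_precision(m$K))),
            0.05)
})

test_that("strong between-member differences are detected", {
  # the test is conservative by design, so "strongly different" means
  # differences on many edges: here 6 edges shifted by 0.5
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    set.seed(26 + r)
    B1 <- generate_stable_temporal_matrix(6, 0.3, 0.4)
    B2 <- B1
    idx <- sample(36, 6)
    B2[idx] <- B2[idx] + sample(c(-1, 1), 6, TRUE) * 0.5
    if (spectral_radius(B2) >= 1) B2 <- B2 * 0.9 / spectral_radius(B2)
    K <- generate_precision_matrix(6, 0.3)
    mA <- true_gvar(rep(50, 6), B1, K)
    mB <- true_gvar(rep(50, 6), B2, K)
    ser <- list(a = detrend(sim_person(mA, seed = 200 + r)),
                b = detrend(sim_person(mB, seed = 300 + r)))
    res <- suppressWarnings(init_test(severity_group(30L, ser),
                                      keep_models = FALSE, warn_obs = 0))
    hits <- hits + res$heterogeneous
  }
  expect_gte(hits, n_rep * 0.6)  # detected in the large majority
})

test_that("singleton groups are rejected", {
  expect_error(severity_group(31L, list(a = matrix(0, 10, 2))), "at least 2")
})
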