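test_that("generated temporal matrices are stable and sparse as requested", {
  expect_equal(generate_stable_temporal_matrix(6, density = 0, seed = 1),
               matrix(0, 6, 6))
  for (seed in 1:25) {
    B <- generate_stable_temporal_matrix(6, 0.3, 0.4, seed = seed)
    expect_lt(spectral_radius(B), 1)  # eigen-decomposition oracle
    expect_equal(sum(B != 0), round(0.3 * 36))
    expect_lte(max(abs(B)), 0.4)
  }
  expect_identical(generate_stable_temporal_matrix(6, 0.3, 0.4, seed = 7),
                   generate_stable_temporal_matrix(6, 0.3, 0.4, seed = 7))
})

test_that("generated precision matrices are SPD with controlled support", {
  K0 <- generate_precision_matrix(4, density = 0, seed = 1)
  expect_true(all(K0[upper.tri(K0)] == 0))
  for (seed in 1:25) {
    K <- generate_precision_matrix(6, 0.3, seed = seed)
    expect_silent(chol(K))                      # Cholesky as SPD oracle
    expect_equal(sum(K[upper.tri(K)] != 0), round(0.3 * 15))
    expect_equal(K %*% solve(K), diag(6), tolerance = 1e-8)
    expect_equal(K, t(K))
  }
})

test_that("simulated series match the design grid and white-noise limit", {
  m <- ref_model()
  s <- simulate_series(m, seed = 1)
  expect_s3_class(s, "symptom_series")
  expect_identical(nrow(s$values), 140L)
  expect_identical(s$n_completed, 140L)

  # beep_missing_prob = 1 removes everything
  s_all <- simulate_series(m, missing = missingness_spec(1), seed = 2)
  expect_identical(s_all$n_completed, 0L)
  expect_true(all(is.na(s_all$values)))

  # B = 0, K = I, mu = 0: sample means and lag-1 autocorrelations vanish
  wn <- true_gvar(rep(0, 3), matrix(0, 3, 3), diag(3))
  sw <- simulate_series(wn, study_design(1000, 5), seed = 3)
  Y <- sw$values
  expect_lt(max(abs(colMeans(Y))), 0.05)
  for (j in 1:3) {
    r <- cor(Y[-1, j], Y[-nrow(Y), j])
    expect_lt(abs(r), 0.05)
  }

  # trend is added after VAR generation
  tr <- trend_spec(3, linear = 0.5)
  st <- simulate_series(wn, study_design(4, 5), trend = tr, seed = 4)
  fit <- lm(st$values[, 1] ~ seq_len(20))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.2)

  # VAS mode clips to [0, 100]
  sv <- simulate_series(true_gvar(rep(110, 3), matrix(0, 3, 3), diag(3)),
                        study_design(4, 5), seed = 5, vas = TRUE)
  expect_true(all(sv$values <= 100))
})

test_that("default missingness reproduces the observed completion rate", {
  wn <- true_gvar(rep(0, 2), matrix(0, 2, 2), diag(2))
  set.seed(99)
  completed <- vapply(seq_len(1000), function(i)
    simulate_series(wn, missing = missingness_spec(0.18))$n_completed,
    integer(1))
  expect_gte(mean(completed), 112)
  expect_lte(mean(completed), 118)
})

test_that("null studies share one true model within each group", {
  study <- build_null_study(n_groups = 3, group_sizes = c(2, 3, 2),
                            seed = 11)
  expect_identical(nrow(study$participants), 7L)
  expect_identical(sum(study$group_sizes), 7L)
  for (g in 1:3) {
    ids <- study$participants$id[study$participants$group == g]
    for (id in ids[-1]) {
      expect_identical(study$truth[[id]]$B, study$truth[[ids[1]]]$B)
      expect_identical(study$truth[[id]]$K, study$truth[[ids[1]]]$K)
    }
    # members share the group severity total
    expect_length(unique(study$participants$severity[
      study$participants$group == g]), 1L)
  }
  # distinct groups get independent (different) temporal matrices
  g1 <- study$truth[[study$participants$id[study$participants$group == 1][1]]]
  g2 <- study$truth[[study$participants$id[study$participants$group == 2][1]]]
  expect_gt(max(abs(g1$B - g2$B)), 0)
  # severity totals are distinct across groups
  expect_length(unique(study$severities), 3L)
  # fixed seed gives a bit-identical study
  study2 <- build_null_study(n_groups = 3, group_sizes = c(2, 3, 2),
                             seed = 11)
  expect_identical(study$series[[1]]$values, study2$series[[1]]$values)
  expect_error(build_null_study(n_groups = 1, group_sizes = 1L), ">= 2")
})

test_that("alternative studies perturb members but stay stationary", {
  study <- build_alternative_study(0.4, n_groups = 2, group_sizes = c(2, 2),
                                   seed = 21, n_perturbed = 3)
  for (id in study$participants$id)
    expect_lt(spectral_radius(study$truth[[id]]$B), 1)
  ids <- study$participants$id[study$participants$group == 1]
  expect_gt(max(abs(study$truth[[ids[1]]]$B - study$truth[[ids[2]]]$B)), 0.3)
  # zero effect size collapses to the null construction
  s0 <- build_alternative_study(0, n_groups = 2, group_sizes = c(2, 2),
                                seed = 21)
  sn <- build_null_study(n_groups = 2, group_sizes = c(2, 2), seed = 21)
  expect_identical(s0$truth[[1]]$B, sn$truth[[1]]$B)
  expect_error(build_alternative_study(-1, n_groups = 2), "effect_size")
})

test_that("group size compositions honour the bounds and total", {
  for (seed in 1:10) {
    sz <- draw_group_sizes(23, 73, seed = seed)
    expect_identical(sum(sz), 73L)
    expect_true(all(sz >= 2L & sz <= 6L))
  }
  expect_error(draw_group_sizes(10, 5), "incompatible")
})
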