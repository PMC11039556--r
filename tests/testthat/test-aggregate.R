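flag_table <- function(sizes, flags) {
  data.frame(size = as.integer(sizes), heterogeneous = as.logical(flags))
}

test_that("the proportion counts members of heterogeneous-flagged groups", {
  # no groups flagged / all groups flagged
  tab <- flag_table(c(2, 3, 4), c(FALSE, FALSE, FALSE))
  expect_equal(proportion_differential(tab)$proportion, 0)
  tab$heterogeneous <- TRUE
  expect_equal(proportion_differential(tab)$proportion, 1)

  p <- proportion_differential(flag_table(c(3, 2, 4), c(TRUE, FALSE, TRUE)))
  expect_identical(p$n_flagged, 7L)
  expect_identical(p$n_total, 9L)

  # invariant to group ordering
  p2 <- proportion_differential(flag_table(c(4, 3, 2), c(TRUE, TRUE, FALSE)))
  expect_equal(p$proportion, p2$proportion)
  expect_error(proportion_differential(flag_table(integer(0), logical(0))))
})

test_that("group bootstrap matches the exact enumeration oracle", {
  sizes <- c(2L, 3L)
  flags <- c(FALSE, TRUE)
  exact <- oracle_bootstrap_enum(sizes, flags)
  # the 4 equally likely ordered resamples give {0, 0.6, 0.6, 1}
  expect_equal(exact$proportion, c(0, 0.6, 1))
  expect_equal(exact$probability, c(0.25, 0.5, 0.25))

  est <- bootstrap_ci(flag_table(sizes, flags), n_boot = 10000, seed = 1)
  reps <- attr(est, "replicates")
  freq <- as.numeric(table(factor(reps, levels = c(0, 0.6, 1)))) / 10000
  expect_equal(freq, exact$probability, tolerance = 0.02)  # 3 MC sds ~ 0.015
})

test_that("bootstrap CI behaves at the edges and under a fixed seed", {
  allflag <- flag_table(c(2, 3, 4), c(TRUE, TRUE, TRUE))
  est <- bootstrap_ci(allflag, n_boot = 2000, seed = 2)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))

  tab <- flag_table(c(2, 5, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  e1 <- bootstrap_ci(tab, n_boot = 5000, seed = 3)
  e2 <- bootstrap_ci(tab, n_boot = 5000, seed = 3)
  expect_identical(c(e1$ci_low, e1$ci_high), c(e2$ci_low, e2$ci_high))
  # CI brackets the resample median and lies in [0, 1]
  med <- median(attr(e1, "replicates"))
  expect_gte(med, e1$ci_low)
  expect_lte(med, e1$ci_high)
  expect_gte(e1$ci_low, 0)
  expect_lte(e1$ci_high, 1)
  expect_error(bootstrap_ci(flag_table(3, TRUE)), "at least 2")
})

test_that("CI width shrinks as the number of groups grows", {
  set.seed(4)
  width <- function(G) {
    tab <- flag_table(sample(2:6, G, replace = TRUE),
                      runif(G) < 0.6)
    e <- bootstrap_ci(tab, n_boot = 3000, seed = 5)
    e$ci_high - e$ci_low
  }
  expect_gt(width(5), width(50))
})

test_that("null replicates detect nothing for duplicated identical members", {
  m <- ref_model(30)
  d <- sim_person(m, miss = 0.1, seed = 400)
  study <- list(
    series = list(a = d, b = d),
    participants = data.frame(id = c("a", "b"), group = 1L,
                              severity = 31L),
    design = study_design()
  )
  res <- idionet:::null_rep_analysis(study, screen = FALSE)
  expect_identical(res$n_flagged, 0L)
  expect_equal(res$proportion, 0)
})

test_that("the null-simulation seed stream is extendable", {
  des <- study_design(12, 5)  # shorter grid keeps this check quick
  a <- run_null_simulation(n_groups = 2, group_sizes = c(2, 2), design = des,
                           reps = 2, seed = 42, screen = FALSE)
  b <- run_null_simulation(n_groups = 2, group_sizes = c(2, 2), design = des,
                           reps = 4, seed = 42, screen = FALSE)
  expect_identical(a$per_rep$seed, b$per_rep$seed[1:2])
  expect_identical(a$per_rep$proportion, b$per_rep$proportion[1:2])
  expect_equal(a$mean_rate, mean(a$per_rep$proportion))
})

test_that("power under strong alternatives exceeds the null rate", {
  # paired design: same seeds, groups of 2, with and without a 0.4-edge
  # perturbation between members
  n_rep <- 12L
  null_flags <- 0L; alt_flags <- 0L
  for (r in seq_len(n_rep)) {
    null_study <- build_null_study(n_groups = 1L, group_sizes = 2L,
                                   seed = 500 + r)
    alt_study <- build_alternative_study(0.5, n_groups = 1L,
                                         group_sizes = 2L, seed = 500 + r,
                                         n_perturbed = 8L)
    for (st in list(null_study, alt_study)) {
      res <- idionet:::null_rep_analysis(st, screen = FALSE)
      flagged <- res$n_flagged > 0L
      if (identical(st, null_study)) null_flags <- null_flags + flagged
      else alt_flags <- alt_flags + flagged
    }
  }
  expect_gt(alt_flags, null_flags)
  expect_lte(null_flags, 2L)       # type I stays rare
  expect_gte(alt_flags, n_rep / 2) # power is substantial
})
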