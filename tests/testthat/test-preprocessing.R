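test_that("IDS-SR scoring follows the 28-item total and published bands", {
  r0 <- score_ids_sr(rep(0L, 30))
  expect_identical(r0$total, 0L)
  expect_equal(as.character(r0$category), "none")
  r3 <- score_ids_sr(rep(3L, 30))
  expect_identical(r3$total, 84L)  # 28 scoring items x 3
  expect_equal(as.character(r3$category), "very severe")

  # band boundaries
  expect_equal(as.character(severity_category(13)), "none")
  expect_equal(as.character(severity_category(14)), "mild")
  expect_equal(as.character(severity_category(22)), "moderate")
  expect_equal(as.character(severity_category(31)), "severe")
  expect_equal(as.character(severity_category(38)), "severe")
  expect_equal(as.character(severity_category(39)), "very severe")

  # bands partition 0-84 exhaustively
  cats <- severity_category(0:84)
  expect_false(anyNA(cats))
  expect_identical(as.integer(table(cats)),
                   c(14L, 8L, 9L, 8L, 46L))

  expect_error(score_ids_sr(rep(0L, 29)), "30 items")
  expect_error(score_ids_sr(c(rep(0L, 29), 4L)), "0-3")
})

test_that("IDS-SR total is monotone in every scoring item", {
  set.seed(1)
  for (rep in 1:20) {
    items <- sample(0:3, 30, replace = TRUE)
    base <- score_ids_sr(items)$total
    j <- sample(30, 1)
    if (items[j] < 3L) {
      items2 <- items
      items2[j] <- items2[j] + 1L
      expect_gte(score_ids_sr(items2)$total, base)
    }
  }
})

test_that("severity grouping keeps matched totals and reports exclusions", {
  g <- build_severity_groups(paste0("p", 1:5), rep(31L, 5))
  expect_identical(g$n_groups, 1L)
  expect_identical(unname(g$sizes), 5L)

  g2 <- build_severity_groups(c("a", "b"), c(10L, 20L))
  expect_identical(g2$n_groups, 0L)
  expect_identical(g2$excluded, c("a", "b"))

  g3 <- build_severity_groups(paste0("p", 1:6),
                              c(15L, 15L, 22L, 22L, 22L, 40L))
  expect_identical(g3$n_groups, 2L)
  expect_identical(unname(g3$sizes[["15"]]), 2L)
  expect_identical(unname(g3$sizes[["22"]]), 3L)
  expect_identical(g3$excluded, "p6")
})

test_that("symptom composites apply reverse scoring and missing rules", {
  beep <- data.frame(down = 80, cheerful = 20, indifferent = 50,
                     listless = 50, enthusiastic = 50, hungry = 50,
                     calm = 100, stressed = 0, relaxed = 100,
                     irritated = 30, tired = 60, energetic = 40)
  comp <- composite_symptoms(beep)
  expect_equal(unname(comp[1, "depressed_mood"]), 80)
  expect_equal(unname(comp[1, "restlessness"]), 0)
  expect_equal(unname(comp[1, "irritability"]), 30)
  expect_equal(unname(comp[1, "lethargy"]), 60)

  # midpoint is the fixed point of reversal
  mid <- beep; mid[1, ] <- 50
  expect_true(all(composite_symptoms(mid) == 50))

  # reversal is involutive
  x <- runif(10, 0, 100)
  expect_equal(reverse_vas(reverse_vas(x)), x)

  # composite missing only when all indicators missing
  part <- beep
  part$down <- NA
  expect_equal(unname(composite_symptoms(part)[1, "depressed_mood"]), 80)
  part$cheerful <- NA
  expect_true(is.na(composite_symptoms(part)[1, "depressed_mood"]))

  expect_error(composite_symptoms(transform(beep, down = 150)), "\\[0, 100\\]")
  expect_error(composite_symptoms(beep[, -1]), "missing item")
})

test_that("detrending removes exactly what it fits", {
  des <- study_design()
  t_idx <- seq_len(des$max_assessments)
  set.seed(5)
  # pure cubic input -> residuals all ~ 0
  cubic <- outer((t_idx / 50)^3, rep(1, 6)) * matrix(runif(6), 140, 6,
                                                     byrow = TRUE)
  s <- symptom_series("c", cubic + 50)
  d <- detrend(s)
  expect_lt(max(abs(d$values)), 1e-8)

  # trend-free noise -> residuals ~ input minus mean; refit coefficients ~ 0
  noise <- matrix(rnorm(140 * 6), 140, 6)
  dn <- detrend(symptom_series("n", noise + 50))
  for (j in 1:6) {
    tt <- (t_idx - mean(t_idx)) / sd(t_idx)
    refit <- lm(dn$values[, j] ~ poly(tt, 3, raw = TRUE))
    expect_lt(max(abs(coef(refit))), 1e-8)
  }

  # idempotence
  d2 <- detrend(dn)
  expect_equal(d2$values, dn$values, tolerance = 1e-8)

  # missing stays missing; grid indexing includes missing slots
  noise[c(3, 77), ] <- NA
  dm <- detrend(symptom_series("m", noise + 50))
  expect_true(all(is.na(dm$values[c(3, 77), ])))
  expect_identical(dm$n_completed, 138L)

  short <- matrix(rnorm(140 * 2), 140, 2)
  short[8:140, 1] <- NA
  expect_error(detrend(short), "observed points")
})

test_that("stationarity screen separates stable series from unit roots", {
  set.seed(10)
  n_rep <- 200
  # stationary AR(1), coefficient 0.3, T = 140: overwhelmingly passes
  pass <- vapply(seq_len(n_rep), function(i) {
    y <- as.numeric(arima.sim(list(ar = 0.3), 140))
    adf_statistic(y)$reject
  }, logical(1))
  expect_gt(mean(pass), 0.95)

  # random walk: fails (unit root not rejected) with high probability
  fail <- vapply(seq_len(n_rep), function(i) {
    y <- cumsum(rnorm(140))
    !adf_statistic(y)$reject
  }, logical(1))
  expect_gt(mean(fail), 0.85)

  # constant series reported as zero-variance failure, never an error
  Y <- matrix(rnorm(140 * 6), 140, 6)
  Y[, 2] <- 5
  d <- detrend(symptom_series("s", Y + 50), min_obs = 8)
  d$values[, 2] <- 0  # detrend of a constant leaves zeros
  scr <- stationarity_screen(d)
  expect_false(scr$stationarity$pass)
  expect_match(scr$stationarity$table$reason[2], "zero variance")

  # whole screen passes for a well-behaved simulated participant
  m <- ref_model()
  s <- sim_person(m, miss = 0.18, seed = 77)
  scr2 <- stationarity_screen(detrend(s))
  expect_true(scr2$stationarity$pass)
})
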