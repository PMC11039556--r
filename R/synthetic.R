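#' Generate a sparse stable temporal coefficient matrix
#'
#' Draws a p x p lag-1 coefficient matrix with a fixed number of nonzero
#' entries (`round(density * p^2)`, positions sampled uniformly) and entry
#' magnitudes uniform on (-max_abs, max_abs). If a draw has spectral radius
#' >= 1 it is rescaled to radius `stability_margin` (< 1), so the returned
#' process is always stationary.
#'
#' @param p Dimension (number of symptom variables).
#' @param density Fraction of the p^2 entries that are nonzero, in \[0, 1\].
#' @param max_abs Upper bound on entry magnitude (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @param stability_margin Spectral radius imposed when rescaling an
#'   unstable draw (default 0.9).
#' @param max_retry Bound on redraw attempts for degenerate cases.
#' @return A p x p matrix with spectral radius < 1.
#' @export
generate_stable_temporal_matrix <- function(p = 6L, density = 0.3,
                                            max_abs = 0.4, seed = NULL,
                                            stability_margin = 0.9,
                                            max_retry = 100L) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (max_abs <= 0) stop("max_abs must be positive")
  if (stability_margin <= 0 || stability_margin >= 1)
    stop("stability_margin must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_nonzero <- round(density * p^2)
  for (i in seq_len(max_retry)) {
    B <- matrix(0, p, p)
    if (n_nonzero > 0L) {
      pos <- sample.int(p^2, n_nonzero)
      B[pos] <- runif(n_nonzero, -max_abs, max_abs)
    }
    sr <- spectral_radius(B)
    if (sr < 1) return(B)
    B <- B * (stability_margin / sr)
    if (spectral_radius(B) < 1) return(B)
  }
  stop("could not construct a stable temporal matrix; ",
       "density/max_abs combination appears infeasible")
}

#' Generate a sparse symmetric positive definite precision matrix
#'
#' Draws off-diagonal support of size `round(density * p*(p-1)/2)` with
#' magnitudes uniform on (-max_abs, max_abs), then sets each diagonal entry
#' to 1 plus the corresponding absolute row sum (strict diagonal dominance),
#' which guarantees positive definiteness.
#'
#' @param p Dimension.
#' @param density Fraction of the p(p-1)/2 off-diagonal pairs that are
#'   nonzero, in \[0, 1\].
#' @param max_abs Upper bound on off-diagonal magnitude.
#' @param seed Optional integer seed.
#' @return A p x p symmetric positive definite matrix.
#' @export
generate_precision_matrix <- function(p = 6L, density = 0.3, max_abs = 0.5,
                                      seed = NULL) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  K <- matrix(0, p, p)
  pairs <- which(upper.tri(K))
  n_nonzero <- round(density * length(pairs))
  if (n_nonzero > 0L) {
    pos <- sample(pairs, n_nonzero)
    K[pos] <- runif(n_nonzero, -max_abs, max_abs)
  }
  K <- K + t(K)
  diag(K) <- 1 + rowSums(abs(K))
  K
}

#' Simulate one participant's GVAR symptom series
#'
#' Generates a series on the study's beep grid from the stationary lag-1
#' recursion `y_t = mu + B (y_{t-1} - mu) + e_t`, `e_t ~ N(0, K^{-1})`, after
#' a burn-in discarded so the retained series starts near the stationary
#' distribution. A deterministic polynomial trend (in the global beep index)
#' is added after VAR generation, then whole beeps are deleted
#' missing-completely-at-random. Simulation operates on the latent
#' continuous scale; `vas = TRUE` additionally clips to the 0-100 visual
#' analogue scale.
#'
#' @param model A [true_gvar()].
#' @param design A [study_design()].
#' @param trend A [trend_spec()] (default: no trend).
#' @param missing A [missingness_spec()] (default: no missingness).
#' @param seed Optional integer seed.
#' @param id Participant identifier for the returned series.
#' @param burn_in Number of initial steps discarded (default 100).
#' @param vas If `TRUE`, clip values to \[0, 100\] (off by default; clipping
#'   breaks the Gaussian likelihood used by the estimators).
#' @return A [symptom_series()].
#' @export
simulate_series <- function(model, design = study_design(),
                            trend = NULL, missing = missingness_spec(0),
                            seed = NULL, id = "sim", burn_in = 100L,
                            vas = FALSE) {
  stopifnot(inherits(model, "true_gvar"))
  if (!is.null(seed)) set.seed(seed)
  p <- model$p
  Tn <- design$max_assessments
  if (is.null(trend)) trend <- trend_spec(p)
  Sigma <- chol2inv(chol(model$K))
  L <- t(chol(Sigma))
  n_steps <- burn_in + Tn
  eps <- L %*% matrix(rnorm(p * n_steps), p, n_steps)
  Y <- matrix(0, n_steps, p)
  y <- model$mu
  for (t in seq_len(n_steps)) {
    y <- model$mu + model$B %*% (y - model$mu) + eps[, t]
    Y[t, ] <- y
  }
  Y <- Y[burn_in + seq_len(Tn), , drop = FALSE]
  Y <- Y + trend_values(trend, seq_len(Tn))
  if (vas) Y <- pmin(pmax(Y, 0), 100)
  drop_beep <- runif(Tn) < missing$beep_missing_prob
  Y[drop_beep, ] <- NA_real_
  symptom_series(id, Y, design)
}

#' @keywords internal
random_true_gvar <- function(p = 6L, density = 0.3, max_abs = 0.4,
                             k_density = 0.3, mu_range = c(30, 70)) {
  B <- generate_stable_temporal_matrix(p, density, max_abs)
  K <- generate_precision_matrix(p, k_density)
  mu <- runif(p, mu_range[1], mu_range[2])
  true_gvar(mu, B, K)
}

#' Draw severity-group sizes as a composition of a target sample size
#'
#' Splits `total` participants into `n_groups` groups with sizes in
#' `[min_size, max_size]`: all groups start at `min_size` and the remainder
#' is distributed one member at a time to randomly chosen groups below
#' `max_size`. The defaults reproduce a 23-group, 73-participant structure
#' with sizes between 2 and 6.
#'
#' @param n_groups Number of groups.
#' @param total Total number of participants.
#' @param min_size,max_size Group size bounds.
#' @param seed Optional integer seed.
#' @return Integer vector of group sizes summing to `total`.
#' @export
draw_group_sizes <- function(n_groups = 23L, total = 73L, min_size = 2L,
                             max_size = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (total < n_groups * min_size || total > n_groups * max_size)
    stop("total incompatible with group size bounds")
  sizes <- rep(as.integer(min_size), n_groups)
  for (i in seq_len(total - n_groups * min_size)) {
    open <- which(sizes < max_size)
    pick <- open[sample.int(length(open), 1L)]
    sizes[pick] <- sizes[pick] + 1L
  }
  sizes
}

#' Simulated multi-participant EMA study with known ground truth
#'
#' `build_null_study()` generates the null scenario used to measure false
#' detection: every member of a severity group shares one true GVAR model
#' (drawn once per group), distinct groups get independent models, and
#' severity totals are assigned so that exactly the intended groups are
#' severity-matched. `build_alternative_study()` is the power-side
#' companion: each member's temporal matrix is the group template plus
#' independent perturbations of magnitude `effect_size` on a random subset
#' of edges (rescaled back to stationarity if needed).
#'
#' @param n_groups Number of severity groups.
#' @param group_sizes Integer vector of group sizes (all >= 2); by default a
#'   random composition of 73 members via [draw_group_sizes()].
#' @param design A [study_design()].
#' @param missing A [missingness_spec()] (default 18% MCAR beeps).
#' @param seed Optional integer seed.
#' @param density,max_abs Sparsity and magnitude of the group-template
#'   temporal matrices (defaults 0.3 and 0.4).
#' @param k_density Off-diagonal density of the template precision matrices.
#' @param severity_range Range of IDS-SR totals the group severity levels
#'   are drawn (without replacement) from.
#' @return An object of class `simulated_study`: a list with `series` (one
#'   [symptom_series()] per participant), `truth` (per-participant
#'   [true_gvar()]), `participants` (data frame: id, group, severity) and
#'   `design`.
#' @export
build_null_study <- function(n_groups = 23L, group_sizes = NULL,
                             design = study_design(),
                             missing = missingness_spec(0.18),
                             seed = NULL, density = 0.3, max_abs = 0.4,
                             k_density = 0.3, severity_range = c(15L, 51L)) {
  build_study(n_groups, group_sizes, design, missing, seed, density, max_abs,
              k_density, severity_range, effect_size = 0, n_perturbed = 0L)
}

#' @rdname build_null_study
#' @param effect_size Magnitude of the per-member edge perturbations (>= 0).
#' @param n_perturbed Number of temporal edges perturbed per member.
#' @export
build_alternative_study <- function(effect_size, n_groups = 23L,
                                    group_sizes = NULL,
                                    design = study_design(),
                                    missing = missingness_spec(0.18),
                                    seed = NULL, density = 0.3,
                                    max_abs = 0.4, k_density = 0.3,
                                    severity_range = c(15L, 51L),
                                    n_perturbed = 3L) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  build_study(n_groups, group_sizes, design, missing, seed, density, max_abs,
              k_density, severity_range, effect_size, n_perturbed)
}

#' @keywords internal
build_study <- function(n_groups, group_sizes, design, missing, seed,
                        density, max_abs, k_density, severity_range,
                        effect_size, n_perturbed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group_sizes)) {
    total <- min(n_groups * 6L, max(n_groups * 2L, round(n_groups * 73 / 23)))
    group_sizes <- draw_group_sizes(n_groups, total)
  }
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != n_groups) stop("need one size per group")
  if (any(group_sizes < 2L)) stop("every severity group must have >= 2 members")
  sev_pool <- seq.int(severity_range[1], severity_range[2])
  if (n_groups > length(sev_pool))
    stop("not enough distinct severity levels for the requested groups")
  severities <- sample(sev_pool, n_groups)
  series <- list(); truth <- list()
  ids <- character(0); grp <- integer(0); sev <- integer(0)
  for (g in seq_len(n_groups)) {
    template <- random_true_gvar(p = 6L, density = density, max_abs = max_abs,
                                 k_density = k_density)
    for (m in seq_len(group_sizes[g])) {
      member_model <- perturb_model(template, effect_size, n_perturbed)
      pid <- sprintf("p%02d_%d", g, m)
      series[[pid]] <- simulate_series(member_model, design,
                                       missing = missing, id = pid)
      truth[[pid]] <- member_model
      ids <- c(ids, pid); grp <- c(grp, g); sev <- c(sev, severities[g])
    }
  }
  structure(
    list(
      series = series,
      truth = truth,
      participants = data.frame(id = ids, group = grp, severity = sev,
                                stringsAsFactors = FALSE),
      design = design,
      group_sizes = group_sizes,
      severities = severities
    ),
    class = "simulated_study"
  )
}

#' @keywords internal
perturb_model <- function(template, effect_size, n_perturbed,
                          stability_margin = 0.9) {
  if (effect_size == 0 || n_perturbed == 0L) {
    # members share the template exactly (null scenario)
    return(template)
  }
  B <- template$B
  pos <- sample.int(length(B), n_perturbed)
  B[pos] <- B[pos] + sample(c(-1, 1), n_perturbed, replace = TRUE) * effect_size
  sr <- spectral_radius(B)
  if (sr >= 1) B <- B * (stability_margin / sr)
  true_gvar(template$mu, B, template$K)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "simulated_study: %d participants in %d severity groups (sizes %s)\n",
    nrow(x$participants), length(x$group_sizes),
    paste(range(x$group_sizes), collapse = "-")
  ))
  invisible(x)
}
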