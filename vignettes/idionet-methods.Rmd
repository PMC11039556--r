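---
title: "Person-specific symptom networks and the invariance test: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific symptom networks and the invariance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idionet)
```

## The question and the model

Two patients with the same depressive symptom severity score can differ in
how their symptoms drive each other over time. `idionet` estimates that
second layer — person-specific *symptom dynamics* — from ecological
momentary assessment (EMA) series and tests whether severity-matched
individuals can be described by one shared network.

The engine is the graphical vector autoregressive (GVAR) model. For one
person, let $y_t \in \mathbb{R}^6$ collect the six momentary symptom
composites (anhedonia, depressed mood, appetite change, restlessness,
irritability, lethargy) at beep $t$ on a fixed grid (5 beeps/day, 3 h
apart, 28 days, so at most 140 assessments). The lag-1 model is

$$ y_t = \mu + B\,(y_{t-1} - \mu) + \varepsilon_t,
   \qquad \varepsilon_t \sim N(0, K^{-1}), $$

with person-specific mean $\mu$, temporal coefficient matrix $B$ (entry
$b_{ij}$: the partialled effect of symptom $j$ at $t-1$ on symptom $i$ at
$t$, i.e. 3 h later — the directed *temporal network*), and residual
precision $K$. Standardizing $K$,
$\omega_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\kappa_{jj}}$, gives the
partial correlations of the *contemporaneous network*: associations within
a 3 h window after temporal effects are removed. Both networks encode
deviations from the person's own mean.

## Preprocessing

**Severity.** The IDS-SR has 30 items scored 0–3; appetite change and
weight change are asked as decrease/increase pairs, each contributing one
item, so 28 items enter the total (range 0–84; each pair contributes its
maximum here). Categories follow the published bands (0–13 none, 14–21
mild, 22–30 moderate, 31–38 severe, 39+ very severe). Severity groups are
the sets of participants sharing an identical total; totals held by a
single participant are reported as excluded, since matching requires a
partner.

**Composites.** Items on the 0–100 visual analogue scale are averaged into
the six composites after reverse-scoring (`x -> 100 - x`) of cheerful,
enthusiastic, calm, relaxed and energetic. A composite is missing only when
all its indicators are missing; with whole-beep missingness (an expired
questionnaire link kills the whole beep) partial availability is rare, and
the mean-of-available rule is a documented convention, not something the
data can distinguish.

**Detrending.** Slow drifts violate the stationary-mean assumption, so
every variable is detrended by an OLS cubic polynomial (linear, quadratic,
cubic) in the global beep index, fitted over the observed beeps on an
orthogonal (centered and scaled) basis. Trends are removed
unconditionally — removing a null trend is harmless and keeps the
procedure uniform — and the fitted coefficients are kept as diagnostics.
The beep index, not clock time, is the axis: the grid is equally spaced by
design, and missing slots keep their place in the indexing.

**Stationarity screen.** The model also assumes a stable autocovariance.
Each variable of the detrended series is screened with a Dickey–Fuller
regression (constant, no trend; lagged differences available via the
`lags` argument) using MacKinnon's finite-sample response-surface critical
values; the test is implemented in the package because no installed
dependency provides it. A variable passes when the unit-root null is
rejected at $\alpha = 0.05$; a participant passes only if all six pass,
constant series fail with an explicit zero-variance reason, and failures
are flagged for exclusion rather than silently dropped. The choice of
diagnostic, level and any-fail rule is a package decision — the assumption
is standard, the test used originally is not documented.

## Unregularized estimation: exact FIML by EM

Inference about individual differences uses unregularized fits, which are
asymptotically unbiased. Missing beeps are marginalized exactly: the
observed beeps split the grid into consecutive pairs separated by gaps of
$g$ missing beeps, and under the VAR(1) chain

$$ y_{t+g+1} \mid y_t \sim N\!\Big(\textstyle\sum_{j=0}^{g} B^j c
   + B^{g+1} y_t,\; \sum_{j=0}^{g} B^j \Sigma B^{j\prime}\Big),
   \qquad c = (I - B)\mu,\; \Sigma = K^{-1}, $$

so every observed value contributes and nothing is listwise-deleted
(full-information likelihood). The likelihood is *conditional on the first
observed beep*; `loglik_gvar()` can also evaluate the exact joint density
in which the first beep contributes its stationary marginal
$N(\mu, S)$, $S = BSB' + \Sigma$. The conditional convention is used for
fitting and model comparison because (i) on complete data its maximizer is
the classical lag-pair regression, giving an exact closed-form oracle the
test suite exploits, and (ii) it yields a closed-form maximization step.

Estimation is by EM rather than quasi-Newton search. The complete-data
model is the full chain between the first and last observed beep; because
the chain is Markov, the E-step only needs the Gaussian conditional
moments of each missing block given its two observed endpoints, computed
in closed form per gap length. The M-step is a multivariate regression of
$y_t$ on $(1, y_{t-1})$ on the expected sufficient statistics. This gives
a monotone likelihood ascent, deterministic results, exact one-step
convergence on complete data, and fits in tens of milliseconds at the
study's scale (the property tests verify agreement with a direct numerical
optimizer). Convergence is declared at a relative log-likelihood change
below `1e-8` (at most 500 iterations); initialization is lag-pair least
squares on adjacent observed pairs. $K$ is obtained from the fitted
residual covariance via its Cholesky inverse, so positive definiteness is
structural. Degenerate inputs are refused loudly: fewer than 30 completed
beeps is an error, fewer than 75 a warning (the design recommendation for
6-node networks), a constant variable is a singular-information error, and
an estimated spectral radius $\ge 1$ warns but does not error (the
conditional likelihood remains well defined).

Beeps with only some composites missing are coarsened to fully missing
(with a warning): the whole-beep missingness mechanism of the design never
produces them, and supporting partial beeps would complicate the exact
E-step for a case the pipeline cannot generate.

## Regularized estimation for display

Visualized networks use LASSO-sparsified fits so the strong edges stand
out; inference never does. For each pair on a grid of temporal and
contemporaneous penalties $(\lambda_B, \lambda_K)$ the fit alternates (i)
L1-penalized regression of each variable at $t$ on all variables at
$t-1$ (coordinate descent on the expected sufficient statistics) and (ii)
a graphical-lasso update of $K$ on the expected residual covariance, with
expectation steps at the current parameters handling missing beeps. Both
penalized solvers are implemented in the package (no installed dependency
accepts sufficient statistics) and are tested against their closed-form
limits: penalties near zero reproduce the unregularized fit, large
penalties give empty networks, and the graphical lasso at $\rho = 0$
equals the matrix inverse. Model selection minimizes
$\mathrm{BIC} = -2\,\ell + \log(N)\,k$ with $N$ the number of observed
beeps (the effective-sample-size convention is a package decision) and
$k$ the count of means, nonzero temporal edges, residual variances and
nonzero partial correlations. Grids default to 20 log-spaced values per
penalty from the smallest empty-network penalty down to 1% of it.

## The invariance test (INIT)

For a severity group of $m \ge 2$ members the test compares, by AIC, two
models sharing one likelihood:

* **heterogeneous (free):** every member's $(\mu_i, B_i, K_i)$ estimated
  independently; $k = 63m$ parameters for 6 variables;
* **homogeneous (constrained):** one $B$ and one $K$ for all members —
  all temporal and contemporaneous edges, including autoregressive
  diagonal and residual variances, constrained equal — with means
  $\mu_i$ left person-specific because the networks are defined on
  deviations from the person's own mean; $k = 57 + 6m$.

Constraining all of $B$ and $K$ (rather than exempting the diagonal) is
the package's reading of "all edges constrained equal"; the test weighs
temporal and contemporaneous differences equally simply by constraining
both blocks in one comparison. The constrained optimum is found by the
same EM with a pooled M-step (within-member-centered regression for the
shared $B$, member-profiled intercepts), initialized from the averaged
free fits. The group is flagged *heterogeneous* iff
$\mathrm{AIC}_{free} < \mathrm{AIC}_{constrained}$, i.e. iff the pooled
log-likelihood gain of freeing the edges exceeds $57(m-1)$; exact ties
resolve to homogeneous. The rule is deliberately conservative — a
type II error (missing a true difference) is more likely than a type I —
and the suite's power measurements confirm it: differences on a few edges
of size 0.4 are detected in only a minority of replicates, while
differences on six or more edges of size 0.5 are detected in the large
majority. Nesting ($\ell_{hom} \le \ell_{free}$) is asserted after every
paired fit; in the rare event an EM path stops short, the free fits are
restarted from the shared solution and the better optimum kept.

## Aggregation, bootstrap, null calibration

The headline quantity is the proportion of participants displaying
differential dynamics: every member of a flagged group counts, and the
numerator is divided by the total membership of all severity groups. The
95% interval resamples *severity groups* (the independent units) with
replacement to the original group count, 10 000 times, and takes the
2.5th/97.5th percentiles of the replicate proportions (a percentile CI;
the replicate size and interval type are package conventions). Because
groups are independent and the flags are deterministic given the data,
resampling fixed flags is equivalent to refitting within each replicate.

The false-detection rate of the entire procedure is measured by
simulation: studies in which every group's members share one true network
(drawn once per group) are pushed through the full pipeline — detrending,
screening, INIT — and the mean proportion of participants falling in
flagged groups is reported with its Monte-Carlo standard error.
Per-replicate seeds are drawn once from the master seed, so extending the
replicate count never changes earlier replicates. Groups that fail to fit
are excluded from numerator and denominator and counted; a numerical
failure is not evidence of heterogeneity.

## What the generator emulates — and what it does not

The synthetic-data module defines the conditions under which every claim
in the test suite is measured: 23 severity groups with sizes 2–6
(73 participants), the 140-beep grid, and 18% whole-beep
missing-completely-at-random beeps, which reproduces the observed mean of
roughly 115 completed assessments. Group-template networks are random
sparse stable models — temporal density 0.3 with entries bounded by 0.4
in magnitude (unstable draws are rescaled to spectral radius 0.9), and
diagonally dominant sparse precision matrices — because the original
estimated networks are not public; this is the one place the null
scenario is necessarily a stand-in. Series are simulated with a 100-step
burn-in so retained draws start near the stationary distribution, on the
latent continuous scale by default: clipping to the 0–100 scale would
break the Gaussian likelihood identities the oracle tests rely on, so VAS
clipping is an explicit opt-in. Severity totals are drawn without
replacement from the observed 15–51 range.

Real EMA data differ in ways the generator does not imitate: missingness
is plausibly not completely at random, nights interrupt the 3 h rhythm
(the likelihood treats the grid as one contiguous chain; whether the
original analysis broke chains at night boundaries is unknown), items are
bounded and skewed rather than Gaussian, and dynamics may be nonlinear or
multi-timescale. Passing tests therefore certify the statistical
machinery under its own assumptions, not those features of real data.

Under these study-matched null conditions the measured false-detection
rate (20 replicates, 460 group tests) is well below the few-percent
level — consistent with the asymptotic rarity of
$\chi^2_{57(m-1)} > 114(m-1)$ — and comfortably on the conservative side.
The companion alternative-study generator perturbs a configurable number
of template edges by a configurable magnitude per member (restabilizing
when needed), which is how the power figures above are measured.

## Problem sizes used by the checks

The test suite and the acceptance script favour configurations that keep
a full run in minutes: 20 null-simulation replicates of the 23-group
study, 100 simulated persons for edge-recovery error, 50 replicates per
condition for the power/type-I comparison, and consistency checks at
5 000 time points. All are package choices of simulation size; estimates
of rates carry the Monte-Carlo error those sizes imply.

## Known limitations

Only lag-1 linear dynamics; no multilevel pooling across persons (the
inference is strictly idiographic); no MAR/MNAR missingness mechanisms in
the generator; no item-level simulation; no edge-level localization of
*which* edges differ when a group is flagged; and the AIC decision offers
no per-group error control beyond its built-in conservatism. The
sensitivity analysis relating detection to severity and group size is a
one-line logistic regression on the INIT report
(`glm(heterogeneous ~ severity + size, family = binomial, data = report)`)
rather than a pipeline stage.
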