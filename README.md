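# idionet

Person-specific dynamic networks of depressive symptoms from ecological
momentary assessment (EMA) data — and a test of whether patients matched on
symptom severity share the same network.

Clinical guidelines characterize major depressive disorder mainly by
overall symptom severity. But two patients with identical severity scores
can differ in *symptom dynamics*: how their symptoms drive each other over
time. `idionet` is for researchers in network psychometrics and intensive
longitudinal psychiatry who want to (1) estimate each person's symptom
network from EMA time series, (2) test severity-matched groups for shared
versus differential dynamics, (3) report the proportion of participants
with differential dynamics and its uncertainty, and (4) calibrate the
procedure's false-detection rate by simulation.

## The model and the test

Each participant's six momentary symptom composites
$y_t \in \mathbb{R}^6$ (anhedonia, depressed mood, appetite change,
restlessness, irritability, lethargy; 0–100 visual analogue scale, 5 beeps
a day for 28 days) follow a lag-1 graphical vector autoregression (GVAR):

$$y_t = \mu + B\,(y_{t-1}-\mu) + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0,\,K^{-1}).$$

* $B$ is the **temporal network**: $b_{ij}$ is the partialled effect of
  symptom $j$ on symptom $i$ three hours later.
* $K$ standardized to partial correlations
  $\omega_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ is the
  **contemporaneous network**: associations within a 3 h window.

Estimation is full-information maximum likelihood — missing beeps are
marginalized exactly along the lag-1 chain, via a closed-form EM — with
LASSO/BIC regularized fits available for sparse visualization. The
**individual network invariance test (INIT)** then compares, within each
group of participants sharing an IDS-SR severity total, the freely
estimated member networks against a model with all temporal and
contemporaneous edges constrained equal (means stay person-specific), by
AIC; lower AIC wins and ties count as "no difference". Group flags
aggregate into the proportion of participants with differential dynamics,
with a 95% CI from resampling severity groups with replacement (10 000
draws), and a companion null simulation measures how often the whole
procedure flags differences when none exist.

## Worked example

Simulate one participant on the study grid, fit their networks, and test a
severity-matched pair:

```r
library(idionet)
set.seed(1)

truth <- true_gvar(mu = runif(6, 30, 70),
                   B = generate_stable_temporal_matrix(6, density = 0.3, max_abs = 0.4),
                   K = generate_precision_matrix(6, density = 0.3))
beeps <- simulate_series(truth, study_design(28, 5),
                         missing = missingness_spec(0.18), seed = 2, id = "p1")
beeps
#> symptom_series 'p1': 140 beeps, 120 completed, 6 variables

fit <- fit_gvar_ml(detrend(beeps))
fit
#> GVAR model (6 variables, 120 completed beeps)
#>   logLik -863.34 on 63 parameters (AIC 1852.67)
#>   temporal edges: spectral radius 0.339; converged: TRUE (6 iter)

# a second participant generated from the *same* network: INIT should —
# and does — prefer the shared (homogeneous) model
peer <- simulate_series(truth, missing = missingness_spec(0.18), seed = 3, id = "p2")
grp <- severity_group(31L, list(p1 = detrend(beeps), p2 = detrend(peer)))
init_test(grp)
#> INIT group 31 (severity 31, 2 members): AIC free 3710.3 vs constrained 3666.6 -> homogeneous
```

The fitted objects expose `B`, `K`, `Omega` (partial correlations),
`loglik`, and convergence details; `fit_gvar_lasso()` adds a BIC-selected
sparse fit, and `write_gvar_model()` exports JSON plus edge-list CSVs.

## The analysis workflow

`analysis/` holds the staged study analysis, each script a thin driver
over the package that prints what it found and writes tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | synthetic 73-participant cohort in 23 severity groups (sizes 2–6), 18% missing beeps, with known ground truth (9 groups truly homogeneous) |
| `02_preprocess.R` | cubic detrending + stationarity screen; preprocessing report |
| `03_fit_networks.R` | FIML fits for everyone; sparse LASSO/BIC exports for one exemplar severity level |
| `04_invariance.R` | INIT per severity group; report with ground-truth comparison |
| `05_bootstrap.R` | proportion of participants with differential dynamics + 95% group-bootstrap CI |
| `06_null_simulation.R` | false-detection rate under a matched null (20 replicates) |

On the shipped configuration the cohort run prints, at stage 4–6:

```
INIT over 23 severity groups: 14 flagged heterogeneous
type I (flagged among truly homogeneous groups): 0 of 9
power (flagged among truly heterogeneous groups): 14 of 14
differential dynamics: 45 of 73 participants = 61.6%
  95% bootstrap CI (10000 group resamples): 40.3% - 82.4%
null simulation: 20 replicates, mean false-detection rate 0.00% (MC s.e. 0.00%)
```

i.e. the procedure recovers exactly the groups built to differ, estimates
the cohort's true 62% share of differential dynamics at 61.6% with a wide
between-group interval, and flags essentially nothing when differences are
absent by construction.

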