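# jfrailty

Joint frailty models for recurrent-event gap times that are informatively
censored by death, with a generalized-linear-mixed-model (GLMM) estimation
engine.

## Who this is for

Biostatisticians analysing registry-style follow-up data in which each
subject can experience a recurrent event (e.g. successive additional
primary cancers — multimorbidity) and follow-up ends at death or at an
administrative cutoff. Because subjects at high recurrence risk tend to
die sooner, treating death as ordinary censoring biases a standard frailty
analysis; this package fits both processes jointly.

## The model

On the gap-time (renewal) scale, subject *j* with covariates *x<sub>j</sub>*
has hazards

    h_R(t) = h_R0(t) exp(x_j' beta + u_j)     (recurrent events)
    h_D(t) = h_D0(t) exp(x_j' gamma + v_j)    (death)

with unspecified baselines and correlated log-normal frailties
(u_j, v_j) ~ N(0, Gamma), Gamma = [theta_u^2, rho theta_u theta_v;
rho theta_u theta_v, theta_v^2]. Estimation maximizes the Breslow-tie Cox
partial log-likelihood plus the Gaussian frailty log-density over
(beta, gamma, u, v) by Newton–Raphson (BLUP), alternating with approximate
REML trace updates for (theta_u^2, theta_v^2, rho) until the update map
reaches its fixed point. Prediction supplies Breslow baseline survival with
exponential tail completion, subject-level event-free survival
S(t;X) = S_R0(t)^exp(X'beta) S_D0(t)^exp(X'gamma), and mean residual life
m(t;X) = ∫_t^∞ S(s;X) ds / S(t;X) in closed form. A simulator of the whole
data-generating process and a replicated-study harness (bias / SEE / SE /
coverage, joint vs naive separate frailty models) are included.

## Worked example

```r
library(jfrailty)

sim <- simulate_dataset(preset_config("set1"), seed = 2026)
censoring_summary(sim$table)$death_censoring_proportion
#> [1] 0.848

fit <- fit_joint(sim$table)
fit
#> Joint frailty model fit (500 subjects, 538 gaps)
#> converged after 23 outer / 65 total inner iterations
#>    process term estimate     se     hr
#>  recurrent   x1  -0.1802 0.3282 0.8351
#>  recurrent   x2   0.9353 0.1718 2.5479
#>   terminal   x1  -0.8173 0.2534 0.4416
#>   terminal   x2   0.4793 0.1225 1.6149
#> frailty variances: theta_u^2 = 0.1288, theta_v^2 = 0.4649, rho = 0.9810

predict(fit, X = c(1, 0), times = c(0, 365, 1825))
#>   profile time  survival      mrl
#> 1       1    0 1.0000000 12578.51
#> 2       1  365 0.9882583 12360.58
#> 3       1 1825 0.8733534 12424.41
```

One simulated registry of 500 subjects (~85% of subjects never observed to
die, as in the base scenario): the fit recovers the terminal covariate
effects (truth gamma = (-0.8, 0.5)) with standard errors from the inverse
information; hazard ratios exponentiate the coefficients. The prediction
block gives a subject with x = (1, 0) and zero frailty an 87% chance of
being event-free at five years (1825 days) and a mean residual life of
~12,400 days — long, because this scenario's hazards are low. Note the
single-replicate frailty estimates are noisy at this event sparsity
(~0.07 recurrent events/subject); `run_study()` averages them over
replicates, where e.g. mean theta_u is within a few percent of truth.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/jfrailty.R simulate --preset set1 --seed 1 --out tab.csv
Rscript inst/cli/jfrailty.R validate tab.csv
Rscript inst/cli/jfrailty.R fit --table tab.csv --out fit.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's headline computations from
scratch: it simulates the five calibration scenarios and reports their mean
death-censoring percentages, fits the joint model to replicated
base-scenario datasets (bias of the binary recurrent-covariate effect,
coverage of the terminal-effect confidence interval, bias of the frailty
correlation), and fits the naive separate terminal model to the
high-variance scenario (bias of its covariate effect). Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the JSON maps each quantity to its
value and the replication used.

## Layout

- `R/event_table.R` — long-format event tables, validation, design matrices
- `R/simulate.R` — scenario presets and the renewal gap-time simulator
- `R/partial_lik.R` — risk sets, penalized partial likelihood, score,
  observed information
- `R/fit.R`, `R/fit_single.R` — joint BLUP/REML fit and the separate
  standard-frailty comparator
- `R/predict.R` — Breslow baselines, tail completion, survival and mean
  residual life
- `R/sim_study.R` — replicated simulation studies and comparisons
- `vignettes/joint-frailty-glmm.Rmd` — model, algorithm and design notes
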