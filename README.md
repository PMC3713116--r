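# llogis4 — competing-risks cumulative incidence with a four-parameter log-logistic distribution

`llogis4` is an R package for **parametric cumulative incidence modelling
under competing risks**.  It is aimed at biostatisticians analysing
time-to-event data in which the occurrence of one event (say, a live birth)
precludes the observation of another (a stillbirth or abortion), and who
want a parametric alternative to the usual nonparametric
(Aalen–Johansen) estimate — for long-term prediction, for smooth hazard
summaries, and for efficiency when a parametric family genuinely fits.

## The model

Competing-risks data are pairs (T, δ) with δ = 0 for censoring and
δ = k ∈ {1, 2} for the event type.  The two central quantities are the
cause-specific hazard h\_k(t) and the cumulative incidence function

    F_k(t) = P(T ≤ t, δ = k) = ∫₀ᵗ S(u) h_k(u) du,

where S = S₁·S₂ is the overall survival, factorised into cause-specific
survival functions.

The package's centrepiece is an **improper four-parameter extension of the
log-logistic distribution**.  Pushing the two-parameter log-logistic
cumulative hazard H(t) = log(1 + λt^τ) through the Hougaard stable
transformation (with the frailty scale collapsed by υ = θ^{2−α}) gives

    S(t; λ, τ, θ, α) = exp{ −(θ²/α) [ (H(t)/θ + 1)^α − 1 ] },
    h(t; λ, τ, θ, α) = θ · λτt^{τ−1}/(1 + λt^τ) · (H(t)/θ + 1)^{α−1},

with λ, τ, θ > 0 and α unrestricted.  The family reduces to the
two-parameter log-logistic at α = θ = 1, covers decreasing, unimodal and
U-shaped hazards, and — crucially for cumulative incidence work — is
*improper* for α < 0, with a mass S(∞) = exp(θ²/α) of subjects who never
experience the event, exactly the plateau behaviour a cause-specific
incidence curve shows.

Around that family the package provides:

* closed-form evaluators (`surv()`, `haz()`, `dens()`, `cumhaz()`,
  `tail_mass()`) for the four-parameter and two-parameter log-logistic,
  Weibull and Gompertz families;
* `parametric_cif()` — cumulative incidence by adaptive quadrature of
  ∫ S₁S₂ h\_k, and `nonparametric_cif()`/`kaplan_meier()` — the
  Kaplan–Meier / Nelson–Aalen (Aalen–Johansen) comparator;
* `simulate_sample()` — competing-risks simulation by all-cause
  inverse-transform sampling with binomial cause allocation at hazard odds
  h₁/(h₁+h₂), plus Bernoulli censoring;
* `fit_mle()` — cause-separable maximum likelihood with multi-start BFGS,
  analytic scores, Fisher-information covariance, AIC/BIC, and
  `compare_models()` for likelihood-ratio tests of nested families;
* `run_study()` — a seeded Monte-Carlo bias/MSE study runner with
  report rendering (`render_report()`, `write_report()`).

## Worked example

Simulate one trial of 1000 subjects from the log-logistic design
(cause 1: λ = 0.3, τ = 2.97; cause 2: λ = 0.03, τ = 1.1; 7% censoring),
fit the four-parameter family to each cause, and compare the fitted
cumulative incidence with the nonparametric estimate and the truth:

```r
library(llogis4)
d <- design_loglogistic(n = 1000, seed = 2026)
s <- simulate_sample(d)
table(s$event)
#>   0   1   2
#>  77 874  49

fit <- fit_mle(s, family = "ll4")
fit
#> <cr_fit> families: ll4 / ll4  n = 1000
#>   cause 1:
#>          lambda    tau  theta  alpha
#> estimate 1.0964 2.8179 0.2099 1.5275
#> se       0.4938 0.3071 0.1803 0.1840
#>   cause 2:
#>          lambda    tau   theta     alpha
#> estimate 0.0027 1.3871  8.3609  -64.6112
#> se       0.0318 0.2133 98.7168 1636.9198
#>   logLik = -1419.042  AIC = 2854.085  BIC = 2893.347

round(step_at(nonparametric_cif(s, 1), report_times()), 3)
#> [1] 0.113 0.217 0.363 0.480 0.667 0.840 0.922
round(cif_from_fit(fit, 1)$values, 3)
#> [1] 0.109 0.226 0.358 0.480 0.662 0.836 0.923
round(parametric_cif(d$cause1, d$cause2, 1)$values, 3)   # truth
#> [1] 0.111 0.226 0.359 0.485 0.676 0.848 0.924
```

The fitted incidence tracks the generating truth to within Monte-Carlo
noise at every report time {0.75, 1, 1.25, 1.5, 2, 3, 5}.  The individual
parameter estimates are less stable than the curve (the θ/α pair is weakly
identified — different (θ, α) combinations produce nearly identical
incidence curves), which is why the package reports and validates fits on
the incidence scale.  A full bias/MSE study over many replicates is one
call:

```r
st <- run_study(design_loglogistic(n = 1000),
                estimators = c("ll4", "nonparametric"),
                n_reps = 200, seed = 101)
st    # renders mean CIF, bias and MSE x 100 per estimator, cause and time
```

A thin command-line front end over the same functions is installed at
`inst/cli/crworkbench.R` with `simulate`, `fit` and `study` subcommands.

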