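# ppsh — proportional principal stratum hazards for semi-competing risks

`ppsh` estimates the **direct** treatment effect on a first nonfatal event
(e.g., heart-failure hospitalization) when death competes with it. The usual
Cox analysis that censors at death estimates the *cause-specific* (CS)
hazard ratio, which mixes the direct effect with an indirect effect through
survival: a treatment that keeps frail patients alive makes the treated arm
look worse on morbidity. The package targets instead the hazard ratio within
the principal stratum of **always survivors** at each time `t` — patients who
would be alive at `t` under either arm — where no competing risk operates.

## The model

The proportional principal stratum hazards (PPSH) model keeps the Cox form
on the stratum-specific hazard,

```
lambda^P(t | Z) = exp(beta * Z) * lambda0^P(t),
```

so `exp(beta)` is the PS hazard ratio, reducing to the ordinary hazard ratio
when there is no mortality. Membership in the stratum is identified
probabilistically through a shared gamma frailty `theta ~ Gamma(gamma,
gamma)` (mean 1, variance `1/gamma`): with
`A = (gamma + eta_T) / (gamma + eta_Y,cf + eta_T)` built from conditional
cumulative hazards recovered in closed form from the marginal survival
estimates, an at-risk subject's membership probability at an event time is
`A^gamma` (`A^(gamma+1)` for the subject having the event), and these
probabilities weight a Cox partial likelihood solved by Newton-Raphson
(Breslow ties). Because `gamma` is not identifiable from the observed data,
it is a **prespecified sensitivity parameter**: results are reported over a
grid of `gamma` values with the CS fit as the homogeneous (`gamma = Inf`)
reference, and confidence intervals come from a subject-level percentile
bootstrap that reruns both estimation stages per replicate.

A simulator for semi-competing-risks trials (gamma or inverse-Gaussian
frailty, exponential death and censoring, administrative cap, event times
inverted from a treated-arm cumulative hazard constructed so the true PS
hazard ratio is exactly `r`) supports validation and operating-characteristic
studies.

## Worked example

```r
library(ppsh)

## a heterogeneous trial with a strong mortality benefit
cfg <- simulation_config(nu0 = 0.4, nu1 = 0.2, gamma = 0.5, n = 300)
coh <- simulate_cohort(cfg, seed = 1)

estimate_ps_hr(coh, gamma_tilde = 0.5)
#> Proportional principal stratum hazards fit
#>   gamma-tilde = 0.5 (frailty variance 2)
#>   beta = -0.6166   HR = 0.5398
#>   events: 149 at 149 distinct times; 3 iterations; converged

sensitivity_grid(coh, gammas = c(0.5, 2, 5), B = 200, seed = 1)
#>   gamma_tilde   beta    hr ci_low ci_high proportionality_p converged n_failed
#> 1         0.5 -0.617 0.540  0.378   0.770             0.155      TRUE        0
#> 2         2.0 -0.544 0.580  0.437   0.795             0.249      TRUE        0
#> 3         5.0 -0.526 0.591  0.413   0.838             0.281      TRUE        0
#> 4         Inf -0.532 0.587  0.429   0.798             0.230      TRUE        0
```

The generator's true PS hazard ratio is `r = 0.5`. With the frailty
dispersion correctly specified (`gamma_tilde = 0.5`, first row) the PS
estimate is 0.540 on this single cohort; the CS fit (last row,
`gamma_tilde = Inf`) is attenuated toward 1 (0.587) because conditioning on
survival leaves frailer subjects in the treated arm. As `gamma_tilde` grows —
assuming an ever more homogeneous population — the PS rows climb toward the
CS value, which is the expected pattern for a treatment that prolongs
survival. The `proportionality_p` column is a 1-df score test of the
time-constancy of `beta` (transform `g(t) = t`); none of the rows signals a
violation. Percentile bootstrap intervals rerun the whole two-stage pipeline
per resample:

```r
bootstrap_ci(coh, gamma_tilde = 0.5, B = 200, seed = 1)
#> Percentile bootstrap (B = 200, 0 failed) for gamma-tilde = 0.5
#>   HR = 0.5398   95% CI (0.3589, 0.7683)
```

Real data enter through a column-mapped reader, so arbitrary source headers
work:

```r
coh <- read_cohort("trial.csv", column_map = c(
  subject_id = "ID", arm = "TRT", event_time = "HOSPDAY",
  event_observed = "HOSP", followup_time = "LASTDAY",
  death_observed = "DIED"))
sensitivity_grid(coh, B = 1000, seed = 2026)
```

A thin command-line front end with `fit`, `bootstrap`, `sensitivity`,
`simulate` and `study` subcommands lives at
`system.file("cli", "ppsh.R", package = "ppsh")`.

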