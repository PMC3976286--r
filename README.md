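# lungtrace

Individual-level microsimulation of the natural history and detection of
lung cancer. lungtrace traces a person from birth to diagnosis through four
linked models:

1. **Smoking history** — configurable initiation/cessation/intensity
   distributions and Gompertz other-cause mortality, emulating the output
   contract of cohort smoking-history generators;
2. **Tumor onset** — the smoking-driven two-stage clonal expansion (TSCE)
   model: initiation at rate ν(d), clonal expansion of initiated cells
   (division α, death β), malignant transformation at μ₂, with
   dose–response in packs per day and piecewise-constant parameters over
   each person's never/current/former segments, solved in closed form;
3. **Growth and metastasis** — exponential growth from a single cell,
   N(t) = e^{λt}, with λ ~ Gamma(K, θ) fixed at onset; cells detach at the
   dimensionless rate ξ (cumulative detached cells ξ(e^{λt} − 1)) and seed
   nodal and distant metastases with deposition rates μₙ ≥ μₘ, giving
   conditional c.d.f. F(t|λ) = 1 − exp(−μ ξ (e^{λt} − 1) κ);
4. **Detection** — a competing process through the primary tumor (hazard
   linear in size, ηs + w₀), nodal metastases (offset w₁) or distant
   metastases (offset w₂), evaluated on a yearly cycle, recording size and
   stage (N0M0 / NxM0 / M1) at diagnosis.

Forward, the chain produces a calendar-time lung-cancer population with
both observable characteristics (age, sex, stage, tumor diameter, smoking
status at diagnosis) and unobservable ones (onset age, growth rate,
metastasis times). Inverted, `fit_size_stage()` calibrates the nine
progression/detection parameters (ξ, μₙ, μₘ, K, θ, η, w₀, w₁, w₂) to an
observed joint tumor-size × stage table — the surface SEER-style registries
publish — by simulation-based least squares with Nelder–Mead under common
random numbers.

The package is written for epidemiological modelers who need a transparent,
testable natural-history engine: every distribution has an exposed closed
form, every sampler is checked against an independent oracle, and the
calibration machinery is the same code path as the forward simulator.

## Worked example

```r
library(lungtrace)

pp <- progression_params()   # ξ = 0.01, μn = 8.05e-9, μm = 2.78e-9, K = 3.80, θ = 1.15
dp <- detection_params()     # η = 1e-4 /cm³/yr, w0 = 0.065, w1 = 1.5e3, w2 = 7e4 /yr

# mean growth rate and implied volume doubling time
pp$K * pp$theta                      # 4.4 per year
doubling_time_days(pp$K * pp$theta)  # 57.9 days

# population timing of metastasis: peaks of the gamma-mixed densities
marginal_met_mode(pp, "nodal")       # 6.60 years from onset
marginal_met_mode(pp, "distant")     # 6.79 years from onset

# simulate a cohort of detected cases (onsets uniform over ages 40-80,
# yearly detection, Gompertz other-cause censoring)
cases <- simulate_cases(50000, pp, dp, seed = 42)
report_cases(cases)
#> <lc_report> 41267 detected cases
#>   stage %: N0M0 96.2, NxM0 2.0, M1 1.8
#>   diameter (cm): mean 44.25, median 24.20, sd 104.97, variance 11017.98
mean(cases$t_detect)                 # 6.21 years from onset to diagnosis

summarize_unobservables(cases)$durations[, c("variable", "mean", "median")]
#>   variable             mean median
#> 1 onset_to_nodal_yr    4.62   4.00
#> 2 onset_to_distant_yr  4.37   3.94
#> 3 onset_to_dx_yr       6.21   6
```

The mean onset-to-diagnosis of about 6 years and the metastasis-density
peaks at 6.6/6.8 years match the published calibration of this model
family; the stage mix and detected sizes under the same printed parameter
estimates do not (the model is almost entirely N0M0 here), which is a
documented inconsistency among the published anchors, not a tuning target —
see the methods vignette (`vignettes/lung-cancer-natural-history.Rmd`) for
the unit-convention analysis and diagnostics.

Calibration against a synthetic "observed" table with known truth:

```r
obs <- make_fixture_table(pp, dp, n = 2e5, seed = 101)    # synthetic registry table
fit <- fit_size_stage(obs, init_pp = pp, init_dp = dp,
                      options = fit_options(n_sim = 2e4, maxit = 300))
tidy(fit)      # nine parameter estimates
glance(fit)    # loss, iterations, convergence
autoplot(obs)  # stage-conditional size histograms (ggplot2)
```

A thin command-line surface (`inst/scripts/lungtrace-cli.R`) exposes
`simulate`, `predict`, `fit`, and `report` subcommands over YAML
configurations (`inst/extdata/example-config.yaml`); every subcommand
honors `--seed` and `--config`.

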