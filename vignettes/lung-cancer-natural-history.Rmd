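---
title: "Modeling the natural history and detection of lung cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the natural history and detection of lung cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtrace)
```

lungtrace traces a lung cancer from a person's birth to diagnosis in four
linked stages: smoking history, smoking-driven tumor onset, tumor growth
with metastasis, and competing-mode detection. Each stage is an independent
module with its own parameters, and the whole chain can be run forward as a
calendar-time population microsimulation or inverted by simulation-based
least squares to calibrate the progression and detection parameters to a
joint tumor-size × stage table of the kind cancer registries such as SEER
publish. This vignette explains the model, the choices behind its defaults,
and the limits of what its tests demonstrate.

## Smoking histories

The onset model consumes, for each person: sex, birth year, smoking
initiation and cessation ages (either may be absent), a lifetime smoking
intensity in packs per day (ppd), and an age at death from causes other
than lung cancer. The package generates these from configurable parametric
distributions (`smoking_config()`): a sex-specific ever-smoking
probability, a normal initiation age truncated to 10–40 years, an
exponential time to cessation, a lognormal intensity, and Gompertz
other-cause mortality with hazard $a e^{bx}$ ($a = 8.5\times10^{-5}$,
$b = 0.085$ per year by default, giving a median lifespan near 77 years).

These defaults describe a generic mid-20th-century cohort and are
deliberately simple: intensity is one lifetime constant per smoker (the
dose–response below uses ppd as a scalar), initiation probabilities do not
vary by birth cohort, and cessation is memoryless. National smoking-history
generators resolve all of these; any generator honoring the same output
contract can be substituted by writing its output to the delimited listing
(`write_histories()` / `read_histories()`). A `vital_cutoff_year` option
mirrors generators whose vital-status follow-up stops at a fixed calendar
year; by default there is no cut-off and mortality is extrapolated from the
Gompertz model.

## Tumor onset: two-stage clonal expansion

Onset — the appearance of the first malignant cell — follows the two-stage
clonal expansion (TSCE) model: normal tissue produces initiated cells at
rate $\nu$ per year; initiated cells divide at rate $\alpha$, die at rate
$\beta$, and transform to malignant at rate $\mu_2$. Smoking enters through
response functions on the identifiable parameters. With dose $d$ in ppd,
the default linear form is

$$\nu(d) = \nu_0 (1 + a_1 d), \qquad
  \gamma(d) = \gamma_0 (1 + a_2 d), \qquad
  \alpha(d) = \alpha_0,$$

where $\gamma = \alpha - \beta - \mu_2$ is the net proliferation rate of
initiated clones and $\beta$ is recovered as
$\alpha - \gamma - \mu_2$. An exponential-saturation form
($\nu_0 e^{a_1 d}$, $\gamma_0 e^{a_2 d}$) is selectable. $\mu_2$ is held
fixed (default $10^{-7}$ per year, a typical somatic rate): with survival
data alone only two of the three rates $\nu, \mu_2, \beta$ are
identifiable, and this convention keeps the $(\nu_0, \alpha_0, \gamma_0,
a_1, a_2)$ surface.

The survival function of the onset age uses the filtered-Poisson
representation: with $\Phi(u, t)$ the probability that a clone initiated at
age $u$ has spawned no malignant cell by age $t$,

$$S(t) = \exp\!\left(-\int_0^t \nu(u)\,\bigl(1 - \Phi(u, t)\bigr)\,du\right),$$

and $\Phi$ satisfies the Riccati equation
$\partial_s \Phi = \alpha \Phi^2 - (\alpha + \beta + \mu_2)\Phi + \beta$
in backward time. Because each person's parameters are piecewise constant
over their never/current/former smoking segments, the equation is solved
in closed form segment by segment (the solution moves between the roots
$r_1 < 1 < r_2$ of the quadratic), composing backward from age $t$; the
inner integral also has a closed form, so no numerical ODE solver is
involved. The test suite checks this closed form against both a
numerical ODE integration and a direct Gillespie simulation of the
branching process.

The numeric defaults of `response_params()` are placeholders chosen once
for plausibility, not fitted values: they give a lifetime onset risk by age
80 of roughly 0.5% for never smokers, 16% for a lifelong one-pack-a-day
smoker, and 54% for two packs (onset of a first malignant cell, not
diagnosed cancer, so figures above diagnosed-incidence rates are expected
for heavy exposure). Users with access to cohort-fitted response parameters
should supply them through the `tsce` configuration section, optionally per
sex.

Onset ages are sampled by inverse transform on an age grid (0.1-year steps
by default, linear interpolation within cells), censored at the earlier of
age 110 and the person's other-cause death age.

## Growth and metastasis

The primary tumor grows exponentially from one cell of volume
$10^{-9}\,\mathrm{cm}^3$: $N(t) = e^{\lambda t}$ cells $t$ years after
onset. The growth rate $\lambda$ is fixed at onset and drawn from a gamma
distribution with shape $K = 3.80$ and scale $\theta = 1.15$ per year
(defaults are published SEER-calibrated estimates of this model family),
so the mean rate $K\theta \approx 4.4$ per year corresponds to a volume
doubling time $365 \ln 2 / (K\theta) \approx 58$ days. Time- or
size-dependent growth is out of scope.

Cells detach from the primary at the dimensionless rate $\xi \in (0, 1]$;
the cumulative number detached by $t$ is $\xi(e^{\lambda t} - 1)$, always
below the tumor's own cell count. Detached cells seed nodal and distant
metastases with deposition rates $\mu_n \ge \mu_m$ (nodal sites are at
least as reachable as distant ones), giving site-specific hazards and
c.d.f.s conditional on $\lambda$:

$$h(t \mid \lambda) = \mu\,\xi\,\lambda e^{\lambda t}\,\kappa, \qquad
  F(t \mid \lambda) = 1 - \exp\!\bigl(-\mu\,\xi\,(e^{\lambda t} - 1)\,\kappa\bigr),$$

where $\kappa$ converts cells to the unit in which $\mu$ is expressed.
Nodal and distant processes are conditionally independent given $\lambda$
(no coupling is specified by the model), and secondary metastasis from
metastases is excluded. Deposits grow at $3\lambda$ (nodal) and $4\lambda$
(distant) from one cell; this enters only through the optional
detectability lag in the detection module.

**Units of the deposition rates.** The model's sources leave the unit of
$\mu$ unstated, and the choice changes the time scale of metastasis by
large factors. The package's canonical default measures detached bulk in
mm³ ($\kappa = 10^{-6}$ mm³/cell): with the default estimates this places
the peaks of the gamma-mixed marginal metastasis-time densities at 6.6
(nodal) and 6.8 (distant) years from onset, matching the metastasis timing
reported for this parameter set, whereas cell-count units would place them
near 4.1/4.3 years and cm³ units near 7.9/8.1. `met_size_unit` exposes all
three. This is a reconstruction from the model's stated assumptions, and it
cannot reconcile every published anchor at once: under the same defaults
the reported primary-tumor volumes at metastasis formation (medians of
order 0.1 cm³) would require an effective per-cell rate roughly five
orders of magnitude larger. We keep the timing-consistent convention and
record the volume discrepancy as a known inconsistency rather than
adjusting any estimate.

The marginal (population) density of metastasis time mixes the conditional
density over the gamma law,
$f(t) = \int_0^\infty g(\lambda; K, \theta)\, h(t\mid\lambda)
e^{-H(t\mid\lambda)}\, d\lambda$, evaluated by adaptive quadrature
(`marginal_met_pdf()`); its peak is located by bounded scalar search
(`marginal_met_mode()`). The quadrature caps the $\lambda$ range where the
cumulative hazard exceeds 50, which keeps the narrow integrand support at
large $t$ resolved; densities are checked to integrate to 1 within
$10^{-3}$. A nodal-only variant multiplies in the distant survival factor.

## Detection

Detection competes across three routes. At primary size $s$ the
primary-route hazard is linear, $\eta s + w_0$ per year; nodal and distant
metastases, once detectable, add offsets $w_1$ and $w_2$. The stage-
dependent total hazards are therefore $z_{00} = \eta s + w_0$,
$z_{10} = z_{00} + w_1$, $z_{01} = z_{00} + w_2$,
$z_{11} = z_{00} + w_1 + w_2$. With the default estimates
($\eta = 10^{-4}$ per cm³ per year, $w_0 = 0.065$,
$w_1 = 1.5\times10^3$, $w_2 = 7\times10^4$ per year) the metastasis
offsets dwarf the primary hazard: once a metastasis exists the tumor is
found at the next evaluation, which reflects symptomatic presentation.

Patients present for possible detection on a fixed cycle (1 year by
default). Each cycle, the stage indicators are updated first (a metastasis
counts `met_lag_years` after formation; default 0), then the tumor is
detected with probability $1 - e^{-z\,\Delta}$ at the hazard of the current
size and stage; on detection the route is drawn in proportion to the three
component hazards and size and stage are recorded at that evaluation time.
Stage updates precede the detection test within a cycle, matching the
yearly-visit discretization. As the cycle shrinks the scheme converges to
the continuous-time inhomogeneous exponential (verified on a
constant-hazard toy in the tests). The size unit of $\eta$ is itself
configurable (`size_unit`, default cm³), since the sources are silent
here too.

**A structural caveat.** Under these default estimates the simulated stage
mix at diagnosis is dominated by N0M0 (~96%) and detected tumors are
implausibly large, while calibrations of this model family report a far
more metastatic mix (roughly a quarter N0M0, half M1) and a median
diameter near 3.7 cm. No unit convention for $\mu$ and $\eta$ reproduces
the metastasis timing, the stage mix, and the metastasis-size scale
simultaneously — the published anchors are mutually inconsistent under
this reconstruction, and the acceptance checks report the failing ones
with diagnostics instead of hiding them. Relatedly, in this model family
the growth-rate selection at diagnosis necessarily runs one way: detected
M1 cases grow *faster* than N0M0 cases (fast growth reaches metastatic
sizes sooner, while slow tumors accumulate more time-based detection
hazard per unit size), so reports of slower-growing M1 primaries cannot
arise from this structure.

## Population simulation

`simulate_population()` runs birth cohorts through the whole chain in
calendar time: each year's births (scaled by a simulation factor, default
0.1) receive histories and death ages, onset ages are sampled, tumors
progress and pass the yearly detection cycle censored by death, and
detected cases whose diagnosis year falls in the observation window are
emitted with both their observable and unobservable characteristics.
Yearly alive counts are accumulated alongside. Proportions (not counts)
are invariant to the scale factor, which the tests check. The pre-1909
birth convention (2,877,000 per year) is available through
`constant_births()`; later years are user data.

## Calibration

`fit_size_stage()` estimates the nine progression/detection parameters
$(\xi, \mu_n, \mu_m, K, \theta, \eta, w_0, w_1, w_2)$ by simulation-based
least squares: the objective simulates a cohort of detected cases under
candidate parameters, histograms it over 3 stages × 20 one-cm diameter
bins (left-closed; >20 cm lumped into the last bin), and sums squared
differences in proportions against the observed table. Nelder–Mead runs in
a transformed space — logs for positive parameters and a logit for
$r = \mu_m/\mu_n$, which enforces the ordering — and in *scaled deviations
from the initial point*, so the initial simplex takes comparable steps
(0.5 on the log scale by default) in every coordinate regardless of the
parameters' magnitudes.

Three numerical choices matter:

* **Common random numbers.** Every objective evaluation reuses one seed,
  making the objective deterministic in the parameters; without this the
  simplex chases Monte-Carlo noise. The residual CRN noise still sets a
  loss floor of order $(1 - \sum p^2)(1/n_{sim} + 1/n_{obs})$; pushing the
  loss far below the observed table's own sampling floor means fitting
  noise, so a two-stage protocol (moderate budget, then a restart with a
  larger `n_sim` and a fresh CRN seed from the first optimum) is the
  recommended and tested usage.
* **$\xi$ is not separately identifiable.** The detachment rate enters the
  model only through $\xi\mu_n$ and $\xi\mu_m$, so `fit_options()` fixes it
  at its initial value by default (`fixed = "xi"`); the deposition rates
  absorb the products. All nine parameters are still reported.
* **Weak identification of the gamma shape.** The observed table pins the
  mean growth rate well but its shape information degrades when much of
  the size distribution lands in the lumped >20 cm bin, as happens under
  the canonical defaults; recovery experiments achieve roughly ±30% on $K$
  there, against ±15–20% for $\theta$ and the deposition rates.

Confidence intervals come from percentile bootstrap over multinomial
resamples of the observed table (`bootstrap_ci()`), a documented
substitute for asymptotic intervals; with $\xi$ profiled its interval is
degenerate at the point estimate.

## What the synthetic data do and do not show

The fixture generator (`make_fixture_table()`, `simulate_cases()`) draws
onset ages uniformly over 40–80 years with Gompertz other-cause censoring
and runs the canonical progression + detection pipeline — the study
conditions for the calibration experiments. Passing tests therefore
demonstrate internal consistency (sampler ↔ closed forms ↔ independent
oracles) and recoverability of parameters from data *generated by the
model itself*. They do not validate the model against real registries: no
histology, no screening programs, no stage-specific survival after
diagnosis, no secondary metastasis, no time-varying smoking intensity, and
registry artifacts such as missing stage are not simulated.

## Problem sizes and numerics

The shipped tests use $10^4$–$2\times10^5$ simulated tumors per scenario,
$2\times10^4$ branching-process replicates per oracle comparison, and a
two-stage calibration of $5\times10^4$ then $2\times10^5$ cases per
evaluation — sizes chosen so the whole suite runs on a laptop-class single
core in a few minutes while keeping Monte-Carlo error well inside the
3-standard-error bands the property tests assert. Exponentials are capped
at the double-precision limit (overflowing sizes become `Inf` and are
detected on the current cycle); quadrature tolerances are $10^{-8}$
relative; ties at segment boundaries resolve as left-closed intervals
(`status_at` is "former" exactly at the quit age, a metastasis counts at
exactly its formation time).
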