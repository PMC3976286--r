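#' Smoking dose-response parameters for the two-stage clonal expansion model
#'
#' The two-stage clonal expansion (TSCE) model describes carcinogenesis as
#' initiation of normal cells at rate \eqn{\nu} (per year), clonal expansion
#' of initiated cells (division rate \eqn{\alpha}, death rate \eqn{\beta}),
#' and malignant transformation at rate \eqn{\mu_2}; tumor onset is the
#' appearance of the first malignant cell. Smoking enters through response
#' functions linking intensity in packs per day (ppd) to the identifiable
#' parameters: with the default `"linear"` form,
#' \eqn{\nu(d) = \nu_0 (1 + a_1 d)} and net proliferation
#' \eqn{\gamma(d) = \gamma_0 (1 + a_2 d)}, with \eqn{\alpha(d) = \alpha_0}
#' and \eqn{\beta = \alpha - \gamma - \mu_2}. An `"exponential"` saturation
#' form (\eqn{\nu_0 e^{a_1 d}}, \eqn{\gamma_0 e^{a_2 d}}) is selectable.
#'
#' The numeric defaults are documented placeholders giving plausible
#' lifetime onset risks (roughly 0.5% for never smokers and 16% for a
#' lifelong 1-ppd smoker by age 80); they are configuration inputs, not
#' fitted values, and should be replaced with study-specific estimates when
#' available. Sex-specific parameter sets are supported by supplying one
#' `response_params` per sex in configuration.
#'
#' @param nu0 Baseline initiation rate (per year).
#' @param alpha0 Initiated-cell division rate (per year).
#' @param gamma0 Baseline net proliferation rate
#'   \eqn{\alpha - \beta - \mu_2} (per year).
#' @param a1,a2 Dose-response coefficients (per ppd) on initiation and net
#'   proliferation.
#' @param mu2 Malignant transformation rate (per initiated cell per year).
#' @param form Response functional form, `"linear"` or `"exponential"`.
#' @return An object of class `response_params`.
#' @export
response_params <- function(nu0 = 0.04, alpha0 = 7, gamma0 = 0.13,
                            a1 = 5, a2 = 1, mu2 = 1e-7,
                            form = c("linear", "exponential")) {
  form <- match.arg(form)
  if (any(c(nu0, alpha0, gamma0, mu2) < 0))
    abort("baseline TSCE rates must be nonnegative.")
  structure(
    list(nu0 = nu0, alpha0 = alpha0, gamma0 = gamma0, a1 = a1, a2 = a2,
         mu2 = mu2, form = form),
    class = "response_params"
  )
}

#' TSCE rates at a given smoking dose
#'
#' Maps a smoking intensity (packs per day) to the TSCE rate set
#' (initiation `nu`, division `alpha`, death `beta`, transformation `mu2`)
#' through the response functions of a [response_params()].
#'
#' @param rp A [response_params()].
#' @param d Smoking dose in packs per day, `>= 0` (vectorized).
#' @return A tibble with columns `d`, `nu`, `alpha`, `beta`, `mu2`.
#' @examples
#' dose_response(response_params(), c(0, 1, 2))
#' @export
dose_response <- function(rp, d) {
  r <- response_rates(rp, d)
  tibble::tibble(d = d, nu = r$nu, alpha = r$alpha, beta = r$beta,
                 mu2 = r$mu2)
}

# plain-list version used in inner loops
response_rates <- function(rp, d) {
  stopifnot(inherits(rp, "response_params"))
  if (any(d < 0)) abort("dose `d` must be nonnegative.")
  if (rp$form == "linear") {
    nu <- rp$nu0 * (1 + rp$a1 * d)
    gamma <- rp$gamma0 * (1 + rp$a2 * d)
  } else {
    nu <- rp$nu0 * exp(rp$a1 * d)
    gamma <- rp$gamma0 * exp(rp$a2 * d)
  }
  beta <- rp$alpha0 - gamma - rp$mu2
  if (any(nu < 0) || any(gamma < 0))
    abort("response functions produced negative rates.")
  if (any(beta < 0))
    abort("`alpha - gamma - mu2` fell below zero: reduce the dose effect or raise `alpha0`.")
  k <- length(d)
  list(nu = nu, alpha = rep(rp$alpha0, k), beta = beta, mu2 = rep(rp$mu2, k))
}

# --- core survival machinery -------------------------------------------------
#
# P(no malignant cell by t) under the filtered-Poisson representation:
#   S(t) = exp(-integral_0^t nu(u) (1 - phi(u, t)) du)
# where phi(u, t) is the probability that a clone initiated at u spawns no
# malignant lineage by t. On a constant-parameter segment phi satisfies the
# Riccati equation d(phi)/ds = alpha phi^2 - (alpha+beta+mu2) phi + beta
# (s = backward time), solved in closed form between the roots r1 < 1 < r2.

# advance phi backward over lengths L (vector) with scalar rates; returns the
# new phi and the integral of phi over the step
tsce_phi_step <- function(phi0, L, alpha, beta, mu2) {
  phi <- phi0
  I <- numeric(length(L))
  on <- L > 0
  if (!any(on)) return(list(phi = phi, I = I))
  if (alpha < 1e-12) {
    A <- beta + mu2
    if (A < 1e-14) {
      I[on] <- phi0[on] * L[on]
      return(list(phi = phi, I = I))
    }
    ss <- beta / A
    e <- exp(-A * L[on])
    phi[on] <- ss + (phi0[on] - ss) * e
    I[on] <- ss * L[on] + (phi0[on] - ss) * (1 - e) / A
    return(list(phi = phi, I = I))
  }
  A <- alpha + beta + mu2
  D <- sqrt(A^2 - 4 * alpha * beta)
  r1 <- (A - D) / (2 * alpha)
  r2 <- (A + D) / (2 * alpha)
  C0 <- (phi0[on] - r1) / (phi0[on] - r2)
  R <- C0 * exp(-D * L[on])
  phi[on] <- (r1 - r2 * R) / (1 - R)
  I[on] <- r1 * L[on] + (r1 - r2) / D * (log1p(-R) - log1p(-C0))
  list(phi = phi, I = I)
}

# survival at times t for piecewise-constant parameters; seg is a list of
# parallel vectors lo, hi, nu, alpha, beta, mu2 covering [0, Inf)
tsce_survival_segments <- function(t, seg) {
  phi <- rep(1, length(t))
  H <- numeric(length(t))
  for (j in rev(seq_along(seg$lo))) {
    L <- pmax(0, pmin(t, seg$hi[j]) - seg$lo[j])
    st <- tsce_phi_step(phi, L, seg$alpha[j], seg$beta[j], seg$mu2[j])
    H <- H + seg$nu[j] * (L - st$I)
    phi <- st$phi
  }
  out <- exp(-H)
  out[t <= 0] <- 1
  out
}

# never/current/former exposure segments for one person
tsce_segments <- function(history, rp) {
  tsce_segments_one(history$init_age, history$quit_age,
                    history$intensity_ppd, rp)
}

tsce_segments_one <- function(init, quit, ppd, rp) {
  if (is.na(init)) {
    breaks <- numeric(0)
    doses <- 0
  } else if (is.na(quit)) {
    breaks <- init
    doses <- c(0, ppd)
  } else {
    breaks <- c(init, quit)
    doses <- c(0, ppd, 0)
  }
  rates <- response_rates(rp, doses)
  c(list(lo = c(0, breaks), hi = c(breaks, Inf)), rates)
}

#' Survival function of the age at tumor onset
#'
#' Probability that a person with the given smoking history has developed no
#' malignant cell by age `t`. TSCE parameters are piecewise constant over the
#' person's never/current/former smoking segments (through [dose_response()]
#' applied to the intensity at each age); within segments the two-stage
#' survival is evaluated in closed form, and segments are composed by
#' integrating the clone-extinction probability backward from age `t`.
#'
#' @param history A single-row histories tibble (see [sample_histories()]).
#' @param rp A [response_params()].
#' @param t Ages in years (vectorized).
#' @return Survival probabilities in `[0, 1]`, equal to 1 at `t = 0` and
#'   nonincreasing in `t`.
#' @export
onset_survival <- function(history, rp, t) {
  stopifnot(nrow(history) == 1)
  if (any(t < 0)) abort("`t` must be nonnegative.")
  tsce_survival_segments(t, tsce_segments(history, rp))
}

#' Sample ages at tumor onset
#'
#' Inverse-c.d.f. sampling of the TSCE onset age for each person: the onset
#' survival curve is evaluated on a regular age grid (`grid_step` years up
#' to `max_age`) and a uniform draw is inverted by linear interpolation.
#' Onset is censored at the earlier of `max_age` and the person's
#' other-cause death age; censored persons get `NA`.
#'
#' @param histories A histories tibble.
#' @param rp A [response_params()].
#' @param max_age Upper age bound for the grid (years).
#' @param grid_step Age-grid resolution in years.
#' @param seed Optional integer seed.
#' @return Numeric vector of onset ages (`NA` where no onset occurs).
#' @export
sample_onset_ages <- function(histories, rp, max_age = 110, grid_step = 0.1,
                              seed = NULL) {
  if (max_age <= 0) abort("`max_age` must be positive.")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(histories)
  u <- runif(n)
  out <- rep(NA_real_, n)
  init <- histories$init_age
  quit <- histories$quit_age
  ppd <- histories$intensity_ppd
  oc <- histories$oc_death_age
  for (i in seq_len(n)) {
    cap <- min(max_age, oc[i])
    seg <- tsce_segments_one(init[i], quit[i], ppd[i], rp)
    S_cap <- tsce_survival_segments(cap, seg)
    if (u[i] <= S_cap) next # no onset before censoring
    grid <- seq(0, cap + grid_step, by = grid_step)
    S <- tsce_survival_segments(grid, seg)
    # S is nonincreasing; find the bracketing grid cell and interpolate
    k <- findInterval(-u[i], -S)
    k <- min(max(k, 1), length(grid) - 1)
    s0 <- S[k]; s1 <- S[k + 1]
    frac <- if (s0 > s1) (s0 - u[i]) / (s0 - s1) else 0
    out[i] <- min(grid[k] + frac * grid_step, cap)
  }
  out
}
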