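#' Primary tumor size under exponential growth
#'
#' The primary tumor grows from a single cell: after `t` years at growth
#' rate `lambda` (per year) it holds `exp(lambda * t)` cells;
#' `volume_at()` converts to cm^3 with the cell volume in `pp`.
#'
#' @param lambda Growth rate per year.
#' @param t Time since onset in years, `>= 0`.
#' @param pp A [progression_params()] (for the cell volume).
#' @return Cell count or volume in cm^3. Exponents are capped near the
#'   double-precision limit; sizes beyond it return `Inf`.
#' @export
cells_at <- function(lambda, t) {
  if (any(t < 0, na.rm = TRUE)) abort("`t` must be nonnegative.")
  exp(pmin(lambda * t, 709))
}

#' @rdname cells_at
#' @export
volume_at <- function(lambda, t, pp = progression_params()) {
  cells_at(lambda, t) * pp$cell_volume
}

#' Tumor volume doubling time
#'
#' Converts an exponential growth rate (per year) to the volume doubling
#' time in days, `365 * log(2) / lambda`.
#'
#' @param lambda Growth rate per year, `> 0`.
#' @return Doubling time in days.
#' @examples
#' doubling_time_days(6.30) # about 40 days
#' @export
doubling_time_days <- function(lambda) {
  if (any(lambda <= 0)) abort("`lambda` must be positive.")
  365 * log(2) / lambda
}

#' Sphere diameter/volume conversions
#'
#' Tumor size is measured clinically as the maximum diameter; assuming the
#' tumor grows as a sphere, `d = (6 v / pi)^(1/3)` and `v = pi d^3 / 6`.
#'
#' @param v Volume in cm^3, `> 0`.
#' @param d Diameter in cm, `> 0`.
#' @return Diameter in cm, or volume in cm^3.
#' @examples
#' diameter_from_volume(0.06) # 0.49 cm
#' @export
diameter_from_volume <- function(v) {
  if (any(v[is.finite(v)] <= 0)) abort("volume must be positive.")
  (6 * v / pi)^(1 / 3)
}

#' @rdname diameter_from_volume
#' @export
volume_from_diameter <- function(d) {
  if (any(d[is.finite(d)] <= 0)) abort("diameter must be positive.")
  pi * d^3 / 6
}

#' Cumulative number of detached cells
#'
#' Cells detach from the primary tumor at the dimensionless rate `xi`
#' applied to its exponential growth, so the total number of cells detached
#' by time `t` is `xi * (exp(lambda * t) - 1)`, always below the tumor's
#' own cell count when `xi <= 1`.
#'
#' @inheritParams cells_at
#' @param xi Detachment rate in (0, 1].
#' @return Detached cell count.
#' @export
detached_cells <- function(lambda, xi, t) {
  xi * expm1(pmin(lambda * t, 709))
}

# detached bulk expressed in the metastasis-hazard size unit
detached_size <- function(lambda, pp, t) {
  detached_cells(lambda, pp$xi, t) * met_unit_scale(pp)
}

#' Metastasis-time distribution conditional on the growth rate
#'
#' The hazard of a metastasis (nodal or distant) is driven by the detached
#' tumor bulk: `h(t) = mu * xi * lambda * exp(lambda * t) * kappa`, where
#' `kappa` converts cells to the unit of `mu` (see
#' [progression_params()]), giving the c.d.f.
#' `F(t) = 1 - exp(-mu * xi * (exp(lambda * t) - 1) * kappa)`.
#'
#' @param lambda Growth rate per year.
#' @param pp A [progression_params()].
#' @param t Years since tumor onset, `>= 0`.
#' @param site `"nodal"` or `"distant"` (selects `mu_n` or `mu_m`).
#' @return `met_cdf()`: probabilities; `met_hazard()`: hazards per year.
#' @export
met_cdf <- function(lambda, pp, t, site = c("nodal", "distant")) {
  site <- match.arg(site)
  if (any(t < 0)) abort("`t` must be nonnegative.")
  mu <- if (site == "nodal") pp$mu_n else pp$mu_m
  -expm1(-mu * detached_size(lambda, pp, t))
}

#' @rdname met_cdf
#' @export
met_hazard <- function(lambda, pp, t, site = c("nodal", "distant")) {
  site <- match.arg(site)
  mu <- if (site == "nodal") pp$mu_n else pp$mu_m
  mu * pp$xi * lambda * cells_at(lambda, t) * met_unit_scale(pp)
}

#' Draw tumor growth rates
#'
#' Gamma-distributed per-tumor growth rates with shape `K` and scale
#' `theta`.
#'
#' @param n Number of draws.
#' @param pp A [progression_params()].
#' @param seed Optional integer seed.
#' @return Numeric vector of rates per year.
#' @export
sample_growth_rates <- function(n, pp = progression_params(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rgamma(n, shape = pp$K, scale = pp$theta)
}

#' Sample nodal and distant metastasis times
#'
#' Conditionally on the growth rate, nodal and distant metastasis times are
#' independent with c.d.f. [met_cdf()]; they are drawn by inversion,
#' `t = log1p(E / (mu * xi * kappa)) / lambda` with `E` standard
#' exponential.
#'
#' @param lambda Vector of growth rates (one tumor each).
#' @param pp A [progression_params()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `t_nodal`, `t_distant` (years from
#'   onset).
#' @export
sample_met_times <- function(lambda, pp = progression_params(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  kap <- met_unit_scale(pp)
  n <- length(lambda)
  tibble::tibble(
    t_nodal = log1p(rexp(n) / (pp$mu_n * pp$xi * kap)) / lambda,
    t_distant = log1p(rexp(n) / (pp$mu_m * pp$xi * kap)) / lambda
  )
}

#' Simulate tumor courses
#'
#' Draws, for `n` tumors, a growth rate and the pair of metastasis times,
#' attached to supplied onset ages.
#'
#' @param n Number of tumors.
#' @param pp A [progression_params()].
#' @param onset_age Onset ages in years (recycled to length `n`).
#' @param seed Optional integer seed.
#' @return A tibble with `id`, `onset_age`, `lambda`, `t_nodal`,
#'   `t_distant`.
#' @export
simulate_courses <- function(n, pp = progression_params(), onset_age = 0,
                             seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  lambda <- sample_growth_rates(n, pp)
  mets <- sample_met_times(lambda, pp)
  tibble::tibble(
    id = seq_len(n),
    onset_age = rep(onset_age, length.out = n),
    lambda = lambda,
    t_nodal = mets$t_nodal,
    t_distant = mets$t_distant
  )
}

# integrand shared by the marginal densities; survive_distant multiplies in
# the probability that no distant metastasis has occurred by t
marginal_integrand <- function(lambda, t, pp, mu, survive_distant = FALSE) {
  kap <- met_unit_scale(pp)
  e <- pmin(lambda * t, 700)
  dens <- dgamma(lambda, shape = pp$K, scale = pp$theta) *
    mu * pp$xi * lambda * exp(e) * kap *
    exp(-mu * pp$xi * expm1(e) * kap)
  if (survive_distant)
    dens <- dens * exp(-pp$mu_m * pp$xi * expm1(e) * kap)
  dens
}

#' Marginal metastasis-time density over the growth-rate distribution
#'
#' The population density of the time from tumor onset to nodal or distant
#' metastasis, mixing the conditional density of [met_cdf()] over the gamma
#' growth-rate distribution:
#' \deqn{f(t) = \int_0^\infty g(\lambda; K, \theta)\, h(t \mid \lambda)
#'   e^{-H(t \mid \lambda)}\, d\lambda,}
#' evaluated by adaptive quadrature. `marginal_met_mode()` locates the peak
#' of this density by bounded scalar search.
#'
#' @param pp A [progression_params()].
#' @param t Years from onset (vectorized in `marginal_met_pdf()`).
#' @param site `"nodal"` or `"distant"`.
#' @param lambda_max Upper quadrature limit for the growth rate.
#' @param interval Search interval (years) for the mode.
#' @return Density values per year, or the mode in years.
#' @examples
#' \donttest{
#' marginal_met_mode(progression_params(), "nodal") # about 6.6 years
#' }
#' @export
marginal_met_pdf <- function(pp, t, site = c("nodal", "distant"),
                             lambda_max = 30) {
  site <- match.arg(site)
  mu <- if (site == "nodal") pp$mu_n else pp$mu_m
  kap <- met_unit_scale(pp)
  vapply(t, function(tt) {
    # beyond cumulative hazard ~50 the integrand is numerically zero; capping
    # the quadrature range keeps the narrow support at large t resolved
    up <- if (tt > 0) min(lambda_max, log1p(50 / (mu * pp$xi * kap)) / tt)
          else lambda_max
    q <- tryCatch(
      integrate(marginal_integrand, 0, up, t = tt, pp = pp, mu = mu,
                rel.tol = 1e-8, subdivisions = 400L),
      error = function(e) abort(paste0(
        "quadrature failed at t = ", tt, ": ", conditionMessage(e)))
    )
    q$value
  }, numeric(1))
}

#' @rdname marginal_met_pdf
#' @export
marginal_met_mode <- function(pp, site = c("nodal", "distant"),
                              interval = c(0.05, 30), lambda_max = 30) {
  site <- match.arg(site)
  optimize(function(tt) marginal_met_pdf(pp, tt, site, lambda_max),
           interval = interval, maximum = TRUE, tol = 1e-4)$maximum
}

#' Density of nodal-only metastasis times
#'
#' Density of the time to nodal metastasis among tumors that have not yet
#' developed distant metastases by that time:
#' \eqn{\int g(\lambda) f_n(t \mid \lambda) (1 - F_m(t \mid \lambda))
#' d\lambda}. It is bounded above by the marginal nodal density.
#'
#' @inheritParams marginal_met_pdf
#' @return Density values per year.
#' @export
nodal_only_pdf <- function(pp, t, lambda_max = 30) {
  kap <- met_unit_scale(pp)
  vapply(t, function(tt) {
    up <- if (tt > 0)
      min(lambda_max, log1p(50 / (pp$mu_m * pp$xi * kap)) / tt)
    else lambda_max
    integrate(marginal_integrand, 0, up, t = tt, pp = pp,
              mu = pp$mu_n, survive_distant = TRUE,
              rel.tol = 1e-8, subdivisions = 400L)$value
  }, numeric(1))
}
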