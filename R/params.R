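#' Tumor progression parameters
#'
#' Parameters governing exponential growth of the primary tumor and the
#' detachment-driven hazards of nodal and distant metastasis. The primary
#' tumor grows from a single cell as \eqn{N(t) = e^{\lambda t}} cells; the
#' per-tumor growth rate \eqn{\lambda} is drawn once at onset from a gamma
#' distribution with shape `K` and scale `theta` (per year). Cells detach
#' from the primary at the dimensionless rate `xi`, so the cumulative number
#' of detached cells by time `t` is \eqn{\xi(e^{\lambda t} - 1)}; detached
#' cells seed nodal and distant metastases with deposition rates `mu_n` and
#' `mu_m`. Deposition rates are expressed per unit of detached tumor volume
#' per year in the unit named by `met_size_unit`; the default `"mm3"`
#' reproduces the published metastasis-time density peaks near 6.4 (nodal)
#' and 6.8 (distant) years with the default estimates.
#'
#' @param xi Detachment rate, a fraction in (0, 1]: not all tumor cells
#'   detach.
#' @param mu_n,mu_m Transfer-and-deposition rates for nodal and distant
#'   metastases (per unit detached volume per year); `mu_n >= mu_m > 0`
#'   since detached cells reach nodal sites at least as easily as distant
#'   sites.
#' @param K,theta Shape and scale (per year) of the gamma distribution of
#'   the growth rate; the mean growth rate is `K * theta`.
#' @param cell_volume Volume of a single tumor cell in cm^3.
#' @param met_growth Growth-rate multipliers for metastatic deposits
#'   relative to the primary (nodal deposits grow at `3 * lambda`, distant
#'   at `4 * lambda`).
#' @param met_size_unit Unit in which detached tumor bulk enters the
#'   metastasis hazard: `"mm3"` (default), `"cm3"`, or `"cells"`.
#' @return An object of class `progression_params` (a named list).
#' @examples
#' pp <- progression_params()
#' pp$K * pp$theta # mean growth rate, about 4.4 per year
#' @export
progression_params <- function(xi = 0.01,
                               mu_n = 8.05e-9,
                               mu_m = 2.78e-9,
                               K = 3.80,
                               theta = 1.15,
                               cell_volume = 1e-9,
                               met_growth = c(nodal = 3, distant = 4),
                               met_size_unit = c("mm3", "cm3", "cells")) {
  met_size_unit <- match.arg(met_size_unit)
  if (!is.numeric(xi) || xi <= 0 || xi > 1)
    abort("`xi` must lie in (0, 1].")
  if (mu_m <= 0 || mu_n < mu_m)
    abort("need `mu_n >= mu_m > 0`.")
  if (K <= 0 || theta <= 0) abort("`K` and `theta` must be positive.")
  if (cell_volume <= 0) abort("`cell_volume` must be positive.")
  structure(
    list(xi = xi, mu_n = mu_n, mu_m = mu_m, K = K, theta = theta,
         cell_volume = cell_volume,
         met_growth = c(nodal = unname(met_growth[1]),
                        distant = unname(met_growth[2])),
         met_size_unit = met_size_unit),
    class = "progression_params"
  )
}

# cells -> met_size_unit conversion factor
met_unit_scale <- function(pp) {
  switch(pp$met_size_unit,
         cells = 1,
         cm3 = pp$cell_volume,
         mm3 = pp$cell_volume * 1e3)
}

#' @export
print.progression_params <- function(x, ...) {
  cat("<progression_params>\n")
  cat(sprintf("  xi = %g, mu_n = %g, mu_m = %g (per %s per yr)\n",
              x$xi, x$mu_n, x$mu_m, x$met_size_unit))
  cat(sprintf("  growth rate ~ Gamma(shape %g, scale %g /yr); cell volume %g cm3\n",
              x$K, x$theta, x$cell_volume))
  cat(sprintf("  metastasis growth multipliers: nodal %g, distant %g\n",
              x$met_growth[["nodal"]], x$met_growth[["distant"]]))
  invisible(x)
}

#' Tumor detection parameters
#'
#' Competing-mode detection of a tumor through its primary mass or through
#' nodal or distant metastases, evaluated on a fixed cycle. The primary-route
#' hazard is linear in primary tumor size, `eta * s + w0` (per year); nodal
#' and distant metastases, once present, add the stage-dependent offsets `w1`
#' and `w2`. With the default estimates `w1, w2 >> w0`: detection becomes
#' near-certain within a cycle of metastatic spread.
#'
#' @param eta Efficiency of detection by tumor size (per size unit per
#'   year).
#' @param w0 Offset hazard for detection at stage N0M0 (per year).
#' @param w1 Additional hazard once nodal metastases are present (per year).
#' @param w2 Additional hazard once distant metastases are present (per
#'   year).
#' @param cycle_years Length of the detection-evaluation cycle in years
#'   (patients present for possible detection once per cycle).
#' @param size_unit Unit of primary tumor size `s` in the linear hazard:
#'   `"cm3"` (default), `"mm3"`, or `"cells"`.
#' @param met_lag_years Optional detectability lag: a metastasis counts
#'   toward stage and its detection offset only `met_lag_years` after it
#'   forms (default 0: present means detectable).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(eta = 1.0e-4,
                             w0 = 0.065,
                             w1 = 1.50e3,
                             w2 = 7.00e4,
                             cycle_years = 1,
                             size_unit = c("cm3", "mm3", "cells"),
                             met_lag_years = 0) {
  size_unit <- match.arg(size_unit)
  if (any(c(eta, w0, w1, w2) < 0))
    abort("hazard parameters must be nonnegative.")
  if (cycle_years <= 0) abort("`cycle_years` must be positive.")
  if (met_lag_years < 0) abort("`met_lag_years` must be nonnegative.")
  structure(
    list(eta = eta, w0 = w0, w1 = w1, w2 = w2, cycle_years = cycle_years,
         size_unit = size_unit, met_lag_years = met_lag_years),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  cat(sprintf("  eta = %g per %s/yr; offsets w0 = %g, w1 = %g, w2 = %g /yr\n",
              x$eta, x$size_unit, x$w0, x$w1, x$w2))
  cat(sprintf("  cycle %g yr; metastasis detectability lag %g yr\n",
              x$cycle_years, x$met_lag_years))
  invisible(x)
}
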