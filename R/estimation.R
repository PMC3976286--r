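#' Joint tumor-size by stage tables
#'
#' The calibration surface: a normalized joint distribution of detected
#' cases over disease stage (N0M0 / NxM0 / M1) and 1-cm diameter bins from
#' 0 to 20 cm (left-closed, right-open; tumors over 20 cm are lumped into
#' the last bin). `new_size_stage_table()` validates and classes a long
#' tibble; `histogram_cases()` builds one from case records.
#'
#' @param x A tibble with columns `stage`, `bin_lo`, `bin_hi`, `prop`.
#' @param n_cases Number of cases behind the proportions.
#' @return A `size_stage_table`: a tibble of 60 rows (3 stages by 20 bins)
#'   whose `prop` column sums to 1, with attribute `n_cases`.
#' @export
new_size_stage_table <- function(x, n_cases = NA_integer_) {
  need <- c("stage", "bin_lo", "bin_hi", "prop")
  if (!all(need %in% names(x)))
    abort("a size-stage table needs columns stage, bin_lo, bin_hi, prop.")
  if (any(x$prop < 0)) abort("proportions must be nonnegative.")
  if (abs(sum(x$prop) - 1) > 1e-9)
    abort("proportions must sum to 1 (within 1e-9).")
  x <- dplyr::arrange(tibble::as_tibble(x),
                      factor(.data$stage, stage_levels()), .data$bin_lo)
  structure(x, n_cases = n_cases,
            class = c("size_stage_table", class(tibble::tibble())))
}

size_stage_grid <- function() {
  tidyr::expand_grid(stage = stage_levels(), bin_lo = 0:19) |>
    dplyr::mutate(bin_hi = .data$bin_lo + 1)
}

#' @rdname new_size_stage_table
#' @param records A case tibble with `stage` and `diameter_cm` columns.
#' @examples
#' cases <- simulate_cases(2000, seed = 1)
#' tab <- histogram_cases(cases)
#' sum(tab$prop)
#' @export
histogram_cases <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    abort("cannot histogram an empty record set.")
  n <- nrow(records)
  counts <- records |>
    dplyr::mutate(bin_lo = pmin(floor(.data$diameter_cm), 19)) |>
    dplyr::count(.data$stage, .data$bin_lo)
  tab <- size_stage_grid() |>
    dplyr::left_join(counts, by = c("stage", "bin_lo")) |>
    dplyr::mutate(prop = dplyr::coalesce(.data$n, 0L) / !!n) |>
    dplyr::select("stage", "bin_lo", "bin_hi", "prop")
  new_size_stage_table(tab, n_cases = n)
}

#' Least-squares distance between size-stage tables
#'
#' The calibration objective: the sum over all stage-by-size cells of the
#' squared difference in proportions,
#' \eqn{L = \sum_i \sum_j (p^{sim}_{ij} - p^{obs}_{ij})^2}.
#'
#' @param sim,obs Two [new_size_stage_table()] objects on the same bins.
#' @return A nonnegative scalar, 0 iff the tables are identical.
#' @export
least_squares <- function(sim, obs) {
  if (nrow(sim) != nrow(obs) ||
      !all(sim$stage == obs$stage) ||
      !all(sim$bin_lo == obs$bin_lo))
    abort("size-stage tables have mismatched bin structure.")
  sum((sim$prop - obs$prop)^2)
}

# --- parameter transforms ----------------------------------------------------
# search runs in an unconstrained space: logs for positive parameters and a
# logit for r = mu_m / mu_n, which encodes the ordering mu_n >= mu_m
fit_par_names <- function() {
  c("xi", "mu_n", "r", "K", "theta", "eta", "w0", "w1", "w2")
}

pack_params <- function(pp, dp) {
  c(xi = log(pp$xi), mu_n = log(pp$mu_n),
    r = qlogis(min(pp$mu_m / pp$mu_n, 1 - 1e-8)),
    K = log(pp$K), theta = log(pp$theta),
    eta = log(dp$eta), w0 = log(dp$w0), w1 = log(dp$w1), w2 = log(dp$w2))
}

unpack_params <- function(th, template_pp, template_dp) {
  mu_n <- exp(th[["mu_n"]])
  pp <- progression_params(
    xi = min(exp(th[["xi"]]), 1), mu_n = mu_n,
    mu_m = mu_n * plogis(th[["r"]]),
    K = exp(th[["K"]]), theta = exp(th[["theta"]]),
    cell_volume = template_pp$cell_volume,
    met_growth = template_pp$met_growth,
    met_size_unit = template_pp$met_size_unit)
  dp <- detection_params(
    eta = exp(th[["eta"]]), w0 = exp(th[["w0"]]),
    w1 = exp(th[["w1"]]), w2 = exp(th[["w2"]]),
    cycle_years = template_dp$cycle_years,
    size_unit = template_dp$size_unit,
    met_lag_years = template_dp$met_lag_years)
  list(pp = pp, dp = dp)
}

#' Options for [fit_size_stage()]
#'
#' @param n_sim Detected cases simulated per objective evaluation.
#' @param maxit Maximum Nelder-Mead iterations.
#' @param reltol Relative convergence tolerance on the objective.
#' @param sim_seed Seed used for every objective evaluation (common random
#'   numbers: the objective is deterministic given the parameters, which
#'   Nelder-Mead requires to make progress against Monte-Carlo noise).
#' @param step_scale Width multiplier for the initial Nelder-Mead simplex
#'   (log-scale steps of `0.1 * step_scale`).
#' @param fixed Names of parameters held at their initial values. The
#'   default fixes `xi`: in this model the detachment rate enters only
#'   through the products `xi * mu_n` and `xi * mu_m`, so it is not
#'   separately identifiable from the deposition rates.
#' @param onset_range,mort_a,mort_b Passed to [simulate_cases()] inside the
#'   objective.
#' @return A list of options.
#' @export
fit_options <- function(n_sim = 2e4, maxit = 300, reltol = 1e-8,
                        sim_seed = 20240101, fixed = "xi",
                        step_scale = 5,
                        onset_range = c(40, 80),
                        mort_a = 8.5e-5, mort_b = 0.085) {
  list(n_sim = n_sim, maxit = maxit, reltol = reltol, sim_seed = sim_seed,
       fixed = fixed, step_scale = step_scale, onset_range = onset_range,
       mort_a = mort_a, mort_b = mort_b)
}

#' Calibrate progression and detection parameters to an observed table
#'
#' Simulation-based least-squares estimation of the nine progression and
#' detection parameters (detachment rate, two deposition rates, gamma shape
#' and scale of the growth rate, size-detection efficiency and three stage
#' offsets) against an observed joint tumor-size by stage distribution.
#' Each objective evaluation simulates a cohort of detected cases under the
#' candidate parameters with common random numbers, histograms it, and
#' computes [least_squares()] against the observed table; the objective is
#' minimized by Nelder-Mead in a log/logit-transformed space that enforces
#' positivity and `mu_n >= mu_m`.
#'
#' @param obs A [new_size_stage_table()] of observed proportions.
#' @param init_pp,init_dp Initial [progression_params()] and
#'   [detection_params()] (also the source of non-estimated structural
#'   settings such as units).
#' @param options A [fit_options()] list.
#' @return An object of class `lc_fit`: estimates (as `pp` and `dp`), the
#'   final loss, the optimizer trace, convergence flag and seed. Methods:
#'   [tidy.lc_fit()], [glance.lc_fit()], [autoplot.lc_fit()].
#' @export
fit_size_stage <- function(obs, init_pp = progression_params(),
                           init_dp = detection_params(),
                           options = fit_options()) {
  stopifnot(inherits(obs, "size_stage_table"))
  th0 <- pack_params(init_pp, init_dp)
  free <- setdiff(fit_par_names(), options$fixed)
  if (!length(free)) abort("no free parameters left to fit.")
  trace_env <- new.env()
  trace_env$rows <- list()

  # the search runs in scaled deviations from the initial point so the
  # Nelder-Mead simplex starts with comparable steps (step_scale * 0.1 on the
  # log scale) in every coordinate
  objective <- function(dth) {
    th <- th0
    th[free] <- th0[free] + options$step_scale * dth
    par <- unpack_params(th, init_pp, init_dp)
    cases <- withr::with_seed(
      options$sim_seed,
      simulate_cases(options$n_sim, par$pp, par$dp,
                     onset_range = options$onset_range,
                     mort_a = options$mort_a, mort_b = options$mort_b))
    loss <- least_squares(histogram_cases(cases), obs)
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      c(loss = loss, th)
    loss
  }

  opt <- optim(rep(0, length(free)), objective, method = "Nelder-Mead",
               control = list(maxit = options$maxit,
                              reltol = options$reltol))
  th <- th0
  th[free] <- th0[free] + options$step_scale * opt$par
  par <- unpack_params(th, init_pp, init_dp)
  trace <- tibble::as_tibble(do.call(rbind, trace_env$rows))
  structure(
    list(pp = par$pp, dp = par$dp, loss = opt$value,
         converged = opt$convergence == 0,
         iterations = length(trace_env$rows),
         trace = trace, obs = obs, options = options,
         init = list(pp = init_pp, dp = init_dp)),
    class = "lc_fit")
}

fit_estimates <- function(fit) {
  tibble::tibble(
    term = c("xi", "mu_n", "mu_m", "K", "theta", "eta", "w0", "w1", "w2"),
    estimate = c(fit$pp$xi, fit$pp$mu_n, fit$pp$mu_m, fit$pp$K,
                 fit$pp$theta, fit$dp$eta, fit$dp$w0, fit$dp$w1, fit$dp$w2))
}

#' @export
print.lc_fit <- function(x, ...) {
  cat("<lc_fit> simulation-based least-squares calibration\n")
  cat(sprintf("  loss %.3g after %d evaluations (%s)\n", x$loss,
              x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  print(fit_estimates(x), n = 9)
  invisible(x)
}

#' Tidy and summarize a calibration fit
#'
#' `tidy()` returns one row per model parameter (with bootstrap confidence
#' limits when [bootstrap_ci()] results are supplied); `glance()` returns a
#' one-row model summary.
#'
#' @param x An `lc_fit`.
#' @param ci Optional tibble from [bootstrap_ci()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lc_fit <- function(x, ci = NULL, ...) {
  est <- fit_estimates(x)
  if (!is.null(ci)) est <- dplyr::left_join(est, ci, by = "term")
  est
}

#' @rdname tidy.lc_fit
#' @export
glance.lc_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, iterations = x$iterations,
                 converged = x$converged, n_sim = x$options$n_sim,
                 n_obs_cases = attr(x$obs, "n_cases"))
}

#' Bootstrap confidence intervals for a calibration fit
#'
#' Percentile intervals from refits to multinomial resamples of the
#' observed table. The published analysis reported asymptotic intervals by
#' an unstated method; the bootstrap here is the package's replacement and
#' is labelled as such.
#'
#' @param obs The observed [new_size_stage_table()] (must carry `n_cases`).
#' @param fit The [fit_size_stage()] result to re-estimate around.
#' @param B Number of bootstrap replicates (`>= 2`; small `B` gives
#'   degenerate intervals and a warning).
#' @param level Interval level.
#' @param options Optional reduced-budget [fit_options()] for the refits
#'   (defaults to the original fit's options).
#' @param seed Optional integer seed.
#' @return A tibble with `term`, `lower`, `upper`, `B`.
#' @export
bootstrap_ci <- function(obs, fit, B = 50, level = 0.95, options = NULL,
                         seed = NULL) {
  stopifnot(inherits(fit, "lc_fit"))
  if (B < 2) abort("`B` must be at least 2.")
  if (B < 20) warn("small `B`: percentile intervals will be unstable.")
  n <- attr(obs, "n_cases")
  if (is.na(n)) abort("`obs` must carry an `n_cases` attribute to resample.")
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(options)) options <- fit$options
  reps <- purrr::map(seq_len(B), function(b) {
    counts <- rmultinom(1, n, obs$prop)[, 1]
    tab <- new_size_stage_table(
      dplyr::mutate(tibble::as_tibble(obs), prop = counts / n), n_cases = n)
    refit <- fit_size_stage(tab, init_pp = fit$pp, init_dp = fit$dp,
                            options = options)
    dplyr::mutate(fit_estimates(refit), rep = b)
  })
  a <- (1 - level) / 2
  dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarize(lower = unname(quantile(.data$estimate, a)),
                     upper = unname(quantile(.data$estimate, 1 - a)),
                     B = B, .groups = "drop")
}
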