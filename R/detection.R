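#' Mode-specific detection hazards
#'
#' Detection competes across three routes: through the primary tumor
#' (hazard linear in its size, `eta * s + w0`), through nodal metastases
#' (`w1` once present) and through distant metastases (`w2` once present).
#' The total stage-dependent hazard `z` is their sum, so for a primary of
#' size `s`: `z00 = eta*s + w0`, `z10 = z00 + w1`, `z01 = z00 + w2`,
#' `z11 = z00 + w1 + w2`.
#'
#' @param s Primary tumor size in the unit named by `dp$size_unit`, `> 0`.
#' @param N,M 0/1 indicators for nodal and distant metastases being
#'   present (vectorized).
#' @param dp A [detection_params()].
#' @return A tibble with columns `h_primary`, `h_nodal`, `h_distant`, `z`.
#' @export
mode_hazards <- function(s, N, M, dp = detection_params()) {
  if (any(s[is.finite(s)] <= 0)) abort("size `s` must be positive.")
  k <- max(length(s), length(N), length(M))
  s <- rep(s, length.out = k)
  N <- rep(as.integer(N), length.out = k)
  M <- rep(as.integer(M), length.out = k)
  h_primary <- dp$eta * s + dp$w0
  h_nodal <- dp$w1 * N
  h_distant <- dp$w2 * M
  tibble::tibble(h_primary = h_primary, h_nodal = h_nodal,
                 h_distant = h_distant, z = h_primary + h_nodal + h_distant)
}

# primary volume converted to the detection size unit
detection_size <- function(lambda, t, pp, dp) {
  scale <- switch(dp$size_unit,
                  cells = 1, cm3 = pp$cell_volume, mm3 = pp$cell_volume * 1e3)
  cells_at(lambda, t) * scale
}

#' Run the yearly detection cycle over tumor courses
#'
#' Advances each tumor in steps of `dp$cycle_years` from onset. At each
#' cycle's evaluation time the nodal/distant indicators are updated first
#' (a metastasis counts once `met_lag_years` past its formation), the total
#' hazard `z` is computed at the current primary size, and the tumor is
#' detected with probability `1 - exp(-z * cycle_years)`; on detection the
#' route is drawn with probabilities proportional to the three
#' mode-specific hazards, and size and stage are recorded at that
#' evaluation time. Tumors whose host dies first are censored.
#'
#' @param courses A tibble from [simulate_courses()] (columns `id`,
#'   `onset_age`, `lambda`, `t_nodal`, `t_distant`).
#' @param dp A [detection_params()].
#' @param pp A [progression_params()] (cell volume for size conversions).
#' @param censor_age Age at death from other causes (scalar or one per
#'   tumor); no detection can occur at or after it.
#' @param seed Optional integer seed.
#' @return The courses tibble with added columns `detected` (logical),
#'   `t_detect` (years from onset), `detection_age`, `mode`
#'   (`"primary"`/`"nodal"`/`"distant"`), `N`, `M`, `stage`,
#'   `volume_cm3`, `diameter_cm` (`NA` for undetected tumors).
#' @export
simulate_detection <- function(courses, dp = detection_params(),
                               pp = progression_params(),
                               censor_age = Inf, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(courses)
  censor_age <- rep(censor_age, length.out = n)
  if (any(censor_age < courses$onset_age))
    abort("`censor_age` must not precede onset.")
  lam <- courses$lambda
  tn <- courses$t_nodal + dp$met_lag_years
  tm <- courses$t_distant + dp$met_lag_years
  onset <- courses$onset_age

  t_det <- rep(NA_real_, n)
  Nv <- Mv <- rep(NA_integer_, n)
  mode <- rep(NA_character_, n)
  open <- rep(TRUE, n)
  horizon <- censor_age - onset
  max_cycles <- ceiling(max(c(0, horizon[is.finite(horizon)]), na.rm = TRUE) /
                          dp$cycle_years)
  max_cycles <- min(max(max_cycles, 1), 1e6)

  for (k in seq_len(max_cycles)) {
    if (!any(open)) break
    tk <- k * dp$cycle_years
    # death before this evaluation censors the tumor
    dead <- open & (tk > horizon)
    open[dead] <- FALSE
    idx <- which(open)
    if (!length(idx)) break
    Nk <- as.integer(tn[idx] <= tk)
    Mk <- as.integer(tm[idx] <= tk)
    s <- detection_size(lam[idx], tk, pp, dp)
    hz <- mode_hazards(s, Nk, Mk, dp)
    p <- -expm1(-hz$z * dp$cycle_years)
    hit <- runif(length(idx)) < p
    if (any(hit)) {
      h <- idx[hit]
      t_det[h] <- tk
      Nv[h] <- Nk[hit]
      Mv[h] <- Mk[hit]
      # competing-mode draw proportional to the route hazards
      hp <- hz$h_primary[hit]; hn <- hz$h_nodal[hit]; hm <- hz$h_distant[hit]
      tot <- hp + hn + hm
      u <- runif(length(h)) * tot
      mode[h] <- dplyr::case_when(
        u < hp ~ "primary",
        u < hp + hn ~ "nodal",
        TRUE ~ "distant"
      )
      open[h] <- FALSE
    }
  }

  vol <- volume_at(lam, t_det, pp)
  out <- courses
  out$detected <- !is.na(t_det)
  out$t_detect <- t_det
  out$detection_age <- onset + t_det
  out$mode <- mode
  out$N <- Nv
  out$M <- Mv
  out$stage <- ifelse(out$detected, stage_label(Nv, Mv), NA_character_)
  out$volume_cm3 <- vol
  out$diameter_cm <- ifelse(is.na(vol), NA_real_, diameter_from_volume(vol))
  out
}

#' Single-tumor detection
#'
#' Convenience wrapper running [simulate_detection()] on one tumor course.
#'
#' @inheritParams simulate_detection
#' @param course A one-row courses tibble.
#' @return A one-row detected-case tibble, or `NULL` if the tumor is never
#'   detected before `censor_age`.
#' @export
cycle_detection <- function(course, dp = detection_params(),
                            pp = progression_params(), censor_age = Inf,
                            seed = NULL) {
  stopifnot(nrow(course) == 1)
  res <- simulate_detection(course, dp, pp, censor_age, seed = seed)
  if (!res$detected[1]) return(NULL)
  res
}

#' Simulate a cohort of detected cases
#'
#' The canonical progression-plus-detection pipeline: tumors receive onset
#' ages (uniform over `onset_range` by default), gamma growth rates and
#' metastasis times, are censored by Gompertz other-cause mortality
#' conditional on having survived to onset, and pass through the yearly
#' detection cycle. This is the simulator behind fixture generation,
#' size-conditional stage probabilities and the calibration objective.
#'
#' @param n Number of tumors (onsets) to simulate.
#' @param pp A [progression_params()].
#' @param dp A [detection_params()].
#' @param onset_range Range of onset ages, sampled uniformly.
#' @param mort_a,mort_b Gompertz other-cause mortality parameters (hazard
#'   `mort_a * exp(mort_b * age)`); mortality is applied conditional on
#'   survival to the onset age.
#' @param keep_undetected Keep censored (never-detected) tumors in the
#'   output (default drops them).
#' @param seed Optional integer seed.
#' @return A tibble of cases: course columns plus detection columns (see
#'   [simulate_detection()]) and `death_age`.
#' @examples
#' cases <- simulate_cases(500, seed = 1)
#' table(cases$stage)
#' @export
simulate_cases <- function(n, pp = progression_params(),
                           dp = detection_params(),
                           onset_range = c(40, 80),
                           mort_a = 8.5e-5, mort_b = 0.085,
                           keep_undetected = FALSE, seed = NULL) {
  if (n <= 0) abort("`n` must be positive.")
  if (!is.null(seed)) withr::local_seed(seed)
  onset <- runif(n, onset_range[1], onset_range[2])
  courses <- simulate_courses(n, pp, onset_age = onset)
  death <- rgompertz(n, mort_a, mort_b, from = onset)
  res <- simulate_detection(courses, dp, pp, censor_age = death)
  res$death_age <- death
  if (!keep_undetected) res <- dplyr::filter(res, .data$detected)
  res
}

#' Stage probabilities conditional on detected tumor size
#'
#' Estimates, by forward simulation of the progression and detection
#' pipeline, the probability that nodal (`P_N`) and distant (`P_M`)
#' metastases are present at diagnosis for cases whose detected primary
#' diameter falls in the 1-cm bin containing `s`.
#'
#' @param s Detected primary diameter in cm (selects the bin
#'   `[floor(s), floor(s) + 1)`).
#' @param pp,dp Progression and detection parameters.
#' @param n Number of simulated tumors.
#' @param min_cases Minimum conditional sample size; fewer detected cases
#'   in the bin triggers an error reporting the achieved count.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `bin_lo`, `bin_hi`, `P_N`, `P_M`, `n_cases`,
#'   and the Monte-Carlo standard errors `se_N`, `se_M`.
#' @export
stage_probs_given_size <- function(s, pp = progression_params(),
                                   dp = detection_params(), n = 1e5,
                                   min_cases = 25, seed = NULL) {
  if (s <= 0) abort("size `s` must be positive.")
  cases <- simulate_cases(n, pp, dp, seed = seed)
  lo <- floor(s); hi <- lo + 1
  inbin <- dplyr::filter(cases, .data$diameter_cm >= lo, .data$diameter_cm < hi)
  m <- nrow(inbin)
  if (m < min_cases)
    abort(sprintf(
      "only %d detected cases in the [%g, %g) cm bin (need >= %d); increase `n`.",
      m, lo, hi, min_cases))
  pN <- mean(inbin$N); pM <- mean(inbin$M)
  tibble::tibble(
    bin_lo = lo, bin_hi = hi, P_N = pN, P_M = pM, n_cases = m,
    se_N = sqrt(pN * (1 - pN) / m), se_M = sqrt(pM * (1 - pM) / m)
  )
}
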