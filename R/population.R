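#' Birth-cohort simulation configuration
#'
#' Calendar-time configuration for the population simulation: yearly live
#' births, the fraction of real births actually simulated, the calendar
#' window over which detected cases are observed, and the sex split.
#' Birth counts for years before 1909 default to a constant 2,877,000 per
#' year when built with [constant_births()]; later years are data the user
#' supplies.
#'
#' @param births A data frame with columns `year` and `count` (live births
#'   per calendar year).
#' @param scale Simulated persons per real birth, in (0, 1].
#' @param obs_window Two calendar years: detected cases are reported when
#'   the diagnosis year falls inside this closed interval.
#' @param sex_split Proportion of males at birth.
#' @param max_age Maximum attained age considered (years).
#' @param onset_grid_step Age-grid resolution (years) used when sampling
#'   onset ages.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(births,
                          scale = 0.1,
                          obs_window = c(1995, 1999),
                          sex_split = 0.5,
                          max_age = 110,
                          onset_grid_step = 0.1) {
  if (missing(births) || is.null(births) || nrow(births) == 0)
    abort("`births` must be a nonempty data frame with columns `year`, `count`.")
  if (!all(c("year", "count") %in% names(births)))
    abort("`births` needs columns `year` and `count`.")
  if (any(births$count < 0)) abort("birth counts must be nonnegative.")
  if (scale <= 0 || scale > 1) abort("`scale` must lie in (0, 1].")
  structure(
    list(births = tibble::as_tibble(births), scale = scale,
         obs_window = obs_window, sex_split = sex_split, max_age = max_age,
         onset_grid_step = onset_grid_step),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @param years Calendar years.
#' @param count Births per year (default the pre-1909 convention,
#'   2,877,000).
#' @export
constant_births <- function(years, count = 2877000) {
  tibble::tibble(year = years, count = count)
}

#' Simulate the lung-cancer population over calendar time
#'
#' For each birth-year cohort: samples smoking histories and other-cause
#' death ages, samples TSCE onset ages, gives persons with onset a tumor
#' course, and runs the yearly detection cycle censored by death. Case
#' records are emitted for detections whose diagnosis year falls inside the
#' observation window; yearly alive-population counts are accumulated for
#' the whole simulated span. Persons dying in a year are removed from the
#' population in the next.
#'
#' @param config A [cohort_config()].
#' @param rp A [response_params()] (onset model).
#' @param pp A [progression_params()].
#' @param dp A [detection_params()].
#' @param smoking A [smoking_config()].
#' @param seed Optional integer seed governing the whole run.
#' @return A list with `cases` (one row per detected case inside the
#'   window; see Details for columns) and `population` (tibble of `year`,
#'   `alive`).
#' @details Case columns: identifiers and demographics (`id`, `sex`,
#' `birth_year`), observables at diagnosis (`dx_year`, `age_dx`, `stage`,
#' `N`, `M`, `mode`, `diameter_cm`, `volume_cm3`, `smoking_status`) and
#' unobservables (`onset_age`, `lambda`, `doubling_days`, `t_nodal`,
#' `t_distant`, `t_detect`, `vol_at_nodal_cm3`, `vol_at_distant_cm3`,
#' `death_age`).
#' @export
simulate_population <- function(config, rp = response_params(),
                                pp = progression_params(),
                                dp = detection_params(),
                                smoking = smoking_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) withr::local_seed(seed)

  years <- config$births$year
  end_year <- max(config$obs_window[2], max(years))
  pop_years <- seq(min(years), end_year)
  alive <- setNames(numeric(length(pop_years)), pop_years)
  all_cases <- vector("list", length(years))

  for (i in seq_along(years)) {
    by <- years[i]
    n_sim <- round(config$births$count[i] * config$scale)
    if (n_sim == 0) next
    n_male <- rbinom(1, n_sim, config$sex_split)
    sexes <- sample(rep(c("male", "female"), c(n_male, n_sim - n_male)))
    hist <- sample_histories(n_sim, smoking, birth_year = by, sex = sexes)
    if (!is.na(smoking$vital_cutoff_year)) {
      # vital status beyond the cut-off is extrapolated from the mortality
      # model; the cut-off only truncates the observation of cases below
      cutoff_age <- smoking$vital_cutoff_year - by
      hist$oc_death_age <- pmin(hist$oc_death_age, pmax(cutoff_age, 0) + Inf)
    }
    death_age <- pmin(hist$oc_death_age, config$max_age)

    # population bookkeeping: alive during [birth year, death year)
    dy <- pmin(by + floor(death_age), end_year)
    span_from <- rep(by, n_sim)
    for (j in seq_len(n_sim)) {
      yrs <- seq(span_from[j], dy[j])
      alive[as.character(yrs)] <- alive[as.character(yrs)] + 1
    }

    onset <- sample_onset_ages(hist, rp, max_age = config$max_age,
                               grid_step = config$onset_grid_step)
    has_tumor <- which(!is.na(onset))
    if (!length(has_tumor)) next
    courses <- simulate_courses(length(has_tumor), pp,
                                onset_age = onset[has_tumor])
    det <- simulate_detection(courses, dp, pp,
                              censor_age = death_age[has_tumor])
    det <- dplyr::filter(det, .data$detected)
    if (!nrow(det)) next
    sel <- has_tumor[det$id]
    dx_year <- by + floor(det$detection_age)
    keep <- dx_year >= config$obs_window[1] & dx_year <= config$obs_window[2]
    if (!any(keep)) next
    det <- det[keep, ]
    sel <- sel[keep]
    all_cases[[i]] <- tibble::tibble(
      id = paste0(by, "-", hist$id[sel]),
      sex = hist$sex[sel],
      birth_year = by,
      dx_year = dx_year[keep],
      age_dx = det$detection_age,
      stage = det$stage, N = det$N, M = det$M, mode = det$mode,
      diameter_cm = det$diameter_cm, volume_cm3 = det$volume_cm3,
      smoking_status = smoking_status_at(hist[sel, ], det$detection_age),
      onset_age = det$onset_age,
      lambda = det$lambda,
      doubling_days = doubling_time_days(det$lambda),
      t_nodal = det$t_nodal, t_distant = det$t_distant,
      t_detect = det$t_detect,
      vol_at_nodal_cm3 = volume_at(det$lambda, det$t_nodal, pp),
      vol_at_distant_cm3 = volume_at(det$lambda, det$t_distant, pp),
      death_age = death_age[sel]
    )
  }

  cases <- dplyr::bind_rows(all_cases)
  list(
    cases = cases,
    population = tibble::tibble(year = pop_years, alive = unname(alive))
  )
}

empty_summary <- function() {
  tibble::tibble(section = character(), statistic = character(),
                 group = character(), value = numeric())
}

#' Summarize clinically observable case characteristics
#'
#' Sex counts and percentages, age at diagnosis (mean/SD/median), stage
#' counts and percentages, tumor diameter (mean/median/SD/variance) and
#' smoking-status split, as a tidy long table.
#'
#' @param records A case tibble (from [simulate_population()]'s `cases` or
#'   a case listing).
#' @return A tibble with columns `section`, `statistic`, `group`, `value`.
#' @export
summarize_observables <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(empty_summary())
  n_tot <- nrow(records)
  sexes <- if ("sex" %in% names(records)) records$sex else rep(NA_character_, n_tot)
  smo <- if ("smoking_status" %in% names(records))
    records$smoking_status else rep(NA_character_, n_tot)
  age <- if ("age_dx" %in% names(records)) records$age_dx
    else records$detection_age
  d <- records$diameter_cm
  d <- d[is.finite(d)]
  rows <- list(
    tibble::tibble(section = "cases", statistic = "n", group = "all",
                   value = n_tot),
    dplyr::count(tibble::tibble(group = sexes), .data$group) |>
      dplyr::transmute(section = "sex", statistic = "n", .data$group,
                       value = as.numeric(.data$n)),
    dplyr::count(tibble::tibble(group = sexes), .data$group) |>
      dplyr::transmute(section = "sex", statistic = "pct", .data$group,
                       value = 100 * .data$n / n_tot),
    tibble::tibble(section = "age",
                   statistic = c("mean", "sd", "median"), group = "all",
                   value = c(mean(age), sd(age), median(age))),
    dplyr::count(tibble::tibble(group = factor(records$stage,
                                               stage_levels())),
                 .data$group, .drop = FALSE) |>
      dplyr::transmute(section = "stage", statistic = "n",
                       group = as.character(.data$group),
                       value = as.numeric(.data$n)),
    dplyr::count(tibble::tibble(group = factor(records$stage,
                                               stage_levels())),
                 .data$group, .drop = FALSE) |>
      dplyr::transmute(section = "stage", statistic = "pct",
                       group = as.character(.data$group),
                       value = 100 * .data$n / n_tot),
    tibble::tibble(section = "diameter_cm",
                   statistic = c("mean", "median", "sd", "variance"),
                   group = "all",
                   value = c(mean(d), median(d), sd(d), var(d))),
    dplyr::count(tibble::tibble(group = smo), .data$group) |>
      dplyr::transmute(section = "smoking", statistic = "n", .data$group,
                       value = as.numeric(.data$n)),
    dplyr::count(tibble::tibble(group = smo), .data$group) |>
      dplyr::transmute(section = "smoking", statistic = "pct", .data$group,
                       value = 100 * .data$n / n_tot)
  )
  dplyr::bind_rows(rows)
}

#' Summarize unobservable case characteristics
#'
#' Times from onset to nodal/distant metastasis and to diagnosis, primary
#' volume and diameter at metastasis formation, and growth rate and
#' doubling time by stage, plus a doubling-time cross-tab by stage and
#' 1-cm size bin.
#'
#' @param records A case tibble carrying the unobservable columns
#'   (`onset_age`, `lambda`, `t_nodal`, `t_distant`, `t_detect`, and
#'   optionally `vol_at_*_cm3`).
#' @return A list of tibbles: `durations`, `met_size`, `growth_by_stage`,
#'   `doubling_by_stage_size`.
#' @export
summarize_unobservables <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(list(durations = empty_summary(), met_size = empty_summary(),
                growth_by_stage = empty_summary(),
                doubling_by_stage_size = empty_summary()))
  stat4 <- function(x) {
    x <- x[is.finite(x)]
    tibble::tibble(mean = mean(x), sd = sd(x), median = median(x),
                   q1 = unname(quantile(x, 0.25)),
                   q3 = unname(quantile(x, 0.75)), n = length(x))
  }
  realized <- function(tmet) is.finite(tmet) & tmet <= records$t_detect
  durations <- dplyr::bind_rows(
    dplyr::mutate(stat4(records$t_nodal[realized(records$t_nodal)]),
                  variable = "onset_to_nodal_yr"),
    dplyr::mutate(stat4(records$t_distant[realized(records$t_distant)]),
                  variable = "onset_to_distant_yr"),
    dplyr::mutate(stat4(records$t_detect), variable = "onset_to_dx_yr")
  )
  met_size <- NULL
  if (all(c("vol_at_nodal_cm3", "vol_at_distant_cm3") %in% names(records))) {
    vn <- records$vol_at_nodal_cm3[realized(records$t_nodal)]
    vm <- records$vol_at_distant_cm3[realized(records$t_distant)]
    met_size <- dplyr::bind_rows(
      dplyr::mutate(stat4(vn), variable = "S_n_cm3"),
      dplyr::mutate(stat4(vm), variable = "S_m_cm3"),
      dplyr::mutate(stat4(diameter_from_volume(vn[vn > 0])),
                    variable = "D_n_cm"),
      dplyr::mutate(stat4(diameter_from_volume(vm[vm > 0])),
                    variable = "D_m_cm")
    )
  }
  growth <- records |>
    dplyr::mutate(stage = factor(.data$stage, stage_levels())) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarize(
      lambda_mean = mean(.data$lambda), lambda_sd = sd(.data$lambda),
      lambda_median = median(.data$lambda),
      doubling_mean = mean(doubling_time_days(.data$lambda)),
      doubling_median = median(doubling_time_days(.data$lambda)),
      n = dplyr::n(), .groups = "drop")
  cross <- records |>
    dplyr::mutate(
      stage = factor(.data$stage, stage_levels()),
      size_bin = pmin(floor(.data$diameter_cm), 19)) |>
    dplyr::group_by(.data$stage, .data$size_bin) |>
    dplyr::summarize(doubling_median = median(doubling_time_days(.data$lambda)),
                     n = dplyr::n(), .groups = "drop")
  list(durations = durations, met_size = met_size,
       growth_by_stage = growth, doubling_by_stage_size = cross)
}
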