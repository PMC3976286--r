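#' Configuration for the smoking-history generator
#'
#' The package emulates the output contract of a cohort smoking-history
#' generator: per-person smoking initiation, cessation, lifetime intensity,
#' and an age at death from causes other than lung cancer. All distributions
#' are configurable; defaults are a sex-specific initiation probability,
#' a normal initiation age truncated to `init_age_range`, an exponential
#' time-to-quit, a lognormal intensity (packs per day), and Gompertz
#' other-cause mortality.
#'
#' @param p_init Named probability of ever initiating smoking, for `male`
#'   and `female`.
#' @param init_age_mean,init_age_sd Mean and SD of the initiation age
#'   (years), truncated to `init_age_range`.
#' @param init_age_range Support of the initiation age.
#' @param quit_rate Hazard of quitting per smoking year; 0 means no one
#'   quits.
#' @param intensity_meanlog,intensity_sdlog Lognormal parameters of smoking
#'   intensity in packs per day.
#' @param mort_a,mort_b Gompertz other-cause mortality: hazard at age x is
#'   `mort_a * exp(mort_b * x)` per year.
#' @param vital_cutoff_year Optional calendar year after which vital status
#'   is not observed (the historical generator stopped at 2000); `NA`
#'   (default) applies no cut-off and extrapolates the mortality model.
#' @return An object of class `smoking_config`.
#' @export
smoking_config <- function(p_init = c(male = 0.55, female = 0.40),
                           init_age_mean = 18,
                           init_age_sd = 4,
                           init_age_range = c(10, 40),
                           quit_rate = 0.025,
                           intensity_meanlog = 0,
                           intensity_sdlog = 0.5,
                           mort_a = 8.5e-5,
                           mort_b = 0.085,
                           vital_cutoff_year = NA) {
  if (any(p_init < 0) || any(p_init > 1))
    abort("initiation probabilities must lie in [0, 1].")
  if (!all(c("male", "female") %in% names(p_init)))
    abort("`p_init` needs `male` and `female` entries.")
  if (init_age_sd < 0) abort("`init_age_sd` must be nonnegative.")
  if (diff(init_age_range) <= 0)
    abort("`init_age_range` must be an increasing interval.")
  if (quit_rate < 0) abort("`quit_rate` must be nonnegative.")
  if (mort_a <= 0 || mort_b <= 0)
    abort("Gompertz mortality parameters must be positive.")
  structure(
    list(p_init = p_init, init_age_mean = init_age_mean,
         init_age_sd = init_age_sd, init_age_range = init_age_range,
         quit_rate = quit_rate, intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog, mort_a = mort_a, mort_b = mort_b,
         vital_cutoff_year = vital_cutoff_year),
    class = "smoking_config"
  )
}

# Gompertz draw, optionally conditional on survival to age `from`
rgompertz <- function(n, a, b, from = 0) {
  E <- rexp(n)
  log(exp(b * from) + b * E / a) / b
}

#' Sample individual smoking histories
#'
#' Draws `n` persons with sex, birth year, smoking trajectory (initiation
#' age, possible cessation age, lifetime intensity in packs per day) and an
#' other-cause death age from a [smoking_config()].
#'
#' @param n Number of persons.
#' @param config A [smoking_config()].
#' @param birth_year Calendar birth year(s), recycled to length `n`.
#' @param sex Optional character vector (`"male"`/`"female"`), recycled;
#'   by default sexes are assigned half and half.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `id`, `sex`, `birth_year`, `init_age`,
#'   `quit_age`, `intensity_ppd`, `oc_death_age`. Never smokers have `NA`
#'   initiation/cessation ages and intensity 0; current smokers have `NA`
#'   `quit_age`.
#' @examples
#' h <- sample_histories(5, smoking_config(), birth_year = 1950, seed = 1)
#' smoking_status_at(h, 50)
#' @export
sample_histories <- function(n, config = smoking_config(), birth_year = 1950,
                             sex = NULL, seed = NULL) {
  stopifnot(inherits(config, "smoking_config"), n >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(sex)) {
    sex <- rep(c("male", "female"), length.out = n)
    sex <- sample(sex)
  } else {
    sex <- rep(sex, length.out = n)
  }
  if (!all(sex %in% c("male", "female")))
    abort("`sex` must be \"male\" or \"female\".")
  birth_year <- rep(birth_year, length.out = n)

  p <- unname(config$p_init[sex])
  smoker <- runif(n) < p
  init_age <- rep(NA_real_, n)
  k <- sum(smoker)
  if (k > 0) {
    # truncated-normal initiation age by rejection; the truncation window is
    # wide relative to the default SD so this terminates quickly
    draw <- rnorm(k, config$init_age_mean, config$init_age_sd)
    lo <- config$init_age_range[1]; hi <- config$init_age_range[2]
    bad <- draw < lo | draw > hi
    while (any(bad)) {
      draw[bad] <- rnorm(sum(bad), config$init_age_mean, config$init_age_sd)
      bad <- draw < lo | draw > hi
    }
    init_age[smoker] <- draw
  }
  quit_age <- rep(NA_real_, n)
  if (k > 0 && config$quit_rate > 0)
    quit_age[smoker] <- init_age[smoker] + rexp(k, config$quit_rate)
  intensity <- ifelse(smoker,
                      rlnorm(n, config$intensity_meanlog, config$intensity_sdlog),
                      0)
  death <- rgompertz(n, config$mort_a, config$mort_b)
  # quitting after death is never observed
  quit_age[!is.na(quit_age) & quit_age >= death] <- NA_real_

  tibble::tibble(
    id = seq_len(n), sex = sex, birth_year = birth_year,
    init_age = init_age, quit_age = quit_age,
    intensity_ppd = intensity, oc_death_age = death
  )
}

#' Smoking status and intensity at a given age
#'
#' `smoking_status_at()` classifies each person as `"never"`, `"current"`,
#' or `"former"` at `age`; `smoking_intensity_at()` returns the intensity in
#' packs per day (the lifetime intensity while current, otherwise 0).
#'
#' @param histories A tibble as returned by [sample_histories()].
#' @param age Age in years (scalar or one per row), `>= 0`.
#' @return A character (status) or numeric (ppd) vector, one per row.
#' @export
smoking_status_at <- function(histories, age) {
  if (any(age < 0)) abort("`age` must be nonnegative.")
  age <- rep(age, length.out = nrow(histories))
  init <- histories$init_age
  quit <- histories$quit_age
  dplyr::case_when(
    is.na(init) | age < init ~ "never",
    !is.na(quit) & age >= quit ~ "former",
    TRUE ~ "current"
  )
}

#' @rdname smoking_status_at
#' @export
smoking_intensity_at <- function(histories, age) {
  status <- smoking_status_at(histories, age)
  ifelse(status == "current", histories$intensity_ppd, 0)
}

#' Read or write smoking histories as delimited text
#'
#' Histories round-trip through a tab-separated table with columns `id`,
#' `sex`, `birth_year`, `init_age`, `quit_age`, `intensity_ppd`,
#' `oc_death_age`; empty fields encode absent ages.
#'
#' @param histories A histories tibble.
#' @param path File path.
#' @return `read_histories()` returns the tibble; `write_histories()`
#'   returns `path` invisibly.
#' @export
write_histories <- function(histories, path) {
  readr::write_tsv(histories, path, na = "")
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      id = readr::col_integer(), sex = readr::col_character(),
      birth_year = readr::col_double(), init_age = readr::col_double(),
      quit_age = readr::col_double(), intensity_ppd = readr::col_double(),
      oc_death_age = readr::col_double()
    )
  )
}
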