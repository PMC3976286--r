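#' Read and write case listings
#'
#' Detected-case records round-trip through a tab-separated listing, one
#' row per case, with units embedded in the column names (`_cm`, `_cm3`,
#' `_yr` suffixes; ages and durations in years). All columns present in
#' the record tibble are preserved.
#'
#' @param records A case tibble.
#' @param path File path.
#' @return `read_case_listing()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_case_listing <- function(records, path) {
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' @rdname write_case_listing
#' @export
read_case_listing <- function(path) {
  out <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0)
    abort(paste0("malformed case listing rows: ",
                 paste(unique(probs$row), collapse = ", ")))
  out
}

#' Read and write size-stage tables
#'
#' Tables are stored as tab-separated text with one row per stage and one
#' column per 1-cm diameter bin (header `d0`..`d19`, each bin
#' left-closed); a leading comment line records the case count.
#'
#' @param tab A [new_size_stage_table()].
#' @param path File path.
#' @return `read_size_stage_table()` returns the table; the writer
#'   returns `path` invisibly.
#' @export
write_size_stage_table <- function(tab, path) {
  stopifnot(inherits(tab, "size_stage_table"))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(tab)[, c("stage", "bin_lo", "prop")],
    names_from = "bin_lo", values_from = "prop", names_prefix = "d")
  lines <- c(
    sprintf("# n_cases: %s", attr(tab, "n_cases")),
    paste(c("stage", paste0("d", 0:19)), collapse = "\t"),
    vapply(seq_len(nrow(wide)), function(i)
      paste(c(wide$stage[i],
              format(as.numeric(wide[i, -1]), digits = 15, trim = TRUE,
                     scientific = FALSE)),
            collapse = "\t"), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_size_stage_table
#' @export
read_size_stage_table <- function(path) {
  first <- readLines(path, n = 1)
  n_cases <- NA_integer_
  if (grepl("^# n_cases:", first))
    n_cases <- suppressWarnings(as.integer(sub("^# n_cases:\\s*", "", first)))
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"stage", names_to = "bin",
                              values_to = "prop") |>
    dplyr::mutate(bin_lo = as.integer(sub("^d", "", .data$bin)),
                  bin_hi = .data$bin_lo + 1L) |>
    dplyr::select("stage", "bin_lo", "bin_hi", "prop")
  new_size_stage_table(long, n_cases = n_cases)
}

#' Generate a synthetic observed size-stage table
#'
#' Simulates `n` detected cases under known progression and detection
#' parameters and histograms them: the standard way to build a synthetic
#' "observed" table with known truth for calibration tests and demos.
#'
#' @param pp,dp Progression and detection parameters.
#' @param n Number of simulated tumors (onsets).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cases()].
#' @return A [new_size_stage_table()].
#' @export
make_fixture_table <- function(pp = progression_params(),
                               dp = detection_params(), n = 1e4,
                               seed = 1, ...) {
  if (n <= 0) abort("`n` must be positive.")
  histogram_cases(simulate_cases(n, pp, dp, seed = seed, ...))
}

#' Read a structured run configuration
#'
#' Loads a YAML configuration with optional sections `smoking`, `tsce`
#' (keyed by sex or flat), `progression`, `detection`, `cohort`,
#' `estimation`, `seed`; absent sections fall back to package defaults.
#' Unknown keys inside a section raise an error.
#'
#' @param path Path to a YAML file.
#' @return A list with constructed parameter objects (`smoking`, `tsce`,
#'   `progression`, `detection`), the raw `cohort` and `estimation`
#'   sections, and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(section, ctor) {
    if (is.null(raw[[section]])) return(ctor())
    args <- raw[[section]]
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      abort(sprintf("unknown keys in `%s` config: %s", section,
                    paste(bad, collapse = ", ")))
    do.call(ctor, args)
  }
  tsce <- if (!is.null(raw$tsce) &&
              all(names(raw$tsce) %in% c("male", "female"))) {
    purrr::map(raw$tsce, function(args) do.call(response_params, args))
  } else {
    build("tsce", response_params)
  }
  smoking <- if (!is.null(raw$smoking)) {
    args <- raw$smoking
    if (!is.null(args$p_init)) args$p_init <- unlist(args$p_init)
    do.call(smoking_config, args)
  } else smoking_config()
  list(
    smoking = smoking,
    tsce = tsce,
    progression = build("progression", progression_params),
    detection = build("detection", detection_params),
    cohort = raw$cohort,
    estimation = raw$estimation,
    seed = raw$seed
  )
}
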