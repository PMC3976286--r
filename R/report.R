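#' Text report over detected cases
#'
#' Bundles the observable and unobservable summaries with the joint
#' size-stage histogram, the standard reporting surface after a simulation
#' run.
#'
#' @param records A case tibble.
#' @return A list of class `lc_report`: `observables`, `unobservables`,
#'   `size_stage` (a [new_size_stage_table()]), `n_cases`.
#' @export
report_cases <- function(records) {
  n <- if (is.null(records)) 0L else nrow(records)
  structure(
    list(
      observables = summarize_observables(records),
      unobservables = summarize_unobservables(records),
      size_stage = if (n > 0) histogram_cases(records) else NULL,
      n_cases = n
    ),
    class = "lc_report")
}

#' @export
print.lc_report <- function(x, ...) {
  cat(sprintf("<lc_report> %d detected cases\n", x$n_cases))
  if (x$n_cases == 0) return(invisible(x))
  obs <- x$observables
  st <- dplyr::filter(obs, .data$section == "stage", .data$statistic == "pct")
  cat("  stage %:", paste(sprintf("%s %.1f", st$group, st$value),
                          collapse = ", "), "\n")
  dm <- dplyr::filter(obs, .data$section == "diameter_cm")
  cat("  diameter (cm):",
      paste(sprintf("%s %.2f", dm$statistic, dm$value), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot a size-stage table
#'
#' Stage-conditional tumor-size histograms: for each stage, the
#' distribution of detected 1-cm diameter bins (bars are proportions of
#' all cases by default, or renormalized within stage).
#'
#' @param object A [new_size_stage_table()].
#' @param within_stage Renormalize each stage's bars to sum to 1.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_stage_table <- function(object, within_stage = FALSE, ...) {
  df <- tibble::as_tibble(object)
  if (within_stage) {
    df <- df |>
      dplyr::group_by(.data$stage) |>
      dplyr::mutate(prop = .data$prop / pmax(sum(.data$prop), 1e-300)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo + 0.5, y = .data$prop)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_wrap(~ factor(stage, stage_levels()), ncol = 1) +
    ggplot2::labs(x = "tumor diameter at detection (cm)",
                  y = if (within_stage) "proportion within stage"
                      else "proportion of all cases") +
    ggplot2::theme_minimal()
}

#' Plot stage composition conditional on tumor size
#'
#' For each 1-cm diameter bin, the stage mix among detected cases of that
#' size (stacked proportions).
#'
#' @param tab A [new_size_stage_table()].
#' @return A ggplot object.
#' @export
plot_stage_by_size <- function(tab) {
  df <- tibble::as_tibble(tab) |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::mutate(cond = .data$prop / pmax(sum(.data$prop), 1e-300)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo + 0.5, y = .data$cond,
                                   fill = factor(stage, stage_levels()))) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "tumor diameter at detection (cm)",
                  y = "stage share within size bin", fill = "stage") +
    ggplot2::theme_minimal()
}

#' Plot the optimizer trace of a calibration fit
#'
#' @param object An `lc_fit`.
#' @param ... Unused.
#' @return A ggplot object of loss against evaluation number.
#' @export
autoplot.lc_fit <- function(object, ...) {
  df <- tibble::tibble(eval = seq_len(nrow(object$trace)),
                       loss = object$trace$loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$eval, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "objective evaluation", y = "least-squares loss") +
    ggplot2::theme_minimal()
}
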