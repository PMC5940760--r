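#' Binned relative error between an estimate and the truth
#'
#' Both masses are mapped to their bins and the signed relative error is
#' computed between the bin centres:
#' `(center(bin(estimate)) - center(bin(truth))) / center(bin(truth))`.
#' Working on bin values reflects that sub-bin mass differences are below the
#' resolution the discretized method claims; estimates landing in the truth's
#' bin score exactly zero.
#'
#' @param estimate,truth Numeric vectors of masses, kDa (recycled).
#' @param bins An `mm_binning`.
#' @return Signed relative errors (`NA` where the estimate is absent).
#' @export
binned_relative_error <- function(estimate, truth, bins) {
  ce <- ifelse(is.finite(estimate) & estimate > 0,
               bins$centers[mm_bin(pmax(estimate, 1e-12), bins)], NA_real_)
  ct <- bins$centers[mm_bin(truth, bins)]
  (ce - ct) / ct
}

#' Per-method error summary
#'
#' Summarizes signed binned relative errors per method: the median, the
#' median absolute deviation about that median, and the count of absent
#' (`NA`) estimates.
#'
#' @param results A tibble with columns `method` and `error` (signed
#'   fractions; `NA` = absent estimate).
#' @return A tibble with one row per method: `median_error`, `mad_error`,
#'   `n`, `n_nan`.
#' @export
mm_error_summary <- function(results) {
  stopifnot(all(c("method", "error") %in% names(results)))
  results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      median_error = median(.data$error, na.rm = TRUE),
      mad_error = median(abs(.data$error - median(.data$error, na.rm = TRUE)),
                         na.rm = TRUE),
      n = dplyr::n(),
      n_nan = sum(!is.finite(.data$error)),
      .groups = "drop"
    )
}

#' ROC-like accuracy curve
#'
#' Sorts the error magnitudes and plots them against the cumulative
#' normalized frequency: an accurate method's curve hugs the upper-left
#' corner. Absent estimates (`NA`s in `errors`, plus `nan_count` extra cases)
#' optionally enter the denominator only, so a method that frequently fails
#' saturates below 1.
#'
#' @param errors Numeric vector of signed relative errors (`NA` = absent).
#' @param include_nan Count absent estimates in the denominator,
#'   default `TRUE`.
#' @param nan_count Additional absent cases not present in `errors`.
#' @return A tibble of class `mm_roc` with columns `abs_error` (sorted) and
#'   `frequency` (cumulative, in `[0, 1]`), both monotone non-decreasing.
#' @export
roc_curve <- function(errors, include_nan = TRUE, nan_count = 0L) {
  nan_total <- sum(!is.finite(errors)) + nan_count
  vals <- sort(abs(errors[is.finite(errors)]))
  if (length(vals) == 0 && nan_total == 0) abort("no errors to summarize")
  denom <- if (include_nan) length(vals) + nan_total else length(vals)
  out <- tibble(abs_error = vals, frequency = seq_along(vals) / denom)
  class(out) <- c("mm_roc", class(out))
  out
}

#' Best-method fractions per shape class
#'
#' For each shape class, the fraction of cases in which each method produced
#' the most accurate mass (smallest error magnitude); exact ties split their
#' case equally among the tied methods, and absent estimates never win.
#'
#' @param results A tibble with columns `case`, `shape_class`, `method` and
#'   `abs_error`.
#' @return A tibble of class `mm_heatmap` with `shape_class`, `method` and
#'   `fraction`; fractions sum to 1 within each class (over cases where at
#'   least one method produced an estimate).
#' @export
best_method_heatmap <- function(results) {
  stopifnot(all(c("case", "shape_class", "method", "abs_error") %in% names(results)))
  wins <- results |>
    dplyr::group_by(.data$shape_class, .data$case) |>
    dplyr::filter(any(is.finite(.data$abs_error))) |>
    dplyr::mutate(
      best = min(.data$abs_error, na.rm = TRUE),
      win = ifelse(is.finite(.data$abs_error) &
                     .data$abs_error <= .data$best + 1e-15, 1, 0),
      win = .data$win / sum(.data$win)
    ) |>
    dplyr::ungroup()
  out <- wins |>
    dplyr::group_by(.data$shape_class, .data$method) |>
    dplyr::summarise(fraction = sum(.data$win), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    dplyr::ungroup()
  class(out) <- c("mm_heatmap", class(out))
  out
}

#' Credibility-interval coverage
#'
#' @param results A tibble with columns `truth`, `ci_low`, `ci_high`; rows
#'   with an absent interval count as misses.
#' @return The fraction of cases whose true mass lies inside its interval.
#' @export
coverage <- function(results) {
  stopifnot(all(c("truth", "ci_low", "ci_high") %in% names(results)))
  if (nrow(results) == 0) abort("no cases")
  hit <- is.finite(results$ci_low) & is.finite(results$ci_high) &
    results$ci_low <= results$truth & results$truth <= results$ci_high
  mean(hit)
}
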