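#' Colony-diameter summary statistics
#'
#' Per-strain descriptive statistics of colony diameters together with the
#' fractions lying strictly below and strictly above a size threshold.
#' Colonies exactly at the threshold count in neither fraction (the
#' "smaller than" / "larger than" convention), so the two fractions sum to
#' at most 1.
#'
#' @param data A data frame with column `diameter_mm` (positive) and
#'   optionally `strain_id`; one row per colony.
#' @param threshold_mm Positive size threshold in mm (default 1.5, the
#'   conventional small/large colony cut for *P. putida* KT2440 plates).
#' @return A tibble, one row per strain: `n`, `mean_mm`, `sd_mm`
#'   (sample sd, `NA` for n = 1), `fraction_below`, `fraction_above`.
#' @examples
#' diameter_summary(simulate_colonies(200, 1.01, 0.17, seed = 1))
#' @export
diameter_summary <- function(data, threshold_mm = 1.5) {
  check_columns(data, "diameter_mm")
  if (nrow(data) == 0) abort_input("`data` has no rows.")
  check_number(data$diameter_mm, "diameter_mm", positive = TRUE)
  check_number(threshold_mm, "threshold_mm", positive = TRUE, allow_vec = FALSE)
  if (!"strain_id" %in% names(data)) data$strain_id <- "sample"
  as_tibble(data) |>
    group_by(.data$strain_id) |>
    summarise(
      n = n(),
      mean_mm = mean(.data$diameter_mm),
      sd_mm = if (n() > 1) stats::sd(.data$diameter_mm) else NA_real_,
      fraction_below = mean(.data$diameter_mm < threshold_mm),
      fraction_above = mean(.data$diameter_mm > threshold_mm),
      .groups = "drop"
    )
}

#' Colony-diameter histogram counts
#'
#' Left-closed, right-open bins of fixed width starting at 0; counts always
#' sum to the number of colonies. Empty input gives an empty histogram.
#'
#' @inheritParams diameter_summary
#' @param bin_width_mm Positive bin width in mm.
#' @return A tibble: `bin_start`, `bin_end`, `count` (only non-empty bins
#'   up to the bin containing the largest diameter).
#' @examples
#' diameter_histogram(simulate_colonies(200, 1.01, 0.17, seed = 1), 0.25)
#' @export
diameter_histogram <- function(data, bin_width_mm = 0.25) {
  check_number(bin_width_mm, "bin_width_mm", positive = TRUE, allow_vec = FALSE)
  check_columns(data, "diameter_mm")
  if (nrow(data) == 0) {
    return(tibble(bin_start = double(), bin_end = double(), count = integer()))
  }
  check_number(data$diameter_mm, "diameter_mm", positive = TRUE)
  idx <- floor(data$diameter_mm / bin_width_mm)
  tab <- table(idx)
  starts <- as.numeric(names(tab)) * bin_width_mm
  tibble(bin_start = starts, bin_end = starts + bin_width_mm,
         count = as.integer(tab)) |>
    arrange(.data$bin_start)
}
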