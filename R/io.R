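# Table I/O: plain TSV (single header row) is the canonical dialect; CSV is
# accepted by sniffing the header line. All readers validate the schema and
# report errors naming file, row and column.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_plasfit_table <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  out <- readr::read_delim(path, delim = sniff_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort_input("%s: missing column(s) %s.", path,
                paste0("`", missing, "`", collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(out))) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort_input("%s: column `%s`, row %d: cannot parse `%s` as a number.",
                    path, col, bad[1], v[bad[1]])
      }
      out[[col]] <- vn
    }
  }
  out
}

#' Read a competition-assay table
#'
#' Expects columns `replicate_id`, `time_h`, `n_screened`, `n_positive`, and
#' either `cfu_total_per_ml` directly or the plate-count triple
#' `colonies_counted`, `dilution_factor`, `volume_plated_ml` from which it is
#' derived with [cfu_per_ml()]. An optional `cum_dilution` column is carried
#' through for cumulative-fitness bookkeeping.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble ready for [fitness_trajectory()].
#' @export
read_competition_table <- function(path) {
  out <- read_plasfit_table(
    path, c("replicate_id", "time_h", "n_screened", "n_positive"),
    c("time_h", "n_screened", "n_positive", "cfu_total_per_ml",
      "colonies_counted", "dilution_factor", "volume_plated_ml", "cum_dilution"))
  if (!"cfu_total_per_ml" %in% names(out)) {
    need <- c("colonies_counted", "dilution_factor", "volume_plated_ml")
    missing <- setdiff(need, names(out))
    if (length(missing)) {
      abort_input("%s: need `cfu_total_per_ml` or columns %s.", path,
                  paste0("`", missing, "`", collapse = ", "))
    }
    out$cfu_total_per_ml <- cfu_per_ml(out$colonies_counted,
                                       out$dilution_factor,
                                       out$volume_plated_ml)
  }
  bad <- which(out$n_positive > out$n_screened)
  if (length(bad)) {
    abort_input("%s: row %d: `n_positive` exceeds `n_screened`.", path, bad[1])
  }
  out
}

#' Read a per-strain coverage table
#'
#' Columns: `strain_id` plus either `coverage_chromosome`/`coverage_plasmid`
#' or `reads_chromosome`/`reads_plasmid` (see [copy_number_table()]).
#'
#' @inheritParams read_competition_table
#' @return A tibble.
#' @export
read_coverage_table <- function(path) {
  out <- read_plasfit_table(
    path, "strain_id",
    c("total_reads", "reads_chromosome", "reads_plasmid",
      "coverage_chromosome", "coverage_plasmid"))
  if (!all(c("coverage_chromosome", "coverage_plasmid") %in% names(out)) &&
      !all(c("reads_chromosome", "reads_plasmid") %in% names(out))) {
    abort_input("%s: need coverage_* or reads_* column pairs.", path)
  }
  out
}

#' Read a colony-diameter table (`strain_id`, `diameter_mm`; one row per
#' colony)
#' @inheritParams read_competition_table
#' @return A tibble.
#' @export
read_colony_table <- function(path) {
  out <- read_plasfit_table(path, "diameter_mm", "diameter_mm")
  bad <- which(!(out$diameter_mm > 0))
  if (length(bad)) {
    abort_input("%s: row %d: `diameter_mm` must be positive.", path, bad[1])
  }
  out
}

#' Read a band-intensity table (`time_h`, `insert_intensity`,
#' `reference_intensity`)
#' @inheritParams read_competition_table
#' @return A tibble.
#' @export
read_band_table <- function(path) {
  read_plasfit_table(path,
                     c("time_h", "insert_intensity", "reference_intensity"),
                     c("time_h", "insert_intensity", "reference_intensity"))
}

#' Read an expression table
#'
#' Wide on disk: `orf_id`, `length_bp`, then one column per sample named
#' `condition.replicate` (e.g. `vc.1`, `vc.2`, `ox.1`, `ox.2`). Returned
#' long (`orf_id`, `length_bp`, `condition`, `replicate`, `value`), the
#' format [call_de()] and [replicate_correlation()] consume.
#'
#' @inheritParams read_competition_table
#' @return A long tibble.
#' @export
read_expression_table <- function(path) {
  out <- read_plasfit_table(path, "orf_id")
  sample_cols <- setdiff(names(out), c("orf_id", "length_bp"))
  if (!length(sample_cols) || !all(grepl("\\.[0-9]+$", sample_cols))) {
    abort_input("%s: sample columns must be named `condition.replicate`.", path)
  }
  if (!"length_bp" %in% names(out)) out$length_bp <- NA_integer_
  tidyr::pivot_longer(out, all_of(sample_cols),
                      names_to = c("condition", "replicate"),
                      names_pattern = "^(.*)\\.([0-9]+)$",
                      values_to = "value") |>
    mutate(replicate = as.integer(.data$replicate))
}

#' Read a COG annotation table (`orf_id`, `cog_code`)
#' @inheritParams read_competition_table
#' @return A tibble with codes normalised to the 23-letter alphabet.
#' @export
read_cog_table <- function(path) {
  out <- read_plasfit_table(path, c("orf_id", "cog_code"))
  out$cog_code <- normalise_cog(out$cog_code)
  out
}

#' Write a tibble as a TSV (deterministic column order, UTF-8, `.` decimal)
#'
#' @param data A data frame; a long expression tibble is written back wide.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_plasfit_table <- function(data, path) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  if (all(c("orf_id", "condition", "replicate", "value") %in% names(data))) {
    data <- tidyr::pivot_wider(
      data, names_from = c("condition", "replicate"),
      names_sep = ".", values_from = "value")
  }
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}
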