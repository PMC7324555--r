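#' Mean sequencing depth of a replicon
#'
#' @param mapped_bases Non-negative numeric; total bases mapped to the replicon.
#' @param replicon_length_bp Positive integer; replicon length in bp.
#' @return Numeric mean depth (x coverage).
#' @examples
#' mean_coverage(236100000, 6181873)
#' @export
mean_coverage <- function(mapped_bases, replicon_length_bp) {
  check_number(mapped_bases, "mapped_bases", non_negative = TRUE)
  check_count(replicon_length_bp, "replicon_length_bp", positive = TRUE)
  mapped_bases / replicon_length_bp
}

#' Plasmid copy number from per-replicon sequencing depth
#'
#' Estimates the average number of plasmid copies per chromosome as the ratio
#' of mean plasmid depth to mean chromosome depth. Because both depths scale
#' identically with library size, the ratio is invariant to sequencing effort
#' and directly estimates copies per chromosome (chromosome copy number 1).
#' The conventional reported value is rounded to one decimal, half away from
#' zero.
#'
#' @param coverage_chromosome Positive numeric; mean chromosome depth.
#' @param coverage_plasmid Positive numeric; mean plasmid depth.
#' @return A tibble with `copy_number_raw` (the depth ratio) and
#'   `copy_number` (rounded to one decimal).
#' @examples
#' copy_number(38.2, 116.9) # 3.1 copies per chromosome
#' @export
copy_number <- function(coverage_chromosome, coverage_plasmid) {
  check_number(coverage_chromosome, "coverage_chromosome", positive = TRUE)
  check_number(coverage_plasmid, "coverage_plasmid", positive = TRUE)
  raw <- coverage_plasmid / coverage_chromosome
  tibble(copy_number_raw = raw, copy_number = round_half_up(raw, 1))
}

#' Copy-number table from per-strain coverage summaries
#'
#' Applies [copy_number()] to every row of a per-strain coverage table,
#' preserving row order. If depths are absent but per-replicon mapped read
#' counts and replicon lengths are supplied, depths are first derived with
#' [mean_coverage()] assuming `effective_read_bp` mapped bases per read.
#'
#' @param data A data frame with columns `strain_id`, `coverage_chromosome`,
#'   `coverage_plasmid` (additional columns such as read counts are carried
#'   through). Alternatively columns `reads_chromosome`, `reads_plasmid` plus
#'   `chromosome_bp`, `plasmid_bp` arguments.
#' @param chromosome_bp,plasmid_bp Replicon lengths in bp, used only when
#'   coverage columns are absent.
#' @param effective_read_bp Mapped bases contributed per read (e.g. 300 for
#'   2 x 150 bp read pairs counted as one), used only when deriving coverage
#'   from read counts.
#' @return The input tibble with `copy_number_raw` and `copy_number` added.
#' @examples
#' copy_number_table(rp4_coverage())
#' @export
copy_number_table <- function(data, chromosome_bp = 6181873L,
                              plasmid_bp = 60099L, effective_read_bp = 300) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort_input("`data` must be a non-empty data frame.")
  }
  have_cov <- all(c("coverage_chromosome", "coverage_plasmid") %in% names(data))
  if (!have_cov) {
    check_columns(data, c("reads_chromosome", "reads_plasmid"))
    data <- data |>
      mutate(
        coverage_chromosome = mean_coverage(.data$reads_chromosome * effective_read_bp,
                                            chromosome_bp),
        coverage_plasmid = mean_coverage(.data$reads_plasmid * effective_read_bp,
                                         plasmid_bp)
      )
  }
  bad <- which(!(data$coverage_chromosome > 0))
  if (length(bad)) {
    abort_input("row %d: chromosome coverage must be positive.", bad[1])
  }
  as_tibble(data) |>
    mutate(copy_number(.data$coverage_chromosome, .data$coverage_plasmid))
}
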