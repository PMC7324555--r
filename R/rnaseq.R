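#' Reads per kilobase per million mapped reads
#'
#' Length- and depth-normalised expression:
#' `RPKM = reads_on_orf * 1e9 / (total_mapped_reads * orf_length_bp)`.
#'
#' @param reads_on_orf Non-negative numeric; reads mapped to the ORF.
#' @param orf_length_bp Positive integer; ORF length, bp.
#' @param total_mapped_reads Positive integer; library size (mapped reads).
#' @return Numeric RPKM.
#' @examples
#' rpkm(10, 1000, 1e6) # 10
#' @export
rpkm <- function(reads_on_orf, orf_length_bp, total_mapped_reads) {
  check_number(reads_on_orf, "reads_on_orf", non_negative = TRUE)
  check_count(orf_length_bp, "orf_length_bp", positive = TRUE)
  check_count(total_mapped_reads, "total_mapped_reads", positive = TRUE)
  reads_on_orf * 1e9 / (total_mapped_reads * orf_length_bp)
}

# Pivot a long expression tibble (orf_id, condition, replicate, value) into a
# per-ORF wide matrix for one condition; errors unless exactly 2 replicates.
condition_reps <- function(data, condition) {
  d <- filter(data, .data$condition == !!condition)
  reps <- sort(unique(d$replicate))
  if (length(reps) != 2L) {
    abort_input("condition `%s` must have exactly 2 replicates (found %d).",
                condition, length(reps))
  }
  wide <- tidyr::pivot_wider(select(d, "orf_id", "replicate", "value"),
                             names_from = "replicate", values_from = "value")
  list(orf_id = wide$orf_id,
       r1 = wide[[as.character(reps[1])]],
       r2 = wide[[as.character(reps[2])]])
}

#' Pearson correlation between the two replicates of a condition
#'
#' The replicate-consistency QC for a duplicate RNA-Seq design: the Pearson
#' correlation of the two replicate expression vectors (a well-behaved pair
#' is expected to correlate above ~0.97).
#'
#' @param data Long-format expression tibble with columns `orf_id`,
#'   `condition`, `replicate`, `value` (see [simulate_expression()] and
#'   [read_expression_table()]).
#' @param condition Condition label to check.
#' @return Pearson correlation in \[-1, 1\].
#' @export
replicate_correlation <- function(data, condition) {
  check_columns(data, c("orf_id", "condition", "replicate", "value"))
  cr <- condition_reps(data, condition)
  if (stats::sd(cr$r1) == 0 || stats::sd(cr$r2) == 0) {
    rlang::abort("a replicate vector is constant: correlation undefined",
                 class = "plasfit_undefined_correlation")
  }
  stats::cor(cr$r1, cr$r2)
}

#' Replicate-consistent fold-change differential-expression calls
#'
#' The deliberately simple DE rule for a two-condition, two-replicate RPKM
#' design: for each ORF all four cross-condition replicate ratios
#' `treatment_rep_i / control_rep_j` are computed on floored values, and an
#' ORF is called up if **all four** exceed `threshold`, down if all four fall
#' below `1/threshold`, otherwise unchanged. Requiring every cross-replicate
#' comparison to agree substitutes replicate consistency for a distributional
#' test. Values below `floor` are raised to `floor` before ratios, so zeros
#' never produce infinite fold-changes.
#'
#' @inheritParams replicate_correlation
#' @param treatment,control Condition labels (each with exactly 2 replicates).
#' @param threshold Fold-change threshold, > 1; strictly-greater comparison
#'   (default 2).
#' @param floor Positive floor applied to values before ratios (default 0.1
#'   RPKM).
#' @return A tibble of class `plasfit_de`: `orf_id`, `direction`
#'   (`"up"`/`"down"`/`"none"`) and the four fold-change columns
#'   `fc_t1_c1`, `fc_t1_c2`, `fc_t2_c1`, `fc_t2_c2`.
#' @examples
#' sim <- simulate_expression(n_orfs = 100, n_planted_up = 5,
#'                            n_planted_down = 5, seed = 1)
#' calls <- call_de(sim$matrix, treatment = "treatment", control = "control")
#' table(calls$direction)
#' @export
call_de <- function(data, treatment, control, threshold = 2, floor = 0.1) {
  check_columns(data, c("orf_id", "condition", "replicate", "value"))
  check_number(threshold, "threshold", positive = TRUE, allow_vec = FALSE)
  if (threshold <= 1) abort_input("`threshold` must be > 1.")
  check_number(floor, "floor", positive = TRUE, allow_vec = FALSE)
  conds <- unique(data$condition)
  if (!all(c(treatment, control) %in% conds)) {
    abort_input("conditions `%s` and `%s` must both be present.", treatment, control)
  }
  tr <- condition_reps(data, treatment)
  ct <- condition_reps(data, control)
  if (!identical(tr$orf_id, ct$orf_id)) {
    ord <- match(tr$orf_id, ct$orf_id)
    if (anyNA(ord)) abort_input("conditions cover different ORF sets.")
    ct <- list(orf_id = ct$orf_id[ord], r1 = ct$r1[ord], r2 = ct$r2[ord])
  }
  f <- function(x) pmax(x, floor)
  fc <- tibble(
    fc_t1_c1 = f(tr$r1) / f(ct$r1),
    fc_t1_c2 = f(tr$r1) / f(ct$r2),
    fc_t2_c1 = f(tr$r2) / f(ct$r1),
    fc_t2_c2 = f(tr$r2) / f(ct$r2)
  )
  m <- as.matrix(fc)
  direction <- ifelse(apply(m > threshold, 1, all), "up",
                      ifelse(apply(m < 1 / threshold, 1, all), "down", "none"))
  out <- dplyr::bind_cols(tibble(orf_id = tr$orf_id, direction = direction), fc)
  structure(out, threshold = threshold, floor = floor,
            class = c("plasfit_de", class(out)))
}

#' Proportion of the genome called differentially expressed
#'
#' @param calls A `plasfit_de` tibble from [call_de()], or any data frame
#'   with a `direction` column.
#' @param genome_orf_count Positive integer; ORFs in the genome annotation.
#' @return Percentage (0-100), rounded to one decimal as conventionally
#'   reported.
#' @examples
#' de_proportion(data.frame(direction = rep(c("up", "none"), c(33, 0))), 5350)
#' @export
de_proportion <- function(calls, genome_orf_count) {
  check_columns(calls, "direction", arg = "calls")
  check_count(genome_orf_count, "genome_orf_count", positive = TRUE)
  n_de <- sum(calls$direction != "none")
  if (genome_orf_count < n_de) {
    abort_input("`genome_orf_count` is smaller than the number of DE calls.")
  }
  round_half_up(100 * n_de / genome_orf_count, 1)
}
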