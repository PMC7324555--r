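#' Colony-forming units per millilitre from a plate count
#'
#' Standard dilution-plating arithmetic: the number of colonies counted on a
#' plate is scaled back through the fold-dilution and the volume plated to a
#' viable-cell density in the original culture.
#'
#' @param colonies_counted Non-negative integer vector; colonies on the plate.
#' @param dilution_factor Positive numeric; fold-dilution applied before
#'   plating (>= 1, e.g. `1e5` for a 10^-5 dilution).
#' @param volume_plated_ml Positive numeric; volume spread on the plate, ml.
#'
#' @return Numeric vector of CFU/ml.
#' @examples
#' cfu_per_ml(150, 1e5, 0.1) # 1.5e8
#' @export
cfu_per_ml <- function(colonies_counted, dilution_factor, volume_plated_ml) {
  check_count(colonies_counted, "colonies_counted")
  check_number(dilution_factor, "dilution_factor", positive = TRUE)
  if (any(dilution_factor < 1)) {
    abort_input("`dilution_factor` must be >= 1 (a fold-dilution).")
  }
  check_number(volume_plated_ml, "volume_plated_ml", positive = TRUE)
  colonies_counted * dilution_factor / volume_plated_ml
}

#' Split a total CFU count into plasmid-bearing and plasmid-free densities
#'
#' A subsample of colonies from the plate is screened (e.g. by colony
#' hybridization against a plasmid-specific probe) and classified as
#' plasmid-bearing or not; the screened proportion partitions the total
#' viable count. The two outputs always sum to the input total.
#'
#' @param cfu_total_per_ml Positive numeric; total CFU/ml at the timepoint.
#' @param n_screened Positive integer; colonies screened.
#' @param n_positive Non-negative numeric; plasmid-bearing among screened.
#'   Integer in real screens; fractional expected counts from
#'   deterministic simulation are accepted.
#'
#' @return A tibble with columns `cfu_bearing` and `cfu_free` (CFU/ml).
#' @examples
#' strain_cfus(2e8, 200, 120)
#' @export
strain_cfus <- function(cfu_total_per_ml, n_screened, n_positive) {
  check_number(cfu_total_per_ml, "cfu_total_per_ml", positive = TRUE)
  check_count(n_screened, "n_screened", positive = TRUE)
  check_number(n_positive, "n_positive", non_negative = TRUE)
  if (any(n_positive > n_screened)) {
    abort_input("`n_positive` cannot exceed `n_screened`.")
  }
  bearing <- cfu_total_per_ml * n_positive / n_screened
  tibble(cfu_bearing = bearing, cfu_free = cfu_total_per_ml - bearing)
}

#' Relative fitness W of the plasmid-bearing strain
#'
#' The competition-assay fitness index: the ratio of natural-log fold-changes
#' of the two competitors over the assay interval,
#' \deqn{W = \frac{\ln(N_{t,\mathrm{bearing}}/N_{0,\mathrm{bearing}})}
#'            {\ln(N_{t,\mathrm{free}}/N_{0,\mathrm{free}})}.}
#' W = 1 means the two strains grew identically (neutral plasmid), W < 1 a
#' fitness cost of carriage, W > 1 an advantage. W is invariant to a common
#' rescaling of all four counts.
#'
#' When the free competitor *declined* over the interval the denominator log
#' is negative and the signed ratio is hard to interpret; the value is still
#' returned but a warning of class `plasfit_w_negative_denominator` is
#' signalled. A free competitor exactly unchanged makes W undefined and is an
#' error.
#'
#' @param n_bearing_t,n_bearing_0 Positive numeric; plasmid-bearing counts
#'   (CFU or CFU/ml) at time t and at baseline.
#' @param n_free_t,n_free_0 Positive numeric; plasmid-free counts at time t
#'   and at baseline.
#'
#' @return Numeric vector of W values (dimensionless).
#' @examples
#' relative_fitness_w(1e7, 1e6, 1e8, 1e6) # 0.5
#' @export
relative_fitness_w <- function(n_bearing_t, n_bearing_0, n_free_t, n_free_0) {
  check_number(n_bearing_t, "n_bearing_t", positive = TRUE)
  check_number(n_bearing_0, "n_bearing_0", positive = TRUE)
  check_number(n_free_t, "n_free_t", positive = TRUE)
  check_number(n_free_0, "n_free_0", positive = TRUE)
  denom <- log(n_free_t / n_free_0)
  if (any(denom == 0)) {
    rlang::abort("free-strain count unchanged: W is undefined (zero denominator log)",
                 class = "plasfit_undefined_fitness")
  }
  if (any(denom < 0)) {
    rlang::warn("free-strain count declined; W computed on a negative denominator log",
                class = "plasfit_w_negative_denominator")
  }
  log(n_bearing_t / n_bearing_0) / denom
}

#' Fitness trajectory from a serial-transfer competition assay
#'
#' Computes per-replicate relative fitness W at every observed timepoint and
#' summarises across replicates (mean and sample standard deviation). Input
#' is one row per replicate x timepoint with the total plate count and the
#' screened-colony classification; strain-specific counts are derived with
#' [strain_cfus()] and W with [relative_fitness_w()].
#'
#' @section Baseline modes:
#' `baseline = "initial"` (default) measures every timepoint against that
#' replicate's t = 0 counts (cumulative W); `baseline = "previous"` uses the
#' preceding observation, giving a per-interval W. With serial transfer the
#' dilution at each transfer divides both competitors equally; for cumulative
#' W the shared dilution is removed by multiplying counts by the optional
#' `cum_dilution` column (the product of dilution factors applied before that
#' observation, 1 at t = 0). If the column is absent counts are used as
#' printed, which is the plain formula on raw CFUs.
#'
#' @param data A data frame with columns `replicate_id`, `time_h`,
#'   `cfu_total_per_ml`, `n_screened`, `n_positive`, and optionally
#'   `cum_dilution`.
#' @param baseline `"initial"` or `"previous"`; see Details.
#'
#' @return A tibble of class `plasfit_fitness`, one row per timepoint
#'   (t > 0): `time_h`, `mean_w`, `sd_w`, `n_replicates`, `n_extinct`,
#'   `single_replicate` (logical flag: sd reported as 0 from one value).
#'   Per-replicate values are attached as attribute `"per_replicate"` and
#'   retrievable with [tidy()].
#'
#' A replicate whose screened subsample contains zero plasmid-bearing
#' colonies at t > 0 is flagged `"extinct"` (W is `NA`): a zero among a few
#' hundred screened colonies reflects plating resolution, not necessarily
#' true extinction, so no -Inf is propagated. Such replicates are excluded
#' from the mean/sd at that timepoint.
#' @examples
#' obs <- tibble::tibble(
#'   replicate_id = rep(c("r1", "r2"), each = 2),
#'   time_h = rep(c(0, 24), 2),
#'   cfu_total_per_ml = c(1e7, 1e9, 1e7, 1e9),
#'   n_screened = 200, n_positive = c(100, 80, 100, 90)
#' )
#' fitness_trajectory(obs)
#' @export
fitness_trajectory <- function(data, baseline = c("initial", "previous")) {
  baseline <- arg_match(baseline)
  check_columns(data, c("replicate_id", "time_h", "cfu_total_per_ml",
                        "n_screened", "n_positive"))
  if (nrow(data) == 0) abort_input("`data` has no rows.")
  if (!"cum_dilution" %in% names(data)) data$cum_dilution <- 1
  check_number(data$cum_dilution, "cum_dilution", positive = TRUE)

  counts <- data |>
    mutate(strain_cfus(.data$cfu_total_per_ml, .data$n_screened, .data$n_positive)) |>
    mutate(
      n_bearing = .data$cfu_bearing * .data$cum_dilution,
      n_free    = .data$cfu_free * .data$cum_dilution
    ) |>
    arrange(.data$replicate_id, .data$time_h)

  per_rep <- counts |>
    group_by(.data$replicate_id) |>
    dplyr::group_modify(function(d, key) {
      if (d$time_h[1] != 0) {
        abort_input("replicate `%s` has no time-0 baseline observation.", key$replicate_id)
      }
      later <- d[-1, , drop = FALSE]
      if (nrow(later) == 0) return(tibble())
      b0 <- if (baseline == "initial") rep(d$n_bearing[1], nrow(later)) else d$n_bearing[-nrow(d)]
      f0 <- if (baseline == "initial") rep(d$n_free[1], nrow(later)) else d$n_free[-nrow(d)]
      extinct <- later$n_bearing == 0
      w <- rep(NA_real_, nrow(later))
      ok <- !extinct
      if (any(ok)) {
        w[ok] <- relative_fitness_w(later$n_bearing[ok], b0[ok],
                                    later$n_free[ok], f0[ok])
      }
      tibble(time_h = later$time_h, w = w,
             status = ifelse(extinct, "extinct", "ok"))
    }) |>
    ungroup()

  summ <- per_rep |>
    filter(.data$status == "ok") |>
    group_by(.data$time_h) |>
    summarise(
      mean_w = mean(.data$w),
      sd_w = if (n() > 1) stats::sd(.data$w) else 0,
      n_replicates = n(),
      .groups = "drop"
    ) |>
    left_join(
      per_rep |> group_by(.data$time_h) |>
        summarise(n_extinct = sum(.data$status == "extinct"), .groups = "drop"),
      by = "time_h"
    ) |>
    mutate(single_replicate = .data$n_replicates == 1L)

  if (any(summ$single_replicate)) {
    rlang::warn("timepoint(s) with a single usable replicate: sd_w reported as 0",
                class = "plasfit_single_replicate")
  }
  structure(summ,
            per_replicate = per_rep,
            baseline = baseline,
            class = c("plasfit_fitness", class(summ)))
}

#' Plasmid persistence fraction
#'
#' Proportion of screened colonies carrying the plasmid, the pure-culture
#' stability readout (a stably maintained plasmid stays at 1 after a growth
#' cycle without selection).
#'
#' @inheritParams strain_cfus
#' @return Numeric in \[0, 1\].
#' @examples
#' persistence_fraction(200, 200) # fully persistent
#' @export
persistence_fraction <- function(n_screened, n_positive) {
  check_count(n_screened, "n_screened", positive = TRUE)
  check_number(n_positive, "n_positive", non_negative = TRUE)
  if (any(n_positive > n_screened)) {
    abort_input("`n_positive` cannot exceed `n_screened`.")
  }
  n_positive / n_screened
}

#' Conjugation frequency
#'
#' Transconjugants per donor after a mating period: the CFU/ml of
#' transconjugants divided by the CFU/ml of donors. Dimensionless.
#'
#' @param transconjugant_cfu_per_ml Non-negative numeric.
#' @param donor_cfu_per_ml Positive numeric.
#' @return Numeric, transconjugants per donor.
#' @examples
#' conjugation_frequency(1.2e3, 1e7) # 1.2e-4
#' @export
conjugation_frequency <- function(transconjugant_cfu_per_ml, donor_cfu_per_ml) {
  check_number(transconjugant_cfu_per_ml, "transconjugant_cfu_per_ml",
               non_negative = TRUE)
  check_number(donor_cfu_per_ml, "donor_cfu_per_ml", positive = TRUE)
  transconjugant_cfu_per_ml / donor_cfu_per_ml
}

#' Relative competition ratio from PCR band intensities
#'
#' The gel-based competition readout: at each timepoint the band intensity of
#' a strain-specific amplicon (e.g. a vector-insert region) is divided by
#' that of a single-copy chromosomal reference amplicon shared by both
#' competitors, and the resulting ratio is normalised to its value at the
#' initial timepoint, so the series starts at exactly 1 and tracks the
#' focal strain's share of the mixed culture.
#'
#' @param data A data frame with columns `time_h`, `insert_intensity`
#'   (non-negative; focal-strain band) and `reference_intensity` (strictly
#'   positive; shared reference band), ordered or orderable by time.
#'
#' @return A tibble: `time_h`, `intensity_ratio` (insert/reference) and
#'   `relative_ratio` (normalised to the first timepoint; 1 at t0).
#' @examples
#' band_relative_ratio(tibble::tibble(
#'   time_h = c(0, 48, 96),
#'   insert_intensity = c(80, 60, 20),
#'   reference_intensity = c(160, 150, 100)
#' ))
#' @export
band_relative_ratio <- function(data) {
  check_columns(data, c("time_h", "insert_intensity", "reference_intensity"))
  if (nrow(data) == 0) abort_input("`data` has no rows.")
  check_number(data$insert_intensity, "insert_intensity", non_negative = TRUE)
  check_number(data$reference_intensity, "reference_intensity", positive = TRUE)
  data <- arrange(as_tibble(data), .data$time_h)
  if (data$insert_intensity[1] <= 0) {
    rlang::abort("initial insert band intensity is zero: relative ratio undefined",
                 class = "plasfit_undefined_ratio")
  }
  ratio <- data$insert_intensity / data$reference_intensity
  tibble(time_h = data$time_h,
         intensity_ratio = ratio,
         relative_ratio = ratio / ratio[1])
}
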