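#' Generative parameters for the serial-transfer competition model
#'
#' Bundles the batch-culture model parameters with validation. Three
#' genotypes are tracked: the plasmid-bearing ancestor, a plasmid-bearing
#' compensated mutant, and the plasmid-free competitor. Defaults describe a
#' succinate minimal-medium serial-transfer assay: 24-h cycles, 1:100
#' transfer dilution, a 50:50 initial mix at the density produced by
#' 100-fold dilution of a saturated (1e9 cells/ml) culture, 200 colonies
#' screened per timepoint, a 10% plasmid cost on the ancestor
#' (0.63 vs 0.70 h^-1) and a compensated mutant 5% faster than the free
#' strain (0.735 h^-1). Conjugation defaults to a mass-action rate low
#' enough that transconjugants stay far below 0.012% per cycle and can be
#' ignored, as observed for RP4 in KT2440.
#'
#' @param m_bearing,m_compensated,m_free Malthusian growth rates, h^-1.
#' @param carrying_capacity_per_ml Shared carrying capacity K (cells/ml);
#'   `Inf` gives pure exponential growth.
#' @param transfer_period_h Hours per growth cycle.
#' @param dilution_factor Fold-dilution at each transfer (> 1).
#' @param initial_density_per_ml Total density at t = 0.
#' @param initial_fraction_bearing Initial plasmid-bearing fraction in
#'   \[0, 1\].
#' @param conjugation_rate_ml_per_cell_h Mass-action transfer rate gamma;
#'   free cells become plasmid-bearing at rate gamma * N_bearing * N_free.
#' @param segregational_loss_per_division Probability a division of a
#'   plasmid-bearing cell yields a plasmid-free daughter.
#' @param compensation_rate_per_cell_h Rate at which bearing-ancestral cells
#'   convert to the compensated genotype.
#' @param n_cycles Number of 24-h cycles to simulate.
#' @param n_screened Colonies screened per observation.
#' @return A validated list of class `growth_params`.
#' @export
growth_params <- function(m_bearing = 0.63,
                          m_compensated = 0.735,
                          m_free = 0.7,
                          carrying_capacity_per_ml = 1e9,
                          transfer_period_h = 24,
                          dilution_factor = 100,
                          initial_density_per_ml = 1e7,
                          initial_fraction_bearing = 0.5,
                          conjugation_rate_ml_per_cell_h = 1e-15,
                          segregational_loss_per_division = 0,
                          compensation_rate_per_cell_h = 1e-6,
                          n_cycles = 6L,
                          n_screened = 200L) {
  check_number(m_bearing, "m_bearing", positive = TRUE, allow_vec = FALSE)
  check_number(m_compensated, "m_compensated", positive = TRUE, allow_vec = FALSE)
  check_number(m_free, "m_free", positive = TRUE, allow_vec = FALSE)
  check_number(carrying_capacity_per_ml, "carrying_capacity_per_ml",
               positive = TRUE, allow_vec = FALSE, finite = FALSE)
  check_number(transfer_period_h, "transfer_period_h", positive = TRUE, allow_vec = FALSE)
  check_number(dilution_factor, "dilution_factor", positive = TRUE, allow_vec = FALSE)
  if (dilution_factor <= 1) abort_input("`dilution_factor` must be > 1.")
  check_number(initial_density_per_ml, "initial_density_per_ml",
               positive = TRUE, allow_vec = FALSE)
  check_number(initial_fraction_bearing, "initial_fraction_bearing",
               non_negative = TRUE, allow_vec = FALSE)
  if (initial_fraction_bearing > 1) {
    abort_input("`initial_fraction_bearing` must lie in [0, 1].")
  }
  check_number(conjugation_rate_ml_per_cell_h, "conjugation_rate_ml_per_cell_h",
               non_negative = TRUE, allow_vec = FALSE)
  check_number(segregational_loss_per_division, "segregational_loss_per_division",
               non_negative = TRUE, allow_vec = FALSE)
  if (segregational_loss_per_division > 1) {
    abort_input("`segregational_loss_per_division` must lie in [0, 1].")
  }
  check_number(compensation_rate_per_cell_h, "compensation_rate_per_cell_h",
               non_negative = TRUE, allow_vec = FALSE)
  check_count(n_cycles, "n_cycles", positive = TRUE)
  check_count(n_screened, "n_screened", positive = TRUE)
  structure(list(
    m_bearing = m_bearing, m_compensated = m_compensated, m_free = m_free,
    carrying_capacity_per_ml = carrying_capacity_per_ml,
    transfer_period_h = transfer_period_h,
    dilution_factor = dilution_factor,
    initial_density_per_ml = initial_density_per_ml,
    initial_fraction_bearing = initial_fraction_bearing,
    conjugation_rate_ml_per_cell_h = conjugation_rate_ml_per_cell_h,
    segregational_loss_per_division = segregational_loss_per_division,
    compensation_rate_per_cell_h = compensation_rate_per_cell_h,
    n_cycles = as.integer(n_cycles), n_screened = as.integer(n_screened)
  ), class = "growth_params")
}

# Right-hand side of the within-cycle batch model. States: A (bearing
# ancestral), C (bearing compensated), F (free), T (transconjugants:
# free-lineage cells that acquired the plasmid), all cells/ml. Growth is
# logistic with a shared capacity; segregational loss diverts a fraction of
# bearing divisions to the free pool; conjugation converts free cells to
# transconjugants by mass action with every plasmid-bearing cell as a
# potential donor; compensation converts A to C at a constant per-cell rate.
competition_rhs <- function(t, y, p) {
  g <- 1 - sum(y) / p$carrying_capacity_per_ml
  lam <- p$segregational_loss_per_division
  bearing <- y[1] + y[2] + y[4]
  conj <- p$conjugation_rate_ml_per_cell_h * bearing * y[3]
  comp <- p$compensation_rate_per_cell_h * y[1]
  dA <- p$m_bearing * y[1] * g * (1 - lam) - comp
  dC <- p$m_compensated * y[2] * g * (1 - lam) + comp
  dF <- p$m_free * y[3] * g +
    (p$m_bearing * (y[1] + y[4]) + p$m_compensated * y[2]) * g * lam - conj
  dT <- p$m_bearing * y[4] * g * (1 - lam) + conj
  list(c(dA, dC, dF, dT))
}

#' Simulate a serial-transfer competition assay
#'
#' Integrates the three-genotype batch model of [growth_params()] over
#' `n_cycles` growth cycles, diluting all genotypes by `dilution_factor` at
#' each transfer, and derives the colony-screen observations an experimenter
#' would record: total CFU/ml plus a binomial subsample of `n_screened`
#' colonies classified plasmid-bearing or not (colony hybridization cannot
#' distinguish the bearing genotypes). With `deterministic = TRUE` all
#' sampling noise is suppressed and the exact expected screen counts are
#' reported (fractional, so downstream estimates are noise-free).
#'
#' @param params A [growth_params()] object.
#' @param deterministic Suppress plating/sampling noise.
#' @param n_replicates Number of replicate observation series to draw from
#'   the (shared) deterministic dynamics.
#' @param seed Optional integer seed for reproducibility.
#' @param rtol,atol Integration tolerances passed to [deSolve::ode()];
#'   tight defaults so closed-form regimes are met to ~1e-12.
#' @return A list of class `plasfit_sim` with elements
#'   \describe{
#'     \item{densities}{tibble: `cycle`, `time_h`, genotype densities at the
#'       end of each cycle (pre-dilution), `fraction_bearing`.}
#'     \item{observations}{tibble in the format [fitness_trajectory()]
#'       consumes: `replicate_id`, `time_h`, `cfu_total_per_ml`,
#'       `n_screened`, `n_positive`, `cum_dilution`.}
#'     \item{params}{the true generating parameters.}
#'   }
#' @examples
#' sim <- simulate_competition(growth_params(n_cycles = 3), seed = 1)
#' fitness_trajectory(sim$observations)
#' @export
simulate_competition <- function(params = growth_params(),
                                 deterministic = FALSE,
                                 n_replicates = 1L, seed = NULL,
                                 rtol = 1e-12, atol = 1e-4) {
  if (!inherits(params, "growth_params")) {
    abort_input("`params` must be created with growth_params().")
  }
  check_count(n_replicates, "n_replicates", positive = TRUE)
  y <- c(A = params$initial_density_per_ml * params$initial_fraction_bearing,
         C = 0,
         F = params$initial_density_per_ml * (1 - params$initial_fraction_bearing),
         T = 0)
  as_row <- function(cycle, y) {
    tibble(cycle = cycle, time_h = cycle * params$transfer_period_h,
           bearing_ancestral = y[["A"]], bearing_compensated = y[["C"]],
           free = y[["F"]], transconjugant = y[["T"]])
  }
  rows <- vector("list", params$n_cycles + 1L)
  rows[[1]] <- as_row(0L, y)
  for (cyc in seq_len(params$n_cycles)) {
    out <- deSolve::ode(y, c(0, params$transfer_period_h), competition_rhs,
                        params, method = "lsoda", rtol = rtol, atol = atol)
    y <- pmax(out[2, c("A", "C", "F", "T")], 0)
    rows[[cyc + 1L]] <- as_row(cyc, y)
    y <- y / params$dilution_factor
  }
  dens <- bind_rows(rows) |>
    mutate(total = .data$bearing_ancestral + .data$bearing_compensated +
             .data$free + .data$transconjugant,
           fraction_bearing = (.data$total - .data$free) / .data$total)

  obs <- with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      p_bear <- dens$fraction_bearing
      n_pos <- if (deterministic) {
        params$n_screened * p_bear
      } else {
        rbinom(length(p_bear), params$n_screened, p_bear)
      }
      tibble(replicate_id = sprintf("sim%d", r),
             time_h = dens$time_h,
             cfu_total_per_ml = dens$total,
             n_screened = params$n_screened,
             n_positive = n_pos,
             # dilutions applied before this observation (pre-transfer counts)
             cum_dilution = params$dilution_factor^pmax(dens$cycle - 1L, 0L))
    })
  })
  structure(list(densities = dens, observations = obs, params = params),
            class = "plasfit_sim")
}

#' Simulate whole-genome read allocation at a known plasmid copy number
#'
#' Allocates `n_reads` between chromosome and plasmid with probability
#' proportional to replicon length times copy number (chromosome copies = 1),
#' then converts allocated reads to mean depths assuming `effective_read_bp`
#' mapped bases per read. Allocated reads always sum to `n_reads`. Default
#' replicon lengths are the published *P. putida* KT2440 chromosome
#' (6,181,873 bp) and plasmid RP4 (60,099 bp).
#'
#' @param true_copy_number Positive; plasmid copies per chromosome.
#' @param chromosome_bp,plasmid_bp Replicon lengths, bp.
#' @param n_reads Total reads to allocate.
#' @param effective_read_bp Mapped bases per read.
#' @param seed Optional integer seed.
#' @param strain_id Label for the output row.
#' @return A one-row tibble in the coverage-table format consumed by
#'   [copy_number_table()], with the true copy number attached as column
#'   `true_copy_number`.
#' @examples
#' simulate_wgs_reads(3, n_reads = 1e5, seed = 1)
#' @export
simulate_wgs_reads <- function(true_copy_number, chromosome_bp = 6181873L,
                               plasmid_bp = 60099L, n_reads = 1e5,
                               effective_read_bp = 300L, seed = NULL,
                               strain_id = "sim") {
  check_number(true_copy_number, "true_copy_number", positive = TRUE, allow_vec = FALSE)
  check_count(chromosome_bp, "chromosome_bp", positive = TRUE)
  check_count(plasmid_bp, "plasmid_bp", positive = TRUE)
  check_count(n_reads, "n_reads")
  check_count(effective_read_bp, "effective_read_bp", positive = TRUE)
  p_plasmid <- true_copy_number * plasmid_bp /
    (chromosome_bp + true_copy_number * plasmid_bp)
  reads_p <- with_seed_if(seed, rbinom(1, n_reads, p_plasmid))
  reads_c <- n_reads - reads_p
  tibble(strain_id = strain_id,
         total_reads = as.integer(n_reads),
         reads_chromosome = reads_c,
         reads_plasmid = reads_p,
         coverage_chromosome = reads_c * effective_read_bp / chromosome_bp,
         coverage_plasmid = reads_p * effective_read_bp / plasmid_bp,
         true_copy_number = true_copy_number)
}

#' Simulate a two-condition, two-replicate expression matrix
#'
#' Baseline per-ORF abundances are drawn lognormally; a chosen number of
#' ORFs have their treatment mean multiplied (up) or divided (down) by
#' `fold`; every replicate measurement is the condition mean times
#' multiplicative lognormal noise with log-scale standard deviation
#' `log_noise_sd`. The planted truth is returned for recovery testing.
#'
#' @param n_orfs Number of ORFs.
#' @param n_planted_up,n_planted_down Planted differentially expressed ORFs.
#' @param fold Planted fold-change (> 1).
#' @param log_noise_sd Replicate noise sd on the natural-log scale.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of baseline
#'   abundance (RPKM-like units).
#' @param seed Optional integer seed.
#' @return A list: `matrix` (long tibble `orf_id`, `length_bp`, `condition`
#'   in `"control"`/`"treatment"`, `replicate` 1:2, `value`, units RPKM) and
#'   `truth` (tibble `orf_id`, `planted` in `"up"`/`"down"`/`"none"`).
#' @examples
#' sim <- simulate_expression(n_orfs = 500, n_planted_up = 10,
#'                            n_planted_down = 5, seed = 1)
#' head(sim$truth)
#' @export
simulate_expression <- function(n_orfs = 2000, n_planted_up = 50,
                                n_planted_down = 0, fold = 4,
                                log_noise_sd = 0.2,
                                baseline_meanlog = log(50),
                                baseline_sdlog = 1.2, seed = NULL) {
  check_count(n_orfs, "n_orfs", positive = TRUE)
  check_count(n_planted_up, "n_planted_up")
  check_count(n_planted_down, "n_planted_down")
  if (n_planted_up + n_planted_down > n_orfs) {
    abort_input("planted ORFs exceed `n_orfs`.")
  }
  check_number(fold, "fold", positive = TRUE, allow_vec = FALSE)
  if (fold <= 1) abort_input("`fold` must be > 1.")
  check_number(log_noise_sd, "log_noise_sd", non_negative = TRUE, allow_vec = FALSE)

  with_seed_if(seed, {
    orf_id <- sprintf("ORF_%04d", seq_len(n_orfs))
    length_bp <- sample(300:3000, n_orfs, replace = TRUE)
    base <- rlnorm(n_orfs, baseline_meanlog, baseline_sdlog)
    planted <- rep("none", n_orfs)
    idx <- sample.int(n_orfs, n_planted_up + n_planted_down)
    planted[idx[seq_len(n_planted_up)]] <- "up"
    if (n_planted_down > 0) {
      planted[idx[n_planted_up + seq_len(n_planted_down)]] <- "down"
    }
    trt_mean <- base * ifelse(planted == "up", fold,
                              ifelse(planted == "down", 1 / fold, 1))
    samples <- tidyr::expand_grid(
      condition = c("control", "treatment"), replicate = 1:2
    )
    mat <- purrr::pmap_dfr(samples, function(condition, replicate) {
      mu <- if (condition == "treatment") trt_mean else base
      tibble(orf_id = orf_id, length_bp = length_bp,
             condition = condition, replicate = replicate,
             value = mu * rlnorm(n_orfs, 0, log_noise_sd))
    })
    list(matrix = mat, truth = tibble(orf_id = orf_id, planted = planted))
  })
}

#' Simulate colony diameters
#'
#' Draws `n` colony diameters from a normal distribution truncated at zero
#' (negative draws are rejected and redrawn).
#'
#' @param n Number of colonies.
#' @param mean_mm,sd_mm Normal mean and sd in mm.
#' @param seed Optional integer seed.
#' @param strain_id Label for the sample.
#' @return A tibble: `strain_id`, `diameter_mm`.
#' @examples
#' diameter_summary(simulate_colonies(200, 1.01, 0.17, seed = 1))
#' @export
simulate_colonies <- function(n, mean_mm, sd_mm, seed = NULL,
                              strain_id = "sim") {
  check_count(n, "n", positive = TRUE)
  check_number(mean_mm, "mean_mm", positive = TRUE, allow_vec = FALSE)
  check_number(sd_mm, "sd_mm", non_negative = TRUE, allow_vec = FALSE)
  d <- with_seed_if(seed, {
    x <- rnorm(n, mean_mm, sd_mm)
    while (any(x <= 0)) {
      x[x <= 0] <- rnorm(sum(x <= 0), mean_mm, sd_mm)
    }
    x
  })
  tibble(strain_id = strain_id, diameter_mm = d)
}

#' Simulate a decaying band-intensity series
#'
#' Generates insert/reference band-intensity pairs whose expected
#' [band_relative_ratio()] equals the supplied true relative ratios.
#' Intensities receive multiplicative noise with coefficient of variation
#' `noise_cv`.
#'
#' @param true_relative_ratios Relative ratios in (0, 1\]; first must be 1.
#' @param reference_level Mean reference band intensity (arbitrary units).
#' @param noise_cv Coefficient of variation of intensity noise.
#' @param time_step_h Hours between consecutive points (default 48).
#' @param seed Optional integer seed.
#' @return A tibble: `time_h`, `insert_intensity`, `reference_intensity`.
#' @examples
#' simulate_band_series(c(1, 0.5, 0.25), noise_cv = 0)
#' @export
simulate_band_series <- function(true_relative_ratios, reference_level = 100,
                                 noise_cv = 0, time_step_h = 48, seed = NULL) {
  check_number(true_relative_ratios, "true_relative_ratios", positive = TRUE)
  if (true_relative_ratios[1] != 1) {
    abort_input("`true_relative_ratios` must start at 1 (the initial point).")
  }
  check_number(reference_level, "reference_level", positive = TRUE, allow_vec = FALSE)
  check_number(noise_cv, "noise_cv", non_negative = TRUE, allow_vec = FALSE)
  k <- length(true_relative_ratios)
  with_seed_if(seed, {
    noise <- function(n) if (noise_cv == 0) rep(1, n) else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    ref <- reference_level * noise(k)
    # initial insert/reference ratio 0.5 (equal mix of two competitors)
    insert <- 0.5 * true_relative_ratios * ref * noise(k)
    tibble(time_h = time_step_h * (seq_len(k) - 1),
           insert_intensity = insert,
           reference_intensity = ref)
  })
}
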