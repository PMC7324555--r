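test_that("generators are reproducible under a fixed seed", {
  p <- growth_params(n_cycles = 2)
  expect_equal(simulate_competition(p, seed = 3)$observations,
               simulate_competition(p, seed = 3)$observations)
  expect_equal(simulate_wgs_reads(3, seed = 5), simulate_wgs_reads(3, seed = 5))
  expect_equal(simulate_expression(n_orfs = 50, seed = 6, n_planted_up = 5),
               simulate_expression(n_orfs = 50, seed = 6, n_planted_up = 5))
  expect_equal(simulate_colonies(20, 1, 0.2, seed = 7),
               simulate_colonies(20, 1, 0.2, seed = 7))
  expect_equal(simulate_band_series(c(1, 0.5), noise_cv = 0.1, seed = 8),
               simulate_band_series(c(1, 0.5), noise_cv = 0.1, seed = 8))
})

test_that("equal growth rates keep the bearing fraction constant and W at 1", {
  p <- growth_params(m_bearing = 0.7, m_compensated = 0.7, m_free = 0.7,
                     conjugation_rate_ml_per_cell_h = 0,
                     compensation_rate_per_cell_h = 0, n_cycles = 4)
  sim <- simulate_competition(p, deterministic = TRUE)
  expect_equal(sim$densities$fraction_bearing, rep(0.5, 5), tolerance = 1e-9)
  tr <- suppressWarnings(fitness_trajectory(sim$observations))
  expect_equal(tr$mean_w, rep(1, 4), tolerance = 1e-9)
})

test_that("non-saturating deterministic growth recovers W = m_bearing/m_free", {
  p <- growth_params(m_bearing = 0.63, m_compensated = 0.63, m_free = 0.7,
                     carrying_capacity_per_ml = Inf,
                     conjugation_rate_ml_per_cell_h = 0,
                     compensation_rate_per_cell_h = 0, n_cycles = 5)
  sim <- simulate_competition(p, deterministic = TRUE)
  tr <- suppressWarnings(fitness_trajectory(sim$observations))
  expect_equal(tr$mean_w, rep(0.63 / 0.7, 5), tolerance = 1e-9)
})

test_that("a plasmid cost without compensation gives monotone decline", {
  p <- growth_params(compensation_rate_per_cell_h = 0, n_cycles = 6)
  sim <- simulate_competition(p, deterministic = TRUE)
  expect_true(all(diff(sim$densities$fraction_bearing) < 0))
})

test_that("compensation produces a U-shaped bearing-fraction trajectory", {
  sim <- simulate_competition(growth_params(n_cycles = 30), deterministic = TRUE)
  fr <- sim$densities$fraction_bearing
  i_min <- which.min(fr)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(fr))
  expect_gt(fr[length(fr)], fr[i_min]) # recovery after the minimum
})

test_that("default conjugation is negligible and plasmid fully persistent", {
  sim <- simulate_competition(growth_params(n_cycles = 1), deterministic = TRUE)
  end <- sim$densities[2, ]
  donors <- end$bearing_ancestral + end$bearing_compensated
  expect_lt(conjugation_frequency(end$transconjugant, donors), 1.2e-4)
  # pure bearing culture, no segregational loss: persistence stays at 100%
  p <- growth_params(initial_fraction_bearing = 1, n_cycles = 1)
  pure <- simulate_competition(p, deterministic = TRUE)
  obs <- pure$observations
  expect_equal(persistence_fraction(obs$n_screened[2], obs$n_positive[2]), 1)
})

test_that("segregational loss erodes a pure bearing culture", {
  p <- growth_params(initial_fraction_bearing = 1,
                     segregational_loss_per_division = 0.05,
                     compensation_rate_per_cell_h = 0, n_cycles = 3)
  sim <- simulate_competition(p, deterministic = TRUE)
  fr <- sim$densities$fraction_bearing
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[4], 1)
})

test_that("read allocation conserves totals and tracks copy number", {
  r <- simulate_wgs_reads(3, n_reads = 1e5, seed = 2)
  expect_equal(r$reads_chromosome + r$reads_plasmid, r$total_reads)
  expect_equal(r$total_reads, 1e5L)
  # equal-length replicons at copy number 1: expected 50/50 split
  halves <- vapply(1:200, function(s) {
    simulate_wgs_reads(1, chromosome_bp = 1e5, plasmid_bp = 1e5,
                       n_reads = 1000, seed = s)$reads_plasmid
  }, numeric(1))
  expect_equal(mean(halves) / 1000, 0.5, tolerance = 0.01)
  # zero reads propagate as an estimator error downstream
  r0 <- simulate_wgs_reads(3, n_reads = 0, seed = 1)
  expect_error(copy_number_table(r0), class = "plasfit_invalid_input")
})

test_that("copy-number estimation recovers the planted value at 1e5 reads", {
  err <- vapply(1:100, function(s) {
    r <- simulate_wgs_reads(3, n_reads = 1e5, seed = s)
    abs(copy_number_table(r)$copy_number_raw - 3)
  }, numeric(1))
  expect_gte(mean(err <= 0.15), 0.95)
})

test_that("DE caller recovers planted 4-fold ORFs at noise sd 0.2", {
  res <- vapply(1:20, function(s) {
    sim <- simulate_expression(n_orfs = 2000, n_planted_up = 50, fold = 4,
                               log_noise_sd = 0.2, seed = s)
    calls <- call_de(sim$matrix, "treatment", "control")
    truth_up <- sim$truth$orf_id[sim$truth$planted == "up"]
    called <- calls$orf_id[calls$direction != "none"]
    c(recall = length(intersect(called, truth_up)) / 50,
      fp = length(setdiff(called, truth_up)))
  }, numeric(2))
  expect_gte(mean(res["recall", ] >= 0.9 & res["fp", ] <= 5), 0.95)
})

test_that("colony generator is truncated at zero and honours sd = 0", {
  d <- simulate_colonies(50, 0.2, 0.5, seed = 3)
  expect_true(all(d$diameter_mm > 0))
  expect_equal(simulate_colonies(5, 2, 0, seed = 1)$diameter_mm, rep(2, 5))
})

test_that("band series round-trips through band_relative_ratio", {
  truth <- c(1, 0.5, 0.25)
  noiseless <- simulate_band_series(truth, noise_cv = 0)
  expect_equal(band_relative_ratio(noiseless)$relative_ratio, truth,
               tolerance = 1e-12)
  noisy <- simulate_band_series(truth, noise_cv = 0.05, seed = 21)
  rec <- band_relative_ratio(noisy)$relative_ratio
  expect_true(all(abs(rec - truth) / truth <= 0.2))
  expect_error(simulate_band_series(c(0.5, 0.2)), class = "plasfit_invalid_input")
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(growth_params(dilution_factor = 1), class = "plasfit_invalid_input")
  expect_error(growth_params(initial_fraction_bearing = 1.2),
               class = "plasfit_invalid_input")
  expect_error(growth_params(segregational_loss_per_division = -0.1),
               class = "plasfit_invalid_input")
  expect_error(simulate_expression(n_orfs = 10, n_planted_up = 11),
               class = "plasfit_invalid_input")
  expect_error(simulate_expression(fold = 1), class = "plasfit_invalid_input")
})
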