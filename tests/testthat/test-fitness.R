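test_that("cfu_per_ml applies dilution-plating arithmetic", {
  expect_equal(cfu_per_ml(150, 1e5, 0.1), 1.5e8)
  expect_equal(cfu_per_ml(0, 1e3, 0.1), 0)
  expect_equal(cfu_per_ml(37, 1e4, 0.05), 7.4e6)
  expect_error(cfu_per_ml(10, 0.5, 0.1), class = "plasfit_invalid_input")
  expect_error(cfu_per_ml(10, 1e3, 0), class = "plasfit_invalid_input")
})

test_that("strain_cfus partitions the total and conserves it", {
  expect_equal(strain_cfus(2e8, 200, 120),
               tibble::tibble(cfu_bearing = 1.2e8, cfu_free = 8e7))
  expect_equal(strain_cfus(1e8, 200, 0),
               tibble::tibble(cfu_bearing = 0, cfu_free = 1e8))
  expect_equal(strain_cfus(5e7, 96, 24),
               tibble::tibble(cfu_bearing = 1.25e7, cfu_free = 3.75e7))
  # conservation over random inputs
  set.seed(11)
  for (i in 1:20) {
    tot <- runif(1, 1e5, 1e9); ns <- sample(50:500, 1); np <- sample(0:ns, 1)
    out <- strain_cfus(tot, ns, np)
    expect_equal(out$cfu_bearing + out$cfu_free, tot)
  }
  expect_error(strain_cfus(1e8, 100, 101), class = "plasfit_invalid_input")
})

test_that("relative_fitness_w evaluates the log-ratio formula", {
  expect_equal(relative_fitness_w(1e8, 1e6, 1e8, 1e6), 1)
  expect_equal(relative_fitness_w(1e7, 1e6, 1e8, 1e6), 0.5)
  expect_equal(relative_fitness_w(3.2e7, 5e5, 6.4e7, 5e5), log(64) / log(128))
  expect_error(relative_fitness_w(0, 1, 2, 1), class = "plasfit_invalid_input")
  expect_error(relative_fitness_w(2, 1, 1e6, 1e6),
               class = "plasfit_undefined_fitness")
  expect_warning(relative_fitness_w(2e6, 1e6, 5e5, 1e6),
                 class = "plasfit_w_negative_denominator")
})

test_that("relative_fitness_w is scale invariant and ordered by fold-change", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(4, 1e3, 1e9); s <- runif(1, 1e-3, 1e3)
    if (abs(log(x[3] / x[4])) < 1e-3) next
    w1 <- suppressWarnings(relative_fitness_w(x[1], x[2], x[3], x[4]))
    w2 <- suppressWarnings(relative_fitness_w(s * x[1], s * x[2], s * x[3], s * x[4]))
    expect_equal(w1, w2, tolerance = 1e-12)
  }
  # both classes expanding: W > 1 iff bearing log fold-change is larger
  expect_gt(relative_fitness_w(5e7, 1e6, 1e7, 1e6), 1)
  expect_lt(relative_fitness_w(5e6, 1e6, 1e7, 1e6), 1)
})

test_that("fitness_trajectory summarises replicates against the t0 baseline", {
  tr <- suppressWarnings(fitness_trajectory(toy_competition()))
  expect_s3_class(tr, "plasfit_fitness")
  # identical replicates, bearing 10x up, free 100x up
  w_expected <- log(1e7 / 1e6) / log(1e8 / 1e6)
  expect_equal(tr$sd_w, 0)
  expect_equal(tr$n_replicates, 3L)
  expect_equal(tr$mean_w, w_expected, tolerance = 1e-12)
  # hand mean/sd of replicate W values 0.5, 0.6, 0.7
  obs <- purrr::map2_dfr(c("a", "b", "c"), c(0.5, 0.6, 0.7), function(id, w) {
    tibble::tibble(replicate_id = id, time_h = c(0, 24),
                   cfu_total_per_ml = c(2e6, 1e6 * (100^w + 100)),
                   n_screened = 1000,
                   n_positive = c(500, 1000 * 100^w / (100^w + 100)))
  })
  tr2 <- fitness_trajectory(obs)
  expect_equal(tr2$mean_w, 0.6, tolerance = 1e-9)
  expect_equal(tr2$sd_w, 0.1, tolerance = 1e-9)
})

test_that("fitness_trajectory flags degenerate designs", {
  one <- toy_competition(1)
  expect_warning(tr <- fitness_trajectory(one), class = "plasfit_single_replicate")
  expect_equal(tr$sd_w, 0)
  expect_true(tr$single_replicate)
  # zero bearing colonies at t>0 is an extinct flag, not -Inf
  ext <- toy_competition(2)
  ext$n_positive[ext$replicate_id == "r1" & ext$time_h == 24] <- 0
  tr2 <- suppressWarnings(fitness_trajectory(ext))
  expect_equal(tr2$n_extinct, 1L)
  expect_equal(tr2$n_replicates, 1L)
  per <- tidy(tr2)
  expect_equal(per$status[per$replicate_id == "r1"], "extinct")
  expect_true(is.na(per$w[per$replicate_id == "r1"]))
  # missing baseline errors
  nob <- toy_competition(1); nob <- nob[nob$time_h > 0, ]
  expect_error(fitness_trajectory(nob), class = "plasfit_invalid_input")
})

test_that("interval baseline measures each transfer against the previous one", {
  obs <- tibble::tibble(
    replicate_id = "r1", time_h = c(0, 24, 48),
    cfu_total_per_ml = c(2e6, 2e8, 2e8),
    n_screened = 1000, n_positive = c(500, 250, 125),
    cum_dilution = c(1, 1, 100)
  )
  cum <- suppressWarnings(fitness_trajectory(obs, baseline = "initial"))
  int <- suppressWarnings(fitness_trajectory(obs, baseline = "previous"))
  expect_equal(nrow(cum), 2)
  # interval W at 48 h uses the 24-h counts as baseline
  b24 <- 2e8 * 0.25; f24 <- 2e8 * 0.75
  b48 <- 2e8 * 0.125 * 100; f48 <- 2e8 * 0.875 * 100
  expect_equal(int$mean_w[2], log(b48 / b24) / log(f48 / f24), tolerance = 1e-12)
})

test_that("persistence and conjugation readouts are plain ratios", {
  expect_equal(persistence_fraction(200, 200), 1)
  expect_equal(persistence_fraction(200, 0), 0)
  expect_equal(persistence_fraction(96, 72), 0.75)
  expect_error(persistence_fraction(96, 97), class = "plasfit_invalid_input")
  expect_equal(conjugation_frequency(1.2e3, 1e7), 1.2e-4)
  expect_equal(conjugation_frequency(0, 1e7), 0)
  expect_equal(conjugation_frequency(5e2, 4e8), 1.25e-6)
  expect_error(conjugation_frequency(1, 0), class = "plasfit_invalid_input")
})

test_that("band_relative_ratio normalises to the initial timepoint", {
  out <- band_relative_ratio(tibble::tibble(
    time_h = c(0, 48), insert_intensity = c(100, 40),
    reference_intensity = c(200, 160)))
  expect_equal(out$relative_ratio, c(1, 0.5))
  out2 <- band_relative_ratio(tibble::tibble(
    time_h = c(0, 48, 96), insert_intensity = c(80, 60, 20),
    reference_intensity = c(160, 150, 100)))
  expect_equal(out2$relative_ratio, c(1, 0.8, 0.4))
  # constant series is identically 1; first point is always exactly 1
  cst <- band_relative_ratio(tibble::tibble(
    time_h = 0:3 * 48, insert_intensity = 70, reference_intensity = 210))
  expect_equal(cst$relative_ratio, rep(1, 4))
  expect_error(band_relative_ratio(tibble::tibble(
    time_h = c(0, 48), insert_intensity = c(0, 10),
    reference_intensity = c(100, 100))), class = "plasfit_undefined_ratio")
})
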