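test_that("exact-moment samples hit their targets and are deterministic", {
  x <- exact_moment_sample(12, 743.53, 252.08, seed = 4)
  expect_equal(mean(x), 743.53, tolerance = 1e-9)
  expect_equal(sd(x), 252.08, tolerance = 1e-9)
  expect_identical(x, exact_moment_sample(12, 743.53, 252.08, seed = 4))
  expect_equal(exact_moment_sample(5, 3, 0), rep(3, 5))
  expect_error(exact_moment_sample(1, 0, 1),
               class = "bsa_insufficient_data_error")
})

test_that("degenerate parent dosages give single-class populations", {
  m0 <- dosage_model(parent_dosage = c(0, 0))
  pop0 <- simulate_f1_population(50, m0, seed = 1)
  expect_true(all(pop0$class == "SD"))
  m8 <- dosage_model(parent_dosage = c(8, 8))
  pop8 <- simulate_f1_population(50, m8, seed = 1)
  expect_true(all(pop8$class == "DN1"))
  expect_error(dosage_model(parent_dosage = c(9, 0)),
               class = "bsa_domain_error")
})

test_that("offspring dosages follow the gamete binomial convolution", {
  model <- dosage_model(parent_dosage = c(6, 0))
  pop <- simulate_f1_population(600, model, seed = 77)
  ## gamete 1 ~ Binomial(4, 0.75), gamete 2 = 0, so dosage ~ Binomial(4, .75)
  expected <- dbinom(0:4, 4, 0.75)
  observed <- tabulate(pop$dosage + 1, nbins = 5) / 600
  expect_lt(max(abs(observed - expected)), 4 * sqrt(0.25 * 0.75 / 600) + 0.02)
  ## class frequencies follow the threshold mapping of the same convolution
  exp_sd <- sum(expected[0:1 + 1])     # dosage <= 1 -> SD
  obs_sd <- mean(pop$class == "SD")
  expect_lt(abs(obs_sd - exp_sd), 0.05)
  expect_identical(pop, simulate_f1_population(600, model, seed = 77))
})

test_that("noise-free simulation yields the exact three-fold planted ratio", {
  model <- signal_model(n_features = 30, planted_index = 7, sigma = 0)
  sim <- simulate_bulk_hybridization(model = model, seed = 2)
  signals <- spike_in_normalize(apply_qc_flags(sim$signals))
  fp <- build_fingerprints(signals)
  planted <- fp[fp$feature_id == sim$truth$planted_feature, ]
  ratio <- planted$value[planted$bulk == "DN1"] /
    planted$value[planted$bulk == "SD"]
  expect_equal(ratio, 3, tolerance = 1e-9)
  expect_equal(sim$truth$expected_dn1_sd_ratio, 3,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spike-in normalisation removes injected slide distortions", {
  model <- signal_model(n_features = 10, planted_index = 1, sigma = 0,
                        slide_sdlog = 0.4)
  sim <- simulate_bulk_hybridization(model = model, seed = 3)
  signals <- spike_in_normalize(apply_qc_flags(sim$signals))
  ## with sigma = 0 each non-planted feature is constant after normalisation
  f2 <- signals$snr[signals$feature_id == "S002"]
  expect_lt(diff(range(f2)) / mean(f2), 1e-9)
})

test_that("a null dosage effect leaves the planted feature unremarkable", {
  model <- signal_model(n_features = 60, planted_index = 30, beta = 0)
  sim <- simulate_bulk_hybridization(model = model, seed = 6)
  signals <- spike_in_normalize(apply_qc_flags(sim$signals))
  st <- feature_stats(signals, "DN1", "SD")
  planted_rank <- rank(-abs(st$t))[st$feature_id == "S030"]
  expect_gt(planted_rank, 3)  # not systematically at the top
})

test_that("simulation is bitwise deterministic under a seed", {
  a <- simulate_bulk_hybridization(seed = 9,
                                   model = signal_model(n_features = 15,
                                                        planted_index = 5))
  b <- simulate_bulk_hybridization(seed = 9,
                                   model = signal_model(n_features = 15,
                                                        planted_index = 5))
  expect_identical(a$signals, b$signals)
})

test_that("simulated runs round-trip through scan files", {
  model <- signal_model(n_features = 8, planted_index = 2)
  sim <- simulate_bulk_hybridization(model = model, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_simulated_run(sim, dir)
  sheet <- read_sample_sheet(paths$sample_sheet)
  layout <- read_feature_layout(paths$layout)
  signals <- collect_signals(sheet, layout, dir)
  merged <- dplyr::inner_join(
    signals, sim$signals,
    by = c("hybridization_id", "feature_id")
  )
  expect_equal(nrow(merged), nrow(sim$signals))
  expect_equal(merged$snr.x, merged$snr.y, tolerance = 1e-9)
})

test_that("beta_for_ratio solves the fingerprint-ratio equation", {
  b <- beta_for_ratio(3, 6, 1)
  expect_equal((1 + b * 6) / (1 + b * 1), 3, tolerance = 1e-12)
  expect_equal(b, 2 / 3, tolerance = 1e-12)
})
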