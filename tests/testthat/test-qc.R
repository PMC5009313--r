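test_that("SNR is background-corrected signal over background SD", {
  expect_equal(compute_snr(150, 50, 10), 10)
  expect_equal(compute_snr(50, 50, 10), 0)
  expect_error(compute_snr(150, 50, 0),
               class = "bsa_degenerate_background_error")
})

test_that("QC flags mask cells and negative controls everywhere", {
  sig <- toy_signals(list(DN1 = list(c(10, 10, 10))), n_features = 2)
  neg <- dplyr::mutate(sig[sig$feature_id == "FT02", ],
                       feature_id = "NEG1", category = "negative_control")
  sig <- dplyr::bind_rows(sig, neg)
  sig$flag[2] <- "bad"
  out <- apply_qc_flags(sig)
  expect_true(all(out$masked[out$category == "negative_control"]))
  expect_true(out$masked[2])
  expect_equal(sum(out$masked), sum(out$category == "negative_control") + 1)
  ## all-good matrix unchanged
  clean <- apply_qc_flags(toy_signals(list(DN1 = list(c(10, 10)))))
  expect_false(any(clean$masked))
})

test_that("detection filter applies the strict more-than-half rule", {
  mk <- function(v) {
    sig <- toy_signals(list(DN1 = list(v)), n_features = 1)
    ## baseline features removed: only FT01 considered
    snr_detection_filter(sig, snr_threshold = 7)
  }
  expect_true("FT01" %in% mk(c(7.1, 7.1, 7.1, 7.1, 2, 2))$retained)   # 4/6
  expect_true("FT01" %in% mk(c(8, 8, 8, 2, 2, 2))$dropped)            # 3/6
  expect_true("FT01" %in% mk(rep(7, 6))$dropped)                      # strict >
})

test_that("a feature detected in any replicate group is retained", {
  sig <- toy_signals(list(DN1 = list(c(1, 1, 1, 1)),
                          SD = list(c(20, 20, 20, 20))), n_features = 1)
  res <- snr_detection_filter(sig)
  expect_true("FT01" %in% res$retained)
})

test_that("lowering the threshold never shrinks the retained set", {
  sim <- simulate_bulk_hybridization(seed = 11,
                                     model = signal_model(n_features = 40,
                                                          planted_index = 5))
  sig <- apply_qc_flags(sim$signals)
  r_hi <- snr_detection_filter(sig, snr_threshold = 20)$retained
  r_lo <- snr_detection_filter(sig, snr_threshold = 5)$retained
  expect_true(all(r_hi %in% r_lo))
})

test_that("spike-in normalisation equalises spike means and is idempotent", {
  sig <- toy_signals(list(DN1 = list(c(10, 10)), SD = list(c(10, 10))),
                     n_features = 2)
  ## distort one hybridisation by half
  h <- sig$hybridization_id == "SD_b1_t1"
  sig$snr[h] <- sig$snr[h] / 2
  out <- spike_in_normalize(sig)
  spike <- out[out$feature_id == "SPIKE", ]
  expect_equal(length(unique(round(spike$snr, 9))), 1)
  ## the distortion is undone: FT01 equal across all hybridisations,
  ## at 10 * (grand spike mean 43.75) / 50
  expect_equal(unique(round(out$snr[out$feature_id == "FT01"], 9)), 8.75)
  ## idempotence
  again <- spike_in_normalize(out)
  expect_equal(again$snr, out$snr, tolerance = 1e-12)
  ## identical spike values leave the matrix unchanged
  clean <- toy_signals(list(DN1 = list(c(5, 6))))
  expect_equal(spike_in_normalize(clean)$snr, clean$snr)
})

test_that("masked or non-positive spike-in is a normalisation error", {
  sig <- toy_signals(list(DN1 = list(c(10, 10))))
  sig$masked[sig$feature_id == "SPIKE" &
               sig$hybridization_id == "DN1_b1_t1"] <- TRUE
  expect_error(spike_in_normalize(sig), class = "bsa_normalization_error")
  sig2 <- toy_signals(list(DN1 = list(c(10, 10))))
  sig2$snr[sig2$feature_id == "SPIKE"][1] <- -1
  expect_error(spike_in_normalize(sig2), class = "bsa_normalization_error")
})

test_that("fingerprints average technical then biological replicates", {
  sig <- toy_signals(list(DN1 = list(1:6, 2:7)), n_features = 1)
  fp <- build_fingerprints(sig)
  expect_equal(fp$value[fp$feature_id == "FT01"], 4)  # (3.5 + 4.5)/2
  ## single bio rep equals the technical mean
  sig1 <- toy_signals(list(DN1 = list(c(2, 4, 9))), n_features = 1)
  expect_equal(build_fingerprints(sig1)$value[1], 5)
  ## a masked technical replicate is excluded
  sig2 <- toy_signals(list(DN1 = list(1:6)), n_features = 1)
  sig2$masked[sig2$feature_id == "FT01" & sig2$tech_rep == 6] <- TRUE
  expect_equal(build_fingerprints(sig2)$value[1], 3)  # mean(1:5)
})

test_that("fingerprints scale linearly with the bulk's SNR", {
  sig <- toy_signals(list(DN1 = list(c(3, 5, 7), c(4, 6, 8))),
                     n_features = 2)
  fp1 <- build_fingerprints(sig)
  sig2 <- dplyr::mutate(sig, snr = snr * 2.5)
  fp2 <- build_fingerprints(sig2)
  expect_equal(fp2$value, fp1$value * 2.5)
})

test_that("subtraction efficiency matches the 3-of-290 worked example", {
  fp <- tibble::tibble(feature_id = sprintf("C%03d", 1:290),
                       value = c(rep(20, 3), rep(1, 287)))
  res <- subtraction_efficiency(fp, threshold = 7)
  expect_equal(res$n_detected, 3)
  expect_equal(res$efficiency_percent, 100 * 287 / 290)
  expect_equal(res$efficiency_rounded, 99L)
  expect_equal(length(setdiff(fp$feature_id, res$detected_ids)), 287)

  none <- subtraction_efficiency(tibble::tibble(feature_id = "a", value = 1))
  expect_equal(none$efficiency_percent, 100)
  all_det <- subtraction_efficiency(tibble::tibble(feature_id = "a",
                                                   value = 100))
  expect_equal(all_det$efficiency_percent, 0)
  expect_error(subtraction_efficiency(fp[0, ]),
               class = "bsa_empty_layout_error")
})
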