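#' Sample with exact first and second moments
#'
#' Draws `n` standard-normal values under the given seed and affinely
#' rescales them so the sample mean and sample standard deviation (n - 1
#' denominator) equal the targets exactly (to floating precision). Used to
#' reconstruct per-replicate value sets from published group statistics.
#'
#' @param n Number of values (>= 2 when `target_sd > 0`).
#' @param target_mean,target_sd Target sample moments.
#' @param seed Integer seed (optional; caller's RNG untouched either way).
#' @return Numeric vector of length `n`.
#' @export
exact_moment_sample <- function(n, target_mean, target_sd, seed = NULL) {
  stopifnot(target_sd >= 0)
  if (target_sd == 0) return(rep(target_mean, n))
  if (n < 2) {
    abort("need n >= 2 for a positive target SD",
          class = "bsa_insufficient_data_error")
  }
  z <- with_seed_if(seed, stats::rnorm(n))
  z <- (z - mean(z)) / stats::sd(z)
  target_mean + target_sd * z
}

#' Allele-dosage model for a polyploid F1 cross
#'
#' Offspring allele dosage at a single locus is the sum of two gamete
#' dosages, each drawn Binomial(ploidy/2, parent_dosage/ploidy): every
#' gamete carries half the chromosome complement, each chromosome bearing
#' the allele with probability equal to the parent's allele frequency at
#' the locus. Flowering strength follows dosage through fixed thresholds:
#' dosage >= `dn1_min` scores 1 (strong day-neutral), >= `dn2_min` scores
#' 2, >= `dn3_min` scores 3, below that scores 4 (short-day). The mapping
#' is a modelling device consistent with a dosage-dependent trait, not an
#' empirical claim.
#'
#' @param ploidy Even integer, default 8 (octoploid).
#' @param parent_dosage Length-2 vector of parental allele dosages in
#'   0..ploidy.
#' @param dn1_min,dn2_min,dn3_min Dosage thresholds for scores 1, 2, 3.
#' @return List of class `dosage_model`.
#' @export
dosage_model <- function(ploidy = 8, parent_dosage = c(6, 0),
                         dn1_min = 6, dn2_min = 4, dn3_min = 2) {
  stopifnot(ploidy %% 2 == 0, dn1_min > dn2_min, dn2_min > dn3_min,
            dn3_min > 0)
  if (any(parent_dosage < 0) || any(parent_dosage > ploidy)) {
    abort("parent dosage outside [0, ploidy]", class = "bsa_domain_error")
  }
  structure(list(ploidy = ploidy, parent_dosage = parent_dosage,
                 dn1_min = dn1_min, dn2_min = dn2_min, dn3_min = dn3_min),
            class = "dosage_model")
}

dosage_to_score <- function(dosage, model) {
  ifelse(dosage >= model$dn1_min, 1L,
         ifelse(dosage >= model$dn2_min, 2L,
                ifelse(dosage >= model$dn3_min, 3L, 4L)))
}

#' Simulate an F1 population under the dosage model
#'
#' @param n_plants Number of offspring.
#' @param model A [dosage_model()].
#' @param seed Integer seed.
#' @return Tibble: `plant_id`, `dosage`, `flowering_score`, `class`.
#' @export
simulate_f1_population <- function(n_plants, model = dosage_model(),
                                   seed = NULL) {
  half <- model$ploidy / 2
  dosage <- with_seed_if(seed, {
    g1 <- stats::rbinom(n_plants, half, model$parent_dosage[1] / model$ploidy)
    g2 <- stats::rbinom(n_plants, half, model$parent_dosage[2] / model$ploidy)
    g1 + g2
  })
  score <- dosage_to_score(dosage, model)
  tibble::tibble(
    plant_id = sprintf("F1_%04d", seq_len(n_plants)),
    dosage = dosage,
    flowering_score = score,
    class = score_to_class(score)
  )
}

#' Signal model for simulated bulk hybridisations
#'
#' Each feature has a log-normal baseline SNR shared by all bulks; the one
#' planted trait-linked feature is amplified by `1 + beta * dosage` in each
#' bulk, reflecting the mean allele dosage of the pooled DNA. Each cell
#' gets independent multiplicative log-normal noise (`sigma` on the log
#' scale), and each hybridisation (slide) gets a systematic multiplicative
#' distortion (`slide_sdlog`) applied to every spot including the
#' spike-in, which spike-in normalisation must undo.
#'
#' @param n_features Number of subtracted features (default 287).
#' @param planted_index Index of the trait-linked feature (default 144).
#' @param beta Dosage effect on the planted feature's signal (default 2/3,
#'   which with the default bulk dosages gives a three-fold strong-DN / SD
#'   fingerprint ratio).
#' @param sigma Log-scale SD of per-cell noise (default 0.35).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-feature baselines (defaults log(100), 0.8).
#' @param slide_sdlog Log-scale SD of per-hybridisation distortions
#'   (default 0.2).
#' @param n_bio,n_tech Biological and technical replicates per bulk
#'   (defaults 2 and 6).
#' @param spike_snr Baseline SNR of the spike-in control (default 50).
#' @param n_pos,n_neg,n_print Numbers of positive, negative and printing
#'   controls (defaults 6, 9, 2).
#' @return List of class `signal_model`.
#' @export
signal_model <- function(n_features = 287, planted_index = 144,
                         beta = 2 / 3, sigma = 0.35,
                         baseline_meanlog = log(100), baseline_sdlog = 0.8,
                         slide_sdlog = 0.2, n_bio = 2, n_tech = 6,
                         spike_snr = 50, n_pos = 6, n_neg = 9, n_print = 2) {
  if (sigma < 0) abort("sigma must be >= 0", class = "bsa_domain_error")
  if (planted_index > n_features) {
    abort("planted index exceeds number of features",
          class = "bsa_domain_error")
  }
  structure(list(n_features = n_features, planted_index = planted_index,
                 beta = beta, sigma = sigma,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 slide_sdlog = slide_sdlog, n_bio = n_bio, n_tech = n_tech,
                 spike_snr = spike_snr, n_pos = n_pos, n_neg = n_neg,
                 n_print = n_print),
            class = "signal_model")
}

#' Dosage effect giving a target fingerprint ratio
#'
#' Solves `(1 + beta * d_high) / (1 + beta * d_low) = ratio` for `beta`.
#'
#' @param ratio Target fingerprint ratio between two bulks.
#' @param d_high,d_low Mean allele dosages of the two bulks.
#' @return The dosage effect `beta`.
#' @export
beta_for_ratio <- function(ratio, d_high, d_low) {
  stopifnot(ratio > 1, d_high > ratio * d_low)
  (ratio - 1) / (d_high - ratio * d_low)
}

simulated_layout <- function(model) {
  tibble::tibble(
    feature_id = c(sprintf("S%03d", seq_len(model$n_features)),
                   sprintf("POS%d", seq_len(model$n_pos)),
                   sprintf("NEG%d", seq_len(model$n_neg)),
                   sprintf("PRINT%d", seq_len(model$n_print)),
                   "SPIKE"),
    category = c(rep("subtracted", model$n_features),
                 rep("positive_control", model$n_pos),
                 rep("negative_control", model$n_neg),
                 rep("printing_control", model$n_print),
                 "spike_in")
  )
}

#' Simulate bulk-hybridisation signal data with a planted marker
#'
#' Generates the full replicate structure (each bulk x `n_bio` biological
#' x `n_tech` technical replicates, one hybridisation per (bulk, bio)
#' slide with the technical replicates as repeated spots... here each
#' (bulk, bio, tech) triple is one hybridisation data point, mirroring the
#' twelve data points per feature of the emulated design) under the
#' [signal_model()], and returns the long signal tibble plus the ground
#' truth of the planted feature.
#'
#' @param bulk_dosages Named numeric vector: mean allele dosage of the
#'   planted locus in each bulk (default `c(DN1 = 6, DN2 = 4, DN3 = 2,
#'   SD = 1)`).
#' @param model A [signal_model()].
#' @param seed Integer seed.
#' @return List: `signals` (long tibble ready for the QC pipeline),
#'   `layout`, `truth` (planted feature id, beta, expected DN1/SD ratio),
#'   `bulk_dosages`.
#' @export
simulate_bulk_hybridization <- function(bulk_dosages = c(DN1 = 6, DN2 = 4,
                                                         DN3 = 2, SD = 1),
                                        model = signal_model(),
                                        seed = NULL) {
  stopifnot(length(bulk_dosages) >= 1, !is.null(names(bulk_dosages)))
  layout <- simulated_layout(model)
  planted_id <- sprintf("S%03d", model$planted_index)
  with_seed_if(seed, {
    baseline <- setNames(
      exp(stats::rnorm(model$n_features, model$baseline_meanlog,
                       model$baseline_sdlog)),
      sprintf("S%03d", seq_len(model$n_features))
    )
    base_all <- c(baseline,
                  setNames(rep(100, model$n_pos),
                           sprintf("POS%d", seq_len(model$n_pos))),
                  setNames(rep(0.5, model$n_neg),
                           sprintf("NEG%d", seq_len(model$n_neg))),
                  setNames(rep(50, model$n_print),
                           sprintf("PRINT%d", seq_len(model$n_print))),
                  SPIKE = model$spike_snr)
    design <- tidyr::expand_grid(
      target = names(bulk_dosages),
      bio_rep = seq_len(model$n_bio),
      tech_rep = seq_len(model$n_tech)
    )
    design$hybridization_id <- sprintf("%s_b%d_t%d", design$target,
                                       design$bio_rep, design$tech_rep)
    slide_factor <- setNames(
      exp(stats::rnorm(nrow(design), 0, model$slide_sdlog)),
      design$hybridization_id
    )
    cells <- tidyr::expand_grid(design, layout)
    dosage <- bulk_dosages[cells$target]
    effect <- ifelse(cells$feature_id == planted_id,
                     1 + model$beta * dosage, 1)
    noise <- exp(stats::rnorm(nrow(cells), 0, model$sigma))
    cells$snr <- unname(base_all[cells$feature_id] * effect *
                          slide_factor[cells$hybridization_id] * noise)
    cells$flag <- "good"
    cells$masked <- FALSE
    cells$mask_reason <- NA_character_
    d <- bulk_dosages
    expected_ratio <- if (all(c("DN1", "SD") %in% names(d))) {
      (1 + model$beta * d[["DN1"]]) / (1 + model$beta * d[["SD"]])
    } else {
      NA_real_
    }
    list(signals = cells,
         layout = layout,
         truth = list(planted_feature = planted_id, beta = model$beta,
                      expected_dn1_sd_ratio = expected_ratio,
                      baseline = baseline),
         bulk_dosages = bulk_dosages)
  })
}

#' Write a simulated run as scan tables plus sample sheet
#'
#' Serialises a [simulate_bulk_hybridization()] result into the file
#' formats the readers consume: one tab-delimited scan table per
#' hybridisation (SNR encoded as signal over a flat background so that
#' [compute_snr()] recovers it exactly), a sample sheet, and the layout.
#'
#' @param sim Result of [simulate_bulk_hybridization()].
#' @param dir Output directory (created if needed).
#' @return Paths of sample sheet and layout, invisibly.
#' @export
write_simulated_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout_path <- file.path(dir, "layout.tsv")
  readr::write_tsv(sim$layout, layout_path, progress = FALSE)
  hybs <- dplyr::distinct(sim$signals, .data$hybridization_id, .data$target,
                          .data$bio_rep, .data$tech_rep)
  sheet <- tibble::tibble(
    hybridization_id = hybs$hybridization_id,
    target = hybs$target,
    biological_replicate = hybs$bio_rep,
    technical_replicate = hybs$tech_rep,
    scan_file = paste0(hybs$hybridization_id, ".tsv")
  )
  for (i in seq_len(nrow(sheet))) {
    cells <- sim$signals[sim$signals$hybridization_id ==
                           sheet$hybridization_id[i], ]
    scan <- tibble::tibble(
      ID = cells$feature_id,
      `F635 Mean` = 100 + cells$snr * 20,
      `B635 Mean` = 100,
      `B635 SD` = 20,
      Flags = 0L
    )
    readr::write_tsv(scan, file.path(dir, sheet$scan_file[i]),
                     progress = FALSE)
  }
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  invisible(list(sample_sheet = sheet_path, layout = layout_path))
}

#' Replicate-level fixture reconstructing the published group statistics
#'
#' For every row of [ref_marker_stats()], builds 12 day-neutral and 12
#' short-day values (2 biological x 6 technical replicates) whose sample
#' moments equal the published means and standard deviations exactly, via
#' [exact_moment_sample()]. Running [independent_t_test()] on a row
#' reproduces the published t statistic and degrees of freedom.
#'
#' @param seed Base seed; each row uses `seed + 10 * row` offsets.
#' @param n_per_group Values per group (default 12).
#' @return Tibble: the reference columns plus list-columns `values_dn`,
#'   `values_sd` and the implied `variant` ("pooled" when the published df
#'   is the pooled n1 + n2 - 2, "welch" otherwise).
#' @export
marker_stats_fixture <- function(seed = 1, n_per_group = 12) {
  ref <- ref_marker_stats()
  ref$values_dn <- purrr::map(seq_len(nrow(ref)), function(i) {
    exact_moment_sample(n_per_group, ref$mean_dn[i], ref$sd_dn[i],
                        seed = seed + 10 * i)
  })
  ref$values_sd <- purrr::map(seq_len(nrow(ref)), function(i) {
    exact_moment_sample(n_per_group, ref$mean_sd[i], ref$sd_sd[i],
                        seed = seed + 10 * i + 5)
  })
  ref$variant <- ifelse(ref$df_printed == 2 * n_per_group - 2,
                        "pooled", "welch")
  ref
}

#' @rdname marker_stats_fixture
#' @param fixture Result of `marker_stats_fixture()`.
#' @param variant Passed to [independent_t_test()]; the default uses each
#'   row's implied variant.
#' @return For `marker_stats_tests`: tibble with computed `t`, `df`,
#'   `df_rounded`, `p`, `fisher_ratio` per row.
#' @export
marker_stats_tests <- function(fixture = marker_stats_fixture(),
                               variant = NULL) {
  rows <- purrr::map(seq_len(nrow(fixture)), function(i) {
    v <- if (is.null(variant)) fixture$variant[i] else variant
    tt <- independent_t_test(fixture$values_dn[[i]], fixture$values_sd[[i]],
                             variant = v)
    tibble::tibble(
      comparison = fixture$comparison[i],
      feature_id = fixture$feature_id[i],
      mean_dn = tt$g1$M, sd_dn = tt$g1$s,
      mean_sd = tt$g2$M, sd_sd = tt$g2$s,
      fisher_ratio = fisher_ratio(tt$g1, tt$g2),
      t = tt$t, df = tt$df, df_rounded = tt$df_rounded, p = tt$p,
      variant = tt$variant
    )
  })
  dplyr::bind_rows(rows)
}
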