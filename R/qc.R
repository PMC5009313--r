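#' Signal-to-noise ratio of a spot
#'
#' SNR is the background-corrected spot intensity in units of local
#' background variability: `(signal_mean - background_mean) / background_sd`.
#' Sub-background spots yield negative SNR; a zero background SD has no
#' defined SNR and is rejected.
#'
#' @param signal_mean,background_mean,background_sd Numeric vectors of spot
#'   statistics (fluorescence units).
#' @return Numeric vector of SNR values.
#' @export
compute_snr <- function(signal_mean, background_mean, background_sd) {
  if (any(background_sd == 0, na.rm = TRUE)) {
    abort("background SD of 0: SNR undefined for degenerate background",
          class = "bsa_degenerate_background_error")
  }
  (signal_mean - background_mean) / background_sd
}

#' Apply manual QC flags and control masking
#'
#' Cells flagged bad or empty by the operator are masked; negative-control
#' features are masked in every hybridisation (they measure unbound
#' background, not markers). Positive and printing controls stay unmasked
#' so they can be inspected, but marker statistics only ever see
#' `category == "subtracted"` features.
#'
#' @param signals Long signal tibble from [collect_signals()] or
#'   [simulate_bulk_hybridization()].
#' @return The tibble with `masked` / `mask_reason` updated.
#' @export
apply_qc_flags <- function(signals) {
  flag <- if ("flag" %in% names(signals)) signals$flag
          else rep("good", nrow(signals))
  bad <- flag %in% c("bad", "empty")
  neg <- signals$category == "negative_control"
  signals$masked <- signals$masked | bad | neg
  signals$mask_reason[bad] <- paste0("flag_", flag[bad])
  signals$mask_reason[neg] <- "negative_control"
  signals
}

#' Detection filter on signal-to-noise ratio
#'
#' A feature is detected in a replicate group (one bulk x biological
#' replicate, i.e. one slide's technical replicates) when strictly more than
#' `min_pass_fraction` of its unmasked technical replicates have SNR
#' strictly above `snr_threshold`. A feature is retained when any replicate
#' group detects it: a feature present in one bulk but absent in another is
#' precisely a candidate marker, so absence somewhere must not discard it.
#'
#' @param signals Long signal tibble (after [apply_qc_flags()]).
#' @param snr_threshold Detection threshold on SNR (default 7).
#' @param min_pass_fraction Fraction of technical replicates that must
#'   exceed the threshold, strictly (default 0.5: 4 of 6 passes, 3 of 6
#'   fails).
#' @return A list with character vectors `retained` and `dropped` (subtracted
#'   features only) and the per-group pass table `detail`.
#' @export
snr_detection_filter <- function(signals, snr_threshold = 7,
                                 min_pass_fraction = 0.5) {
  stopifnot(snr_threshold > 0, min_pass_fraction > 0, min_pass_fraction < 1)
  sub <- dplyr::filter(signals, .data$category == "subtracted")
  detail <- dplyr::summarise(
    dplyr::group_by(sub, .data$feature_id, .data$target, .data$bio_rep),
    n_unmasked = sum(!.data$masked),
    n_pass = sum(!.data$masked & .data$snr > .env$snr_threshold),
    pass = .data$n_unmasked > 0 &
      .data$n_pass > .env$min_pass_fraction * .data$n_unmasked,
    .groups = "drop"
  )
  status <- dplyr::summarise(
    dplyr::group_by(detail, .data$feature_id),
    any_pass = any(.data$pass),
    any_data = any(.data$n_unmasked > 0),
    .groups = "drop"
  )
  if (any(!status$any_data)) {
    warn(paste0(sum(!status$any_data),
                " feature(s) had no unmasked replicates and were dropped"))
  }
  list(
    retained = status$feature_id[status$any_pass],
    dropped = status$feature_id[!status$any_pass],
    detail = detail
  )
}

#' Spike-in normalisation across hybridisations
#'
#' Rescales every hybridisation so that its mean spike-in SNR equals the
#' grand mean of the spike-in SNR over all hybridisations. The spike-in is
#' an exogenous printed sequence expected to bind its labelled counterpart
#' identically on every slide, so any deviation measures a systematic
#' slide/hybridisation effect, which this step divides out.
#'
#' @param signals Long signal tibble with a `spike_in` category present.
#' @return The tibble with `snr` rescaled (masked cells rescaled too, they
#'   stay excluded from statistics by their mask).
#' @export
spike_in_normalize <- function(signals) {
  spikes <- dplyr::filter(signals, .data$category == "spike_in")
  if (nrow(spikes) == 0) {
    abort("no spike_in features present", class = "bsa_normalization_error")
  }
  per_hyb <- dplyr::summarise(
    dplyr::group_by(spikes, .data$hybridization_id),
    n_usable = sum(!.data$masked),
    spike_mean = mean(.data$snr[!.data$masked]),
    .groups = "drop"
  )
  all_hybs <- unique(signals$hybridization_id)
  bad <- union(
    setdiff(all_hybs, per_hyb$hybridization_id),
    per_hyb$hybridization_id[per_hyb$n_usable == 0 |
                             !is.finite(per_hyb$spike_mean) |
                             per_hyb$spike_mean <= 0]
  )
  if (length(bad) > 0) {
    abort(paste0("spike-in masked or non-positive in hybridisation(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "bsa_normalization_error")
  }
  reference <- mean(per_hyb$spike_mean)
  factors <- setNames(reference / per_hyb$spike_mean, per_hyb$hybridization_id)
  signals$snr <- signals$snr * unname(factors[signals$hybridization_id])
  signals
}

#' Build per-bulk feature fingerprints
#'
#' Collapses the replicate structure into one value per feature per bulk:
#' the mean of normalised SNR over unmasked technical replicates within each
#' biological replicate, then the equal-weight mean over biological
#' replicates.
#'
#' @param signals Normalised long signal tibble.
#' @param features Optional character vector restricting (and ordering) the
#'   features; defaults to all subtracted features present.
#' @param targets Optional character vector of bulks; defaults to all.
#' @return Long tibble `feature_id`, `bulk`, `value`, `n_bio`, `n_tech`
#'   (total unmasked technical replicates combined). Features unmasked in
#'   zero replicates get `NA` values.
#' @export
build_fingerprints <- function(signals, features = NULL, targets = NULL) {
  if (is.null(features)) {
    features <- unique(signals$feature_id[signals$category == "subtracted"])
  }
  if (is.null(targets)) targets <- unique(signals$target)
  sub <- dplyr::filter(signals, .data$feature_id %in% .env$features,
                       .data$target %in% .env$targets)
  per_bio <- dplyr::summarise(
    dplyr::group_by(sub, .data$feature_id, .data$target, .data$bio_rep),
    tech_mean = if (any(!.data$masked)) mean(.data$snr[!.data$masked])
                else NA_real_,
    n_tech = sum(!.data$masked),
    .groups = "drop"
  )
  fp <- dplyr::summarise(
    dplyr::group_by(per_bio, .data$feature_id, .data$target),
    value = if (any(!is.na(.data$tech_mean)))
      mean(.data$tech_mean, na.rm = TRUE) else NA_real_,
    n_bio = sum(!is.na(.data$tech_mean)),
    n_tech = sum(.data$n_tech),
    .groups = "drop"
  )
  fp <- dplyr::rename(fp, bulk = "target")
  fp <- dplyr::arrange(fp, .data$bulk, match(.data$feature_id, features))
  fp
}

#' Subtraction efficiency from a driver-pool hybridisation
#'
#' A subtracted library should be depleted of sequences shared with the
#' driver pool, so few printed features should hybridise when the driver
#' itself is labelled. Efficiency is the percentage of printed subtracted
#' features NOT detected by the driver target.
#'
#' @param driver_fingerprint Fingerprint tibble of a driver-pool target
#'   (columns `feature_id`, `value`), restricted to subtracted features.
#' @param threshold Detection threshold on the fingerprint value
#'   (default 7, the SNR detection threshold).
#' @return List: `n_detected`, `n_total`, `efficiency_percent` (exact),
#'   `efficiency_rounded` (half-up integer percent), `detected_ids`.
#' @export
subtraction_efficiency <- function(driver_fingerprint, threshold = 7) {
  n_total <- nrow(driver_fingerprint)
  if (n_total == 0) {
    abort("empty feature layout", class = "bsa_empty_layout_error")
  }
  detected <- !is.na(driver_fingerprint$value) &
    driver_fingerprint$value > threshold
  eff <- 100 * (n_total - sum(detected)) / n_total
  list(
    n_detected = sum(detected),
    n_total = n_total,
    efficiency_percent = eff,
    efficiency_rounded = as.integer(round_half_up(eff)),
    detected_ids = driver_fingerprint$feature_id[detected]
  )
}
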