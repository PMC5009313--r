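#' Pipeline configuration
#'
#' All tunable thresholds of the marker-discovery pipeline in one place.
#' Defaults are the emulated study's settings: SNR detection threshold 7
#' with a strict more-than-half technical-replicate rule, stepwise entry
#' and removal probabilities 0.05 / 0.10, Fisher's-ratio top-10, t-test
#' significance 0.05 with Levene gating at 0.05, and a 5 cM annotation
#' window.
#'
#' @param snr_threshold SNR detection threshold.
#' @param min_pass_fraction Strict fraction of technical replicates that
#'   must pass detection.
#' @param p_enter,p_remove,tolerance,max_steps,select_on,priors Stepwise
#'   DFA settings, see [dfa_config()].
#' @param fisher_k Fisher's-ratio top-k cut.
#' @param t_alpha t-test significance level for the marker criterion.
#' @param levene_alpha Levene gate for pooled-vs-Welch.
#' @param cm_window Annotation window in centimorgans.
#' @param seed Seed recorded with the run (the analysis itself is
#'   deterministic; the seed matters when the config drives simulation).
#' @return List of class `bsa_config`.
#' @export
bsa_config <- function(snr_threshold = 7, min_pass_fraction = 0.5,
                       p_enter = 0.05, p_remove = 0.10, tolerance = 1e-8,
                       max_steps = 50L, select_on = "all", priors = "equal",
                       fisher_k = 10, t_alpha = 0.05, levene_alpha = 0.05,
                       cm_window = 5, seed = NULL) {
  structure(list(
    snr_threshold = snr_threshold, min_pass_fraction = min_pass_fraction,
    dfa = dfa_config(p_enter = p_enter, p_remove = p_remove,
                     tolerance = tolerance, max_steps = max_steps,
                     select_on = select_on, priors = priors),
    fisher_k = fisher_k, t_alpha = t_alpha, levene_alpha = levene_alpha,
    cm_window = cm_window, seed = seed
  ), class = "bsa_config")
}

#' Run the full marker-discovery pipeline
#'
#' QC flags -> spike-in normalisation -> SNR detection filter ->
#' fingerprints -> per-feature statistics and stepwise DFA for every
#' DN-vs-SD comparison present -> three-way marker selection. The run is
#' deterministic given the input signals and configuration.
#'
#' @param signals Long signal tibble ([collect_signals()] or
#'   [simulate_bulk_hybridization()]`$signals`).
#' @param config A [bsa_config()].
#' @param sd_bulk Label of the short-day reference bulk (default "SD").
#' @param out_dir Optional directory; when given, all artifact tables are
#'   written there (QC report, fingerprints, statistics, DFA report, Venn
#'   partition, marker report, resolved config).
#' @return Object of class `bsa_run` with elements `qc`, `retained`,
#'   `fingerprints`, `stats`, `dfa` (named list of `bsa_dfa`), `report`
#'   (a `marker_report`) and `config`.
#' @export
run_bsa_pipeline <- function(signals, config = bsa_config(),
                             sd_bulk = "SD", out_dir = NULL) {
  signals <- apply_qc_flags(signals)
  signals <- spike_in_normalize(signals)
  qc <- snr_detection_filter(signals, config$snr_threshold,
                             config$min_pass_fraction)
  if (length(qc$retained) == 0) {
    abort("detection filter retained no features", class = "bsa_stage_error")
  }
  fingerprints <- build_fingerprints(signals, features = qc$retained)
  dn_bulks <- intersect(c("DN1", "DN2", "DN3"), unique(signals$target))
  if (length(dn_bulks) == 0 || !(sd_bulk %in% signals$target)) {
    abort("pipeline needs at least one DN bulk and the SD bulk",
          class = "bsa_stage_error")
  }
  stats <- dplyr::bind_rows(purrr::map(dn_bulks, function(b) {
    feature_stats(signals, b, sd_bulk, features = qc$retained,
                  alpha_levene = config$levene_alpha)
  }))
  dfa <- purrr::map(dn_bulks, function(b) {
    reciprocal_dfa(signals, b, sd_bulk, features = qc$retained,
                   config = config$dfa)
  })
  names(dfa) <- paste0(dn_bulks, "-", sd_bulk)
  report <- select_markers(dfa, stats, fisher_k = config$fisher_k,
                           t_alpha = config$t_alpha)
  run <- structure(list(qc = qc, retained = qc$retained,
                        fingerprints = fingerprints, stats = stats,
                        dfa = dfa, report = report, config = config),
                   class = "bsa_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.bsa_run <- function(x, ...) {
  cat("BSA marker-discovery run\n")
  cat("  features retained:", length(x$retained), "\n")
  cat("  comparisons:", paste(names(x$dfa), collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}

#' Write the machine-readable artifacts of a pipeline run
#'
#' @param run A `bsa_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$qc$detail, file.path(out_dir, "qc_report.tsv"),
                   progress = FALSE)
  write_fingerprint_table(run$fingerprints,
                          file.path(out_dir, "fingerprints.tsv"))
  readr::write_tsv(run$stats, file.path(out_dir, "feature_stats.tsv"),
                   progress = FALSE)
  dfa_report <- purrr::map(run$dfa, function(d) {
    list(comparison = d$comparison, selected = d$selected,
         lambda = d$lambda,
         training_accuracy = d$training_accuracy,
         test_accuracy = d$test_accuracy)
  })
  jsonlite::write_json(dfa_report, file.path(out_dir, "dfa_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  venn <- run$report$venn
  venn_json <- setNames(venn$regions$members, venn$regions$region)
  jsonlite::write_json(venn_json, file.path(out_dir, "venn.json"),
                       pretty = TRUE)
  if (nrow(run$report$markers) > 0) {
    readr::write_tsv(run$report$markers, file.path(out_dir, "markers.tsv"),
                     progress = FALSE)
  } else {
    readr::write_tsv(tibble::tibble(feature_id = character()),
                     file.path(out_dir, "markers.tsv"), progress = FALSE)
  }
  cfg <- run$config
  cfg_list <- list(snr_threshold = cfg$snr_threshold,
                   min_pass_fraction = cfg$min_pass_fraction,
                   p_enter = cfg$dfa$p_enter, p_remove = cfg$dfa$p_remove,
                   tolerance = cfg$dfa$tolerance,
                   max_steps = cfg$dfa$max_steps,
                   select_on = cfg$dfa$select_on, priors = cfg$dfa$priors,
                   fisher_k = cfg$fisher_k, t_alpha = cfg$t_alpha,
                   levene_alpha = cfg$levene_alpha,
                   cm_window = cfg$cm_window,
                   seed = cfg$seed)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
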