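#' Reference values from the strawberry day-neutrality experiment
#'
#' The package ships the published summary tables of the octoploid
#' strawberry day-neutrality bulked-segregant experiment it models, as
#' plain tibbles. They serve as worked-example inputs: the original slide
#' scans are not redistributed here, but the printed group statistics are
#' sufficient to reconstruct the univariate tests exactly and to verify the
#' three-way marker intersection.
#'
#' @return `ref_cross_counts()`: per-cross progeny counts by
#'   day-neutrality class (DN1 strong, DN2 intermediate, DN3 weak, SD
#'   short-day).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
ref_cross_counts <- function() {
  tibble::tribble(
    ~cross_id,                 ~cross_type, ~DN1, ~DN2, ~DN3, ~SD,
    "01-061-311 x Juliette",   "DN x SD",   0L,   6L,   6L,   10L,
    "01-061-311 x 05-069-63",  "DN x DN",   1L,   8L,   7L,   0L,
    "01-069-311 x 05-069-194", "DN x DN",   1L,   5L,   5L,   0L
  )
}

#' @rdname reference_tables
#' @return `ref_phenotype_records()`: the same counts expanded to one row
#'   per plant (plant ids synthesised as cross/class/index) for
#'   [assemble_bulks()].
#' @export
ref_phenotype_records <- function() {
  counts <- tidyr::pivot_longer(ref_cross_counts(), c("DN1", "DN2", "DN3", "SD"),
                                names_to = "class", values_to = "n")
  rows <- purrr::pmap(counts, function(cross_id, cross_type, class, n) {
    if (n == 0) return(NULL)
    tibble::tibble(
      plant_id = paste(gsub("[^0-9A-Za-z]+", "_", cross_id), class,
                       seq_len(n), sep = "."),
      cross_id = cross_id,
      flowering_score = match(class, c("DN1", "DN2", "DN3", "SD")),
      class = class
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname reference_tables
#' @return `ref_dfa_selected()`: the stepwise-DFA-selected feature sets and
#'   reported training/test classification percentages for the three bulk
#'   comparisons.
#' @export
ref_dfa_selected <- function() {
  tibble::tribble(
    ~comparison, ~features, ~training_accuracy, ~test_accuracy,
    "DN1-SD", list(c("FaP2E11", "FaP3F4", "FaP2D6", "FaP2B4", "FaP2D12",
                     "FaP2G4")), 100.0, 83.3,
    "DN2-SD", list(c("FaP2E2", "FaP3H2", "FaP3E5", "FaP1E10", "FaP3E7",
                     "FaP2E9")), 100.0, 66.7,
    "DN3-SD", list(c("FaP1A1", "FaP2A2", "FaP3D4", "FaP3B3", "FaP3B10",
                     "FaP2E9")), 100.0, 83.3
  ) |>
    dplyr::mutate(features = purrr::map(.data$features, 1))
}

#' @rdname reference_tables
#' @return `ref_fisher_top10()`: the per-comparison top-10 features by
#'   Fisher's ratio.
#' @export
ref_fisher_top10 <- function() {
  tibble::tibble(
    rank = rep(1:10, 3),
    comparison = rep(c("DN1-SD", "DN2-SD", "DN3-SD"), each = 10),
    feature_id = c(
      "FaP1G3", "FaP2G5", "FaP2E11", "FaP1B10", "FaP3F7",
      "FaP1B9", "FaP2E4", "FaP1G1", "FaP1C4", "FaP1H8",
      "FaP1A1", "FaP4A8", "FaP2D3", "FaP4D1", "FaP2F11",
      "FaP2G5", "FaP1G7", "FaP3B1", "FaP2C11", "FaP3F7",
      "FaP1A1", "FaP2G12", "FaP3F7", "FaP2G11", "FaP3A5",
      "FaP4B1", "FaP2D3", "FaP1C8", "FaP2F5", "FaP3G6"
    )
  )
}

#' @rdname reference_tables
#' @return `ref_marker_stats()`: group statistics (mean and SD of the
#'   normalised SNR over 2 biological x 6 technical replicates) and the
#'   reported t, df and significance tier for every DFA-selected feature in
#'   each comparison. `t_printed` is transcribed as published; its sign is
#'   not always consistent with the printed means (see the package
#'   vignette), so sign-insensitive comparisons should use `abs(t_printed)`.
#' @export
ref_marker_stats <- function() {
  tibble::tribble(
    ~comparison, ~feature_id, ~mean_dn, ~sd_dn, ~mean_sd, ~sd_sd,
      ~t_printed, ~df_printed, ~sig,
    "DN1-SD", "FaP2E11", 743.53, 252.08, 259.98, 148.78,  5.723, 22,   "**",
    "DN1-SD", "FaP3F4",  133.90,  71.34, 210.06, 191.96,  1.288, 22,   "ns",
    "DN1-SD", "FaP2D6",  188.96, 119.83, 337.52, 250.68,  1.852, 22,   "ns",
    "DN1-SD", "FaP2B4",   74.95,  53.71, 117.72,  89.99,  1.414, 22,   "ns",
    "DN1-SD", "FaP2D12", 223.23, 146.47, 433.96, 143.61, -3.559, 22,   "**",
    "DN1-SD", "FaP2G4",  161.45,  69.35, 105.77,  65.22, -2.026, 22,   "ns",
    "DN2-SD", "FaP2E2",   85.71,  48.94, 232.53, 172.45, -2.837, 12.8, "*",
    "DN2-SD", "FaP3H2",  545.45, 243.59, 368.65, 322.27, -1.516, 22,   "ns",
    "DN2-SD", "FaP3E5",  104.54,  41.97, 131.37, 108.95,  0.796, 22,   "ns",
    "DN2-SD", "FaP1E10", 200.32, 118.04, 179.75, 116.79, -0.429, 22,   "ns",
    "DN2-SD", "FaP3E7",  202.05,  85.17, 296.19, 232.35,  1.318, 22,   "ns",
    "DN2-SD", "FaP2E9",   40.82,  25.66,  67.17,  30.59,  2.287, 22,   "*",
    "DN3-SD", "FaP1A1",    0.27,   0.35, 713.71, 499.52, -4.948, 11.0, "**",
    "DN3-SD", "FaP2A2",  253.29, 117.27, 354.78, 287.26,  1.133, 14.6, "ns",
    "DN3-SD", "FaP3D4",  133.98,  82.77, 137.14,  70.63,  0.101, 22,   "ns",
    "DN3-SD", "FaP3B3",  227.30, 136.36, 300.66, 237.70, -0.927, 22,   "ns",
    "DN3-SD", "FaP3B10",  38.87,  18.90,  49.46,  23.85,  1.206, 22,   "ns",
    "DN3-SD", "FaP2E9",   46.73,  19.48,  67.17,  30.59,  1.953, 22,   "ns"
  )
}
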