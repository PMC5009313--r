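## Small in-code fixtures shared across test files.

toy_layout <- function(n_sub = 3) {
  tibble::tibble(
    feature_id = c(sprintf("FT%02d", seq_len(n_sub)), "NEG1", "SPIKE"),
    category = c(rep("subtracted", n_sub), "negative_control", "spike_in")
  )
}

write_toy_scan <- function(path, layout, signal = NULL, flags = 0L) {
  n <- nrow(layout)
  if (is.null(signal)) signal <- 100 + 10 * seq_len(n)
  readr::write_tsv(tibble::tibble(
    ID = layout$feature_id,
    `F635 Mean` = signal,
    `B635 Mean` = 50,
    `B635 SD` = 10,
    Flags = flags
  ), path, progress = FALSE)
  path
}

## Long signal tibble built directly (no files): `values` is a named list
## target -> list of per-bio-rep numeric vectors (tech replicates) for a
## single subtracted feature, with flat baselines for the other features.
toy_signals <- function(values, n_features = 4, spike_snr = 50,
                        feature = "FT01") {
  feats <- sprintf("FT%02d", seq_len(n_features))
  rows <- list()
  for (target in names(values)) {
    for (b in seq_along(values[[target]])) {
      v <- values[[target]][[b]]
      for (k in seq_along(v)) {
        hyb <- sprintf("%s_b%d_t%d", target, b, k)
        snr <- c(stats::setNames(rep(20, n_features), feats),
                 SPIKE = spike_snr)
        snr[feature] <- v[k]
        rows[[length(rows) + 1]] <- tibble::tibble(
          hybridization_id = hyb, target = target, bio_rep = b, tech_rep = k,
          feature_id = names(snr), snr = unname(snr),
          category = c(rep("subtracted", n_features), "spike_in"),
          flag = "good", masked = FALSE, mask_reason = NA_character_
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

## Random two-group case matrix with optional group shifts.
random_case_matrix <- function(n_per_group = 10, n_features = 4,
                               shift = rep(0, n_features), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(2 * n_per_group * n_features),
                2 * n_per_group, n_features,
                dimnames = list(NULL, sprintf("V%02d", seq_len(n_features))))
    X[seq_len(n_per_group), ] <-
      X[seq_len(n_per_group), ] + rep(shift, each = n_per_group)
    list(X = X, y = factor(rep(c("g1", "g2"), each = n_per_group)))
  })
}
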