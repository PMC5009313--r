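#' Feature categories printed on a subtracted diversity array
#'
#' The five feature classes recognised by the quality-control and
#' normalisation steps. Subtracted features carry the marker information;
#' positive, negative and printing controls monitor the hybridisation;
#' the spike-in control (an exogenous sequence with no homologue in the
#' target genome) anchors between-slide normalisation.
#'
#' @return Character vector of the five category labels.
#' @export
feature_categories <- function() {
  c("subtracted", "positive_control", "negative_control",
    "printing_control", "spike_in")
}

#' Read a feature-annotation (array layout) table
#'
#' The layout declares every printed feature once, with its category and
#' grid position. Feature order in the layout is the canonical order used
#' by every downstream table.
#'
#' @param path Tab-delimited file with columns `feature_id`, `category`
#'   and optionally `block`, `row`, `column`, `sequence_accession`.
#' @return A tibble with one row per printed feature.
#' @export
read_feature_layout <- function(path) {
  layout <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_layout(layout)
}

#' @rdname read_feature_layout
#' @param layout A data frame to validate as a layout.
#' @export
validate_feature_layout <- function(layout) {
  layout <- tibble::as_tibble(layout)
  req <- c("feature_id", "category")
  missing <- setdiff(req, names(layout))
  if (length(missing) > 0) {
    abort(paste0("layout is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bsa_format_error")
  }
  if (anyDuplicated(layout$feature_id)) {
    abort("duplicated feature_id in layout", class = "bsa_format_error")
  }
  bad <- setdiff(unique(layout$category), feature_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown feature category: ", paste(bad, collapse = ", ")),
          class = "bsa_format_error")
  }
  if (!any(layout$category == "spike_in")) {
    abort("layout must contain at least one spike_in feature for normalisation",
          class = "bsa_format_error")
  }
  layout
}

#' Column map for quantified array-scan tables
#'
#' Scan tables are tab-delimited exports of spot-quantification software.
#' The default profile matches GenePix-results-style headers; any export
#' with equivalent columns can be read by overriding individual entries.
#'
#' @param feature_id,signal_mean,background_mean,background_sd,flag Header
#'   names of the respective columns in the scan file.
#' @return Named character vector mapping logical fields to file headers.
#' @export
scan_column_map <- function(feature_id = "ID",
                            signal_mean = "F635 Mean",
                            background_mean = "B635 Mean",
                            background_sd = "B635 SD",
                            flag = "Flags") {
  c(feature_id = feature_id, signal_mean = signal_mean,
    background_mean = background_mean, background_sd = background_sd,
    flag = flag)
}

## Manual spot flags come from the quantification software in whatever
## vocabulary it uses; everything maps onto good / bad / empty.
## The numeric defaults are the GenePix user-flag conventions.
default_flag_map <- function() {
  list(good = c("0", "good", "ok", "100"),
       bad = c("-100", "bad"),
       empty = c("-75", "empty", "absent"))
}

normalise_flags <- function(flag, flag_map = default_flag_map()) {
  token <- tolower(trimws(as.character(flag)))
  out <- rep(NA_character_, length(token))
  for (lvl in names(flag_map)) out[token %in% flag_map[[lvl]]] <- lvl
  unknown <- is.na(out)
  if (any(unknown)) {
    ## Unrecognised nonzero tokens are conservatively treated as bad.
    out[unknown] <- ifelse(token[unknown] %in% c("", "na"), "good", "bad")
  }
  out
}

#' Read one quantified array-scan table
#'
#' Parses a tab-delimited spot-quantification export into one hybridisation's
#' spot measurements, keyed and ordered by the array layout.
#'
#' @param path Path to the tab-delimited scan file.
#' @param layout Feature layout (see [read_feature_layout()]); every feature
#'   in the file must be declared in the layout.
#' @param col_map Column map, see [scan_column_map()].
#' @param flag_map Flag vocabulary mapping tokens to good/bad/empty.
#' @return A tibble with columns `feature_id`, `signal_mean`,
#'   `background_mean`, `background_sd`, `flag`, ordered as the layout.
#' @export
read_scan_table <- function(path, layout, col_map = scan_column_map(),
                            flag_map = default_flag_map()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    abort(paste0("scan table ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bsa_format_error")
  }
  spots <- tibble::tibble(
    feature_id = as.character(raw[[col_map[["feature_id"]]]]),
    signal_mean = as.numeric(raw[[col_map[["signal_mean"]]]]),
    background_mean = as.numeric(raw[[col_map[["background_mean"]]]]),
    background_sd = as.numeric(raw[[col_map[["background_sd"]]]]),
    flag = normalise_flags(raw[[col_map[["flag"]]]], flag_map)
  )
  unknown <- setdiff(spots$feature_id, layout$feature_id)
  if (length(unknown) > 0) {
    abort(paste0("scan table contains feature(s) absent from layout: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "bsa_annotation_error")
  }
  if (any(spots$signal_mean < 0, na.rm = TRUE) ||
      any(spots$background_mean < 0, na.rm = TRUE)) {
    abort("negative signal or background mean in scan table",
          class = "bsa_value_error")
  }
  if (any(spots$background_sd < 0, na.rm = TRUE)) {
    abort("negative background SD in scan table", class = "bsa_value_error")
  }
  ## layout order is canonical
  spots[order(match(spots$feature_id, layout$feature_id)), ]
}

#' Read a sample sheet describing the hybridisations
#'
#' The sample sheet maps each hybridisation to its target (the DNA bulk or
#' pool labelled onto the slide), its biological replicate and technical
#' replicate indices, and the scan file holding its quantified spots.
#'
#' @param path CSV or TSV file with columns `hybridization_id`, `target`,
#'   `biological_replicate`, `technical_replicate`, `scan_file`.
#' @return Tibble of hybridisation descriptors.
#' @export
read_sample_sheet <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  sheet <- reader(path, show_col_types = FALSE, progress = FALSE)
  req <- c("hybridization_id", "target", "biological_replicate",
           "technical_replicate", "scan_file")
  missing <- setdiff(req, names(sheet))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bsa_format_error")
  }
  if (nrow(sheet) == 0) {
    warn("sample sheet is empty")
    return(tibble::as_tibble(sheet))
  }
  key <- paste(sheet$target, sheet$biological_replicate,
               sheet$technical_replicate, sep = "/")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (target, biological, technical) replicate key: ",
                 key[duplicated(key)][1]),
          class = "bsa_duplicate_replicate_error")
  }
  tibble::as_tibble(sheet)
}

#' Assemble a long signal table from a sample sheet and scan files
#'
#' Reads every scan file referenced by the sample sheet, computes the
#' signal-to-noise ratio of each spot, and returns the long per-cell table
#' that all downstream statistics consume.
#'
#' @param sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param layout Feature layout.
#' @param dir Directory against which relative `scan_file` paths resolve.
#' @inheritParams read_scan_table
#' @return A long tibble with one row per (hybridisation, feature):
#'   `hybridization_id`, `target`, `bio_rep`, `tech_rep`, `feature_id`,
#'   `category`, `snr`, `flag`, `masked`, `mask_reason`.
#' @export
collect_signals <- function(sheet, layout, dir = ".",
                            col_map = scan_column_map(),
                            flag_map = default_flag_map()) {
  rows <- purrr::pmap(sheet, function(hybridization_id, target,
                                      biological_replicate,
                                      technical_replicate, scan_file, ...) {
    path <- if (file.exists(scan_file)) scan_file else file.path(dir, scan_file)
    spots <- read_scan_table(path, layout, col_map, flag_map)
    tibble::tibble(
      hybridization_id = hybridization_id,
      target = target,
      bio_rep = as.integer(biological_replicate),
      tech_rep = as.integer(technical_replicate),
      feature_id = spots$feature_id,
      snr = compute_snr(spots$signal_mean, spots$background_mean,
                        spots$background_sd),
      flag = spots$flag
    )
  })
  signals <- dplyr::bind_rows(rows)
  signals <- dplyr::left_join(
    signals, dplyr::select(layout, "feature_id", "category"),
    by = "feature_id"
  )
  signals$masked <- FALSE
  signals$mask_reason <- NA_character_
  signals
}

#' Write / read a fingerprint matrix
#'
#' A fingerprint is one normalised value per retained feature per bulk.
#' The on-disk form is a tab-delimited matrix, rows = features (layout
#' order), columns = bulks, values printed at 12 significant digits so the
#' matrix round-trips losslessly through [read_fingerprint_table()].
#'
#' @param fingerprints Long tibble with columns `feature_id`, `bulk`,
#'   `value` (as produced by [build_fingerprints()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fingerprints, path) {
  by_bulk <- split(fingerprints$feature_id, fingerprints$bulk)
  ref <- by_bulk[[1]]
  same <- vapply(by_bulk, function(f) identical(sort(f), sort(ref)), logical(1))
  if (!all(same)) {
    abort("bulks do not share a common feature set",
          class = "bsa_alignment_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(fingerprints, "feature_id", "bulk", "value"),
    names_from = "bulk", values_from = "value"
  )
  out <- dplyr::mutate(wide, dplyr::across(
    -"feature_id", ~ formatC(.x, digits = 12, format = "g")
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_table
#' @export
read_fingerprint_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"feature_id", names_to = "bulk",
                              values_to = "value")
  dplyr::arrange(long, .data$bulk, match(.data$feature_id, wide$feature_id))
}
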