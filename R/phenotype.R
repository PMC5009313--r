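#' Flowering-score to day-neutrality class mapping
#'
#' Progeny are scored 1-4 for flowering response in midsummer: 1 = flower
#' formation on runners (strong day-neutral), 2 = two or more recently
#' emerged inflorescences (intermediate), 3 = fewer than two recently
#' emerged inflorescences (weak), 4 = no flowers or fruits (short-day).
#'
#' @param score Integer vector of flowering scores in 1..4.
#' @return Character vector of classes: DN1, DN2, DN3 or SD.
#' @export
score_to_class <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 1) || any(score > 4)) {
    abort("flowering score must be an integer in 1..4",
          class = "bsa_domain_error")
  }
  c("DN1", "DN2", "DN3", "SD")[as.integer(score)]
}

#' Assemble DNA bulks from classified phenotype records
#'
#' Groups classified progeny into one bulk per day-neutrality class. Bulks
#' are metadata: the actual DNA pooling happens at the bench, but bulk
#' membership drives the simulator's mean allele dosage and documents the
#' bulked-segregant design. A bulk smaller than `min_recommended` plants
#' (default 10, the usual BSA recommendation) gets a warning recorded, since
#' small bulks poorly average out unlinked alleles.
#'
#' @param records Tibble with columns `plant_id`, `cross_id` and either
#'   `class` or `flowering_score` (mapped via [score_to_class()]).
#' @param min_recommended Minimum recommended bulk size (default 10).
#' @return List with `bulks` (tibble: `bulk_id`, `size`, `members`
#'   (list-column), `warning`), `counts` (cross x class count table) and
#'   `n_total`.
#' @export
assemble_bulks <- function(records, min_recommended = 10) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    warn("no phenotype records: empty bulk set")
    return(list(bulks = tibble::tibble(bulk_id = character(),
                                       size = integer(),
                                       members = list(),
                                       warning = character()),
                counts = tibble::tibble(), n_total = 0L))
  }
  if (!"class" %in% names(records)) {
    records$class <- score_to_class(records$flowering_score)
  }
  counts <- dplyr::count(records, .data$cross_id, .data$class)
  counts <- tidyr::pivot_wider(counts, names_from = "class",
                               values_from = "n", values_fill = 0L)
  bulks <- dplyr::summarise(
    dplyr::group_by(records, bulk_id = .data$class),
    size = dplyr::n(),
    members = list(.data$plant_id),
    .groups = "drop"
  )
  bulks$warning <- ifelse(
    bulks$size < min_recommended,
    paste0("bulk size ", bulks$size, " below recommended minimum of ",
           min_recommended),
    NA_character_
  )
  for (w in bulks$warning[!is.na(bulks$warning)]) {
    warn(paste0(bulks$bulk_id[match(w, bulks$warning)], ": ", w))
  }
  list(bulks = dplyr::arrange(bulks, .data$bulk_id),
       counts = counts,
       n_total = nrow(records))
}
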