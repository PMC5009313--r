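#' Convert a genetic distance to a physical window
#'
#' Under the simplifying assumption that a chromosome spans 100 cM of
#' genetic distance uniformly, a window of `cM` centimorgans corresponds to
#' `cM/100` of the chromosome's physical length. This is a coarse
#' approximation (recombination is not uniform along real chromosomes) but
#' gives a defensible search radius around a marker when no genetic map is
#' available.
#'
#' @param cM Genetic distance in centimorgans (>= 0).
#' @param chromosome_length_bp Physical length of the chromosome in bp.
#' @return Window size in base pairs (rounded half-up to integer).
#' @export
cm_to_bp <- function(cM, chromosome_length_bp) {
  stopifnot(cM >= 0, chromosome_length_bp > 0)
  if (any(cM > 100)) {
    warn("genetic distance exceeds the assumed 100 cM chromosome length")
  }
  round_half_up(cM / 100 * chromosome_length_bp)
}

#' Read gene models from a GFF3 file
#'
#' Thin wrapper over [ape::read.gff()] keeping gene-type records and
#' extracting a gene id from the `ID=` (or `Name=`) attribute.
#'
#' @param path GFF3 file.
#' @param feature_type GFF3 `type` value to keep (default `"gene"`).
#' @return Tibble: `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == feature_type, , drop = FALSE]
  id <- ifelse(grepl("ID=", gff$attributes),
               sub(".*ID=([^;]+).*", "\\1", gff$attributes),
               ifelse(grepl("Name=", gff$attributes),
                      sub(".*Name=([^;]+).*", "\\1", gff$attributes),
                      NA_character_))
  tibble::tibble(gene_id = id,
                 chromosome = as.character(gff$seqid),
                 start = gff$start, end = gff$end,
                 strand = as.character(gff$strand))
}

#' Genes within a physical window of a marker locus
#'
#' Returns the genes whose nearest boundary lies within `window_bp` of the
#' marker interval, with a signed boundary-to-boundary distance:
#' positive when the gene lies downstream of the marker (increasing
#' coordinates), negative upstream, and zero when the intervals overlap.
#' Coordinates are 1-based inclusive (GFF3 convention). Results are sorted
#' by absolute distance, ties by gene id.
#'
#' @param marker List or one-row data frame with `chromosome`, `start`,
#'   `end`.
#' @param genes Gene tibble from [read_gene_annotation()].
#' @param window_bp Window size in bp (see [cm_to_bp()]).
#' @return Tibble: `gene_id`, `start`, `end`, `distance`.
#' @export
genes_within_window <- function(marker, genes, window_bp) {
  stopifnot(window_bp >= 0, marker$start >= 1, marker$start <= marker$end)
  on_chrom <- genes[genes$chromosome == marker$chromosome, , drop = FALSE]
  if (nrow(on_chrom) == 0) {
    warn(paste0("no genes on chromosome ", marker$chromosome))
    return(tibble::tibble(gene_id = character(), start = integer(),
                          end = integer(), distance = numeric()))
  }
  distance <- dplyr::case_when(
    on_chrom$start > marker$end ~ on_chrom$start - marker$end,
    on_chrom$end < marker$start ~ on_chrom$end - marker$start,
    .default = 0
  )
  hit <- abs(distance) <= window_bp
  out <- tibble::tibble(gene_id = on_chrom$gene_id,
                        start = on_chrom$start, end = on_chrom$end,
                        distance = distance)[hit, ]
  dplyr::arrange(out, abs(.data$distance), .data$gene_id)
}

#' Annotate markers with nearby genes
#'
#' Convenience wrapper applying [cm_to_bp()] and [genes_within_window()] to
#' a table of marker loci.
#'
#' @param markers Tibble with `feature_id`, `chromosome`, `start`, `end`.
#' @param genes Gene tibble.
#' @param chromosome_lengths Tibble with `chromosome`,
#'   `length_bp`.
#' @param cM Genetic window half-width in centimorgans (default 5).
#' @return Tibble of (marker, gene, distance) rows.
#' @export
annotate_markers <- function(markers, genes, chromosome_lengths, cM = 5) {
  rows <- purrr::pmap(markers, function(feature_id, chromosome, start, end,
                                        ...) {
    len <- chromosome_lengths$length_bp[
      chromosome_lengths$chromosome == chromosome]
    if (length(len) == 0) {
      warn(paste0("no length for chromosome ", chromosome))
      return(NULL)
    }
    win <- cm_to_bp(cM, len)
    hits <- genes_within_window(
      list(chromosome = chromosome, start = start, end = end), genes, win)
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(feature_id = feature_id, window_bp = win, hits)
  })
  dplyr::bind_rows(rows)
}
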