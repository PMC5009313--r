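#' Top-k features by Fisher's ratio
#'
#' Ranks features of each comparison by descending Fisher's ratio and keeps
#' the top `k`. A tie at rank k is broken by the lexicographically smaller
#' feature id, making the cut deterministic.
#'
#' @param stats Per-feature statistics tibble from [feature_stats()] (or
#'   any tibble with `feature_id`, `comparison`, `fisher_ratio`).
#' @param k Number of features to keep per comparison (default 10).
#' @return List with `ranked` (tibble: comparison, rank, feature_id,
#'   fisher_ratio) and `union` (character vector over comparisons).
#' @export
fisher_top_k <- function(stats, k = 10) {
  if (any(!is.finite(stats$fisher_ratio))) {
    abort("non-finite Fisher's ratio", class = "bsa_value_error")
  }
  ranked <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(stats, .data$comparison),
      dplyr::desc(.data$fisher_ratio), .data$feature_id,
      .by_group = TRUE
    ),
    n = k
  )
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number())
  ranked <- dplyr::ungroup(ranked)
  n_feat <- dplyr::count(stats, .data$comparison)
  if (any(n_feat$n < k)) {
    warn(paste0("fewer than k = ", k, " features in some comparison; ",
                "all features kept"))
  }
  list(ranked = dplyr::select(ranked, "comparison", "rank", "feature_id",
                              "fisher_ratio"),
       union = sort(unique(ranked$feature_id)))
}

#' Features significant by t-test
#'
#' @param stats Per-feature statistics tibble with `feature_id` and `p`
#'   (any number of comparisons).
#' @param alpha Significance level (default 0.05).
#' @return Sorted character vector of features with `p < alpha` in any
#'   comparison.
#' @export
significant_by_ttest <- function(stats, alpha = 0.05) {
  sort(unique(stats$feature_id[stats$p < alpha]))
}

#' Three-way Venn partition
#'
#' Partitions the union of three feature sets into the seven disjoint Venn
#' regions. Membership is by unique feature id (set semantics): a feature
#' selected in several comparisons counts once.
#'
#' @param A,B,C Character vectors: typically the DFA-selected union, the
#'   Fisher top-k union and the t-test-significant set.
#' @param labels Names of the three sets for reporting.
#' @return Object of class `bsa_venn`: tibble `regions` with `region`
#'   (e.g. "A&B&C"), `n`, `members` (list-column), plus the input sets.
#' @export
venn3_partition <- function(A, B, C, labels = c("DFA", "Fisher", "t-test")) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  C <- unique(as.character(C))
  u <- sort(unique(c(A, B, C)))
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  key <- paste0(ifelse(inA, "A", ""), ifelse(inB, "B", ""),
                ifelse(inC, "C", ""))
  all_regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  regions <- purrr::map(all_regions, function(r) {
    members <- sort(u[key == r])
    tibble::tibble(region = r, n = length(members), members = list(members))
  })
  structure(list(regions = dplyr::bind_rows(regions),
                 sets = list(A = sort(A), B = sort(B), C = sort(C)),
                 labels = labels),
            class = "bsa_venn")
}

#' @rdname venn3_partition
#' @param venn A `bsa_venn`.
#' @param region Region key: any of "A", "B", "C", "AB", "AC", "BC", "ABC".
#' @return For `venn_region`: the member feature ids of that region.
#' @export
venn_region <- function(venn, region) {
  stopifnot(inherits(venn, "bsa_venn"))
  venn$regions$members[[match(region, venn$regions$region)]]
}

#' @export
print.bsa_venn <- function(x, ...) {
  cat("Three-way Venn partition (", paste(x$labels, collapse = " / "),
      ")\n", sep = "")
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    cat(sprintf("  %-4s n=%2d  %s\n", r$region, r$n,
                paste(r$members[[1]], collapse = ", ")))
  }
  invisible(x)
}

#' Combine the three selection criteria into a marker report
#'
#' Assembles the three-way intersection of (A) the union of stepwise-DFA
#' feature sets over comparisons, (B) the union of per-comparison Fisher's
#' ratio top-k lists and (C) the t-test-significant features. Features in
#' the triple intersection are the putative markers; each marker's
#' direction of association (DN or SD) is read off the sign of the group
#' mean difference in the comparison where it is most significant.
#'
#' @param dfa_results List of `bsa_dfa` objects (one per comparison).
#' @param stats Combined per-feature statistics tibble over the same
#'   comparisons ([feature_stats()] rows bound together).
#' @param fisher_k Top-k cut for the Fisher's ratio criterion (default 10).
#' @param t_alpha Significance level for the t-test criterion
#'   (default 0.05).
#' @return Object of class `marker_report`: `venn` (a `bsa_venn`),
#'   `markers` (tibble: feature_id, association, comparisons, p_min),
#'   `evidence` (per feature per criterion), and the criterion sets.
#' @export
select_markers <- function(dfa_results, stats, fisher_k = 10,
                           t_alpha = 0.05) {
  if (nrow(stats) == 0) {
    warn("empty retained feature set: empty marker report")
    return(structure(list(venn = venn3_partition(character(), character(),
                                                 character()),
                          markers = tibble::tibble(),
                          evidence = tibble::tibble()),
                     class = "marker_report"))
  }
  A <- sort(unique(unlist(purrr::map(dfa_results, "selected"))))
  top <- fisher_top_k(stats, k = fisher_k)
  B <- top$union
  C <- significant_by_ttest(stats, alpha = t_alpha)
  venn <- venn3_partition(A, B, C)
  marker_ids <- venn_region(venn, "ABC")
  markers <- purrr::map(marker_ids, function(f) {
    rows <- stats[stats$feature_id == f, ]
    best <- rows[which.min(rows$p), ]
    tibble::tibble(
      feature_id = f,
      ## higher mean in the DN bulk means the sequence is enriched in the
      ## day-neutral pool, i.e. DN-associated
      association = if (best$mean_dn > best$mean_sd) "DN" else "SD",
      best_comparison = best$comparison,
      p_min = best$p
    )
  })
  ids <- sort(unique(c(A, B, C)))
  evidence <- tibble::tibble(
    feature_id = ids,
    dfa = ids %in% A,
    fisher_top_k = ids %in% B,
    t_significant = ids %in% C
  )
  structure(list(venn = venn,
                 markers = dplyr::bind_rows(markers),
                 evidence = evidence,
                 sets = list(A = A, B = B, C = C),
                 fisher_ranked = top$ranked),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Putative markers (all three criteria):",
      if (nrow(x$markers)) paste(x$markers$feature_id, collapse = ", ")
      else "(none)", "\n")
  print(x$venn)
  invisible(x)
}
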