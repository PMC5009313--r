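#' Plot a three-way Venn partition
#'
#' Draws the classic three-circle diagram with region counts; member ids
#' are shown for the (usually small) intersection regions.
#'
#' @param object A `bsa_venn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_venn
#' @export
autoplot.bsa_venn <- function(object, ...) {
  circle <- function(cx, cy, r, n = 120) {
    t <- seq(0, 2 * pi, length.out = n)
    tibble::tibble(x = cx + r * cos(t), y = cy + r * sin(t))
  }
  centers <- tibble::tibble(
    set = c("A", "B", "C"),
    label = object$labels,
    cx = c(-0.6, 0.6, 0), cy = c(0.4, 0.4, -0.6)
  )
  circles <- dplyr::bind_rows(purrr::pmap(centers, function(set, label, cx,
                                                            cy) {
    dplyr::mutate(circle(cx, cy, 1.05), set = set)
  }))
  region_pos <- tibble::tibble(
    region = c("A", "B", "C", "AB", "AC", "BC", "ABC"),
    x = c(-1.05, 1.05, 0, 0, -0.62, 0.62, 0),
    y = c(0.7, 0.7, -1.15, 0.65, -0.25, -0.25, 0.12)
  )
  counts <- dplyr::left_join(region_pos, object$regions, by = "region")
  labels <- dplyr::mutate(
    counts,
    text = purrr::map2_chr(.data$n, .data$members, function(n, m) {
      if (n > 0 && n <= 3) paste0(n, "\n", paste(m, collapse = "\n"))
      else as.character(n)
    })
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(.data$x, .data$y, colour = .data$set),
                       linewidth = 0.8) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$x, .data$y, label = .data$text),
                       size = 3) +
    ggplot2::geom_text(data = centers,
                       ggplot2::aes(.data$cx, .data$cy + 1.25,
                                    label = .data$label, colour = .data$set),
                       fontface = "bold") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the Wilks' lambda trace of a stepwise DFA
#'
#' @param object A `bsa_dfa`.
#' @param ... Unused.
#' @return A ggplot object showing lambda after each stepwise action.
#' @method autoplot bsa_dfa
#' @export
autoplot.bsa_dfa <- function(object, ...) {
  tr <- object$trace
  if (nrow(tr) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no features entered") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(tr, ggplot2::aes(.data$step, .data$lambda)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = paste("Stepwise DFA:", object$comparison),
                  x = "step", y = "Wilks' lambda") +
    ggplot2::theme_minimal()
}

#' Fingerprint profile plot
#'
#' Per-bulk fingerprint values for a chosen set of features, on a log
#' scale (microarray intensities are positive and multiplicative).
#'
#' @param fingerprints Long fingerprint tibble from [build_fingerprints()].
#' @param features Features to show (default: 20 with the largest
#'   between-bulk spread).
#' @return A ggplot object.
#' @export
plot_fingerprints <- function(fingerprints, features = NULL) {
  if (is.null(features)) {
    spread <- dplyr::summarise(
      dplyr::group_by(fingerprints, .data$feature_id),
      spread = max(.data$value, na.rm = TRUE) -
        min(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
    features <- head(
      spread$feature_id[order(spread$spread, decreasing = TRUE)], 20)
  }
  sub <- dplyr::filter(fingerprints, .data$feature_id %in% .env$features)
  ggplot2::ggplot(sub, ggplot2::aes(.data$bulk, .data$value,
                                    group = .data$feature_id,
                                    colour = .data$feature_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "bulk", y = "fingerprint (normalised SNR)") +
    ggplot2::theme_minimal()
}
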