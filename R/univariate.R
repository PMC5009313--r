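#' Two-group summary statistics for one feature
#'
#' Mean, sample variance (n - 1 denominator) and standard deviation of a
#' group's normalised SNR values — the M, V and s entering Fisher's ratio
#' and the t-tests.
#'
#' @param values Numeric vector, at least 2 finite values.
#' @return List with `n`, `M`, `V`, `s`.
#' @export
group_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("need at least 2 finite values for group statistics",
          class = "bsa_insufficient_data_error")
  }
  v <- stats::var(values)
  list(n = length(values), M = mean(values), V = v, s = sqrt(v))
}

#' Fisher's ratio of two groups
#'
#' A univariate two-class separability score: the squared mean difference
#' over the sum of the group variances, `(M1 - M2)^2 / (V1 + V2)`.
#' Symmetric in group order; zero when the means coincide.
#'
#' @param g1,g2 Group summaries from [group_stats()], or numeric vectors
#'   (which are summarised first).
#' @return Nonnegative scalar.
#' @export
fisher_ratio <- function(g1, g2) {
  if (is.numeric(g1)) g1 <- group_stats(g1)
  if (is.numeric(g2)) g2 <- group_stats(g2)
  num <- (g1$M - g2$M)^2
  den <- g1$V + g2$V
  if (den == 0) {
    if (num == 0) return(0)
    abort("zero variance in both groups with distinct means",
          class = "bsa_degenerate_variance_error")
  }
  num / den
}

#' Levene's test for equality of variances (two groups, mean-centred)
#'
#' One-way ANOVA F-test on the absolute deviations of each value from its
#' group mean — the classical mean-centred Levene statistic. Used to decide
#' between the pooled and Welch t-test variants.
#'
#' @param values1,values2 Numeric vectors, at least 2 values each.
#' @return Two-sided p-value of the Levene F statistic.
#' @export
levene_test <- function(values1, values2) {
  if (length(values1) < 2 || length(values2) < 2) {
    abort("need at least 2 values per group for Levene's test",
          class = "bsa_insufficient_data_error")
  }
  d <- c(abs(values1 - mean(values1)), abs(values2 - mean(values2)))
  g <- factor(rep(c("a", "b"), c(length(values1), length(values2))))
  gm <- tapply(d, g, mean)
  if (gm[1] == gm[2]) return(1)  # zero between-group spread difference
  if (all(d == d[1])) {
    abort("zero total deviation: Levene statistic undefined",
          class = "bsa_degenerate_variance_error")
  }
  res <- stats::oneway.test(d ~ g, var.equal = TRUE)
  unname(res$p.value)
}

#' Independent two-sample t-test with Levene-gated variant choice
#'
#' Compares the day-neutral and short-day bulk values for one feature.
#' Orientation is DN minus SD. With `variant = "auto"` the pooled-variance
#' test (df = n1 + n2 - 2) is used when Levene's test does not reject
#' variance equality at `alpha_levene`, otherwise the Welch test with
#' Satterthwaite degrees of freedom.
#'
#' @param values_dn,values_sd Numeric vectors of per-replicate normalised
#'   SNR (DN bulk and SD bulk).
#' @param variant `"auto"` (default), `"pooled"` or `"welch"`.
#' @param alpha_levene Significance level gating the variant choice.
#' @return List with `t`, `df` (exact), `df_rounded` (1 decimal, half-up),
#'   `p` (two-sided), `variant` (resolved), `levene_p`, and the group
#'   summaries `g1`, `g2`.
#' @export
independent_t_test <- function(values_dn, values_sd,
                               variant = c("auto", "pooled", "welch"),
                               alpha_levene = 0.05) {
  variant <- match.arg(variant)
  g1 <- group_stats(values_dn)
  g2 <- group_stats(values_sd)
  levene_p <- NA_real_
  if (variant == "auto") {
    levene_p <- levene_test(values_dn, values_sd)
    variant <- if (levene_p < alpha_levene) "welch" else "pooled"
  }
  if (g1$V == 0 && g2$V == 0) {
    ## degenerate spread: identical means give the null t = 0, different
    ## means an infinite-t sentinel
    df <- g1$n + g2$n - 2
    if (g1$M == g2$M) {
      t <- 0; p <- 1
    } else {
      t <- sign(g1$M - g2$M) * Inf; p <- 0
    }
  } else {
    res <- stats::t.test(values_dn, values_sd,
                         var.equal = (variant == "pooled"))
    t <- unname(res$statistic)
    df <- unname(res$parameter)
    p <- res$p.value
  }
  list(t = t, df = df, df_rounded = round_half_up(df, 1), p = p,
       variant = variant, levene_p = levene_p, g1 = g1, g2 = g2)
}

#' Per-feature two-group statistics table
#'
#' Runs [group_stats()], [fisher_ratio()] and [independent_t_test()] for
#' every feature of one bulk comparison, returning the tidy per-feature
#' statistics table that feeds marker selection.
#'
#' @param signals Normalised long signal tibble (after QC).
#' @param group_dn,group_sd Target labels of the two bulks (orientation is
#'   `group_dn` minus `group_sd`).
#' @param features Features to test; defaults to all subtracted features.
#' @inheritParams independent_t_test
#' @return Tibble: `feature_id`, `comparison`, `n_dn`, `mean_dn`, `sd_dn`,
#'   `n_sd`, `mean_sd`, `sd_sd`, `fisher_ratio`, `t`, `df`, `df_rounded`,
#'   `p`, `variant`, `levene_p`, `sig_tier` ("**" p<0.01, "*" p<0.05, "ns").
#' @export
feature_stats <- function(signals, group_dn, group_sd = "SD",
                          features = NULL,
                          variant = "auto", alpha_levene = 0.05) {
  if (is.null(features)) {
    features <- unique(signals$feature_id[signals$category == "subtracted"])
  }
  sub <- dplyr::filter(signals, !.data$masked,
                       .data$feature_id %in% .env$features,
                       .data$target %in% c(group_dn, group_sd))
  split_vals <- split(
    sub[c("snr", "target")],
    factor(sub$feature_id, levels = features)
  )
  rows <- purrr::map(features, function(f) {
    cell <- split_vals[[f]]
    x <- cell$snr[cell$target == group_dn]
    y <- cell$snr[cell$target == group_sd]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tt <- independent_t_test(x, y, variant = variant,
                             alpha_levene = alpha_levene)
    tibble::tibble(
      feature_id = f,
      comparison = paste0(group_dn, "-", group_sd),
      n_dn = tt$g1$n, mean_dn = tt$g1$M, sd_dn = tt$g1$s,
      n_sd = tt$g2$n, mean_sd = tt$g2$M, sd_sd = tt$g2$s,
      fisher_ratio = fisher_ratio(tt$g1, tt$g2),
      t = tt$t, df = tt$df, df_rounded = tt$df_rounded, p = tt$p,
      variant = tt$variant, levene_p = tt$levene_p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$sig_tier <- dplyr::case_when(
    out$p < 0.01 ~ "**",
    out$p < 0.05 ~ "*",
    .default = "ns"
  )
  out
}
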