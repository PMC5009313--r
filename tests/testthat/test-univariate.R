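test_that("group statistics use the n-1 variance", {
  g <- group_stats(c(1, 2, 3))
  expect_equal(g$M, 2)
  expect_equal(g$V, 1)
  expect_equal(g$s, 1)
  expect_equal(group_stats(rep(4, 5))$V, 0)
  expect_error(group_stats(2), class = "bsa_insufficient_data_error")
})

test_that("exact-moment samples reproduce published group statistics", {
  x <- exact_moment_sample(12, 743.53, 252.08, seed = 7)
  expect_equal(mean(x), 743.53, tolerance = 1e-9)
  expect_equal(sd(x), 252.08, tolerance = 1e-9)
})

test_that("Fisher's ratio matches hand-evaluated cases", {
  expect_equal(fisher_ratio(group_stats(c(1, 2, 3)),
                            group_stats(c(0, 2, 4))), 0)
  expect_equal(fisher_ratio(list(M = 3, V = 1), list(M = 1, V = 1)), 2)
  ## published group statistics of the strongest day-neutrality marker
  g1 <- list(M = 743.53, V = 252.08^2)
  g2 <- list(M = 259.98, V = 148.78^2)
  expect_equal(fisher_ratio(g1, g2), 2.729, tolerance = 1e-3)
  ## symmetric in group order
  expect_equal(fisher_ratio(g1, g2), fisher_ratio(g2, g1))
  expect_error(fisher_ratio(list(M = 1, V = 0), list(M = 2, V = 0)),
               class = "bsa_degenerate_variance_error")
})

test_that("Levene's test agrees with the reference implementation", {
  skip_if_not_installed("car")
  withr::with_seed(42, {
    for (i in 1:5) {
      x <- rnorm(12, sd = sample(1:5, 1))
      y <- rnorm(12, sd = sample(1:5, 1))
      ours <- levene_test(x, y)
      ref <- car::leveneTest(c(x, y),
                             factor(rep(c("a", "b"), each = 12)),
                             center = "mean")[["Pr(>F)"]][1]
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  })
})

test_that("Levene's test separates clearly unequal variances", {
  withr::with_seed(99, {
    x <- rnorm(50, sd = 1)
    y <- rnorm(50, sd = 5)
  })
  expect_lt(levene_test(x, y), 0.01)
  expect_equal(levene_test(x, y), levene_test(y, x))
  expect_equal(levene_test(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("t-test reproduces published statistics from exact moments", {
  fx <- marker_stats_fixture(seed = 1)
  res <- marker_stats_tests(fx)
  ## every row: |t| to 3 decimals against the printed value
  expect_equal(abs(res$t), abs(fx$t_printed), tolerance = 1.1e-3)
  ## pooled rows have df exactly 22; Welch rows match to 0.1 after rounding
  pooled <- fx$variant == "pooled"
  expect_true(all(res$df[pooled] == 22))
  expect_true(all(abs(res$df_rounded[!pooled] - fx$df_printed[!pooled])
                  <= 0.1))
  ## orientation DN - SD: sign follows the mean difference
  expect_equal(sign(res$t), sign(res$mean_dn - res$mean_sd))
})

test_that("degenerate t-test inputs follow the documented conventions", {
  same <- independent_t_test(rep(2, 5), rep(2, 5), variant = "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- independent_t_test(rep(2, 5), rep(3, 5), variant = "pooled")
  expect_true(is.infinite(sep$t) && sep$t < 0)
  expect_equal(sep$p, 0)
  expect_error(independent_t_test(1, c(1, 2)),
               class = "bsa_insufficient_data_error")
})

test_that("Welch df lies between min(n)-1 and n1+n2-2", {
  withr::with_seed(3, {
    for (i in 1:20) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      x <- rnorm(n1, sd = runif(1, 0.5, 4))
      y <- rnorm(n2, sd = runif(1, 0.5, 4))
      tt <- independent_t_test(x, y, variant = "welch")
      expect_gte(tt$df, min(n1, n2) - 1 - 1e-9)
      expect_lte(tt$df, n1 + n2 - 2 + 1e-9)
    }
  })
})

test_that("exchanging groups flips t and preserves Fisher's ratio", {
  withr::with_seed(8, {
    x <- rnorm(12, 5); y <- rnorm(12, 3)
  })
  a <- independent_t_test(x, y, variant = "pooled")
  b <- independent_t_test(y, x, variant = "pooled")
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(fisher_ratio(x, y), fisher_ratio(y, x))
})

test_that("feature_stats assembles the per-feature table", {
  sig <- toy_signals(list(DN1 = list(c(10, 12, 14), c(11, 13, 15)),
                          SD = list(c(4, 5, 6), c(5, 6, 7))),
                     n_features = 2)
  st <- feature_stats(sig, "DN1", "SD")
  expect_equal(nrow(st), 2)
  row <- st[st$feature_id == "FT01", ]
  expect_equal(row$n_dn, 6)
  expect_gt(row$t, 0)
  expect_equal(row$comparison, "DN1-SD")
  ## FT02 is flat at 20 in both bulks -> t = 0, p = 1
  expect_equal(st$p[st$feature_id == "FT02"], 1)
})
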