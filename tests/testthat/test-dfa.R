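test_that("Wilks' lambda matches hand-computed scatter ratios", {
  X1 <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "a"))
  y <- factor(c("g1", "g1", "g2", "g2"))
  expect_equal(wilks_lambda(X1, y, "a"), 0.2)  # SSW/SST = 1/5
  ## equal group means: no between-group scatter
  X2 <- matrix(c(1, 3, 2, 2), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(wilks_lambda(X2, y, "a"), 1)
  ## zero within-group variance, distinct means
  X3 <- matrix(c(1, 1, 3, 3), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(wilks_lambda(X3, y, "a"), 0)
  ## constant feature: total scatter singular
  X4 <- matrix(rep(2, 4), ncol = 1, dimnames = list(NULL, "a"))
  expect_error(wilks_lambda(X4, y, "a"), class = "bsa_degenerate_data_error")
})

test_that("partial F at first entry equals the squared pooled t", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "a"))
  y <- factor(c("g1", "g1", "g2", "g2"))
  pf <- partial_f(X, y, character(0), "a", mode = "enter")
  expect_equal(pf$F, 8)  # (4-2) * (1/0.2 - 1)
  tt <- independent_t_test(c(1, 2), c(3, 4), variant = "pooled")
  expect_equal(pf$F, tt$t^2, tolerance = 1e-12)
})

test_that("single-feature F-to-enter equals squared pooled t (property)", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(3:10, 1)
      x <- rnorm(n); y <- rnorm(n, mean = runif(1, 0, 2))
      X <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "f"))
      grp <- factor(rep(c("a", "b"), each = n))
      pf <- partial_f(X, grp, character(0), "f", mode = "enter")
      tt <- independent_t_test(x, y, variant = "pooled")
      expect_equal(pf$F, tt$t^2, tolerance = 1e-9)
      expect_equal(pf$p, tt$p, tolerance = 1e-9)
    }
  })
})

test_that("a candidate orthogonal to the group difference has F near 0", {
  ## b has equal group means and is within-group orthogonal to a
  X <- cbind(a = c(1, 2, 3, 10, 11, 12), b = c(1, -2, 1, 1, -2, 1))
  y <- factor(rep(c("g1", "g2"), each = 3))
  pf <- partial_f(X, y, "a", "b", mode = "enter")
  expect_equal(pf$F, 0, tolerance = 1e-6)
  expect_gt(pf$p, 0.999)
})

test_that("stepwise enters a perfectly separating feature first", {
  cm <- random_case_matrix(8, 5, shift = c(0, 0, 8, 0, 0), seed = 2)
  sel <- stepwise_select(cm$X, cm$y)
  expect_equal(sel$selected[1], "V03")
})

test_that("a collinear copy of an entered feature is never entered", {
  cm <- random_case_matrix(8, 3, shift = c(6, 0, 0), seed = 3)
  X <- cbind(cm$X, V01copy = cm$X[, "V01"])
  sel <- stepwise_select(X, cm$y)
  expect_true("V01" %in% sel$selected)
  expect_false("V01copy" %in% sel$selected)
})

test_that("pure-noise selections are empty at the stepwise false-entry rate", {
  nonempty <- vapply(1:100, function(s) {
    cm <- random_case_matrix(12, 5, seed = 1000 + s)
    length(stepwise_select(cm$X, cm$y)$selected) > 0
  }, logical(1))
  ## P(any of 5 independent nulls enters) = 1 - 0.95^5 ~ 0.23
  expect_gt(mean(nonempty), 0.08)
  expect_lt(mean(nonempty), 0.45)
})

test_that("first entry matches the exhaustive minimum-lambda feature", {
  withr::with_seed(31, {
    for (i in 1:20) {
      m <- sample(2:6, 1)
      n <- sample(4:10, 1)
      shift <- runif(m, 0, 1.5)
      cm <- random_case_matrix(n, m, shift = shift,
                               seed = sample.int(1e6, 1))
      sel <- stepwise_select(cm$X, cm$y)
      lambdas <- vapply(colnames(cm$X), function(f)
        wilks_lambda(cm$X, cm$y, f), numeric(1))
      if (length(sel$selected) > 0) {
        expect_equal(sel$selected[1], names(which.min(lambdas)))
      } else {
        ## nothing entered: no single feature reaches the entry threshold
        ps <- vapply(colnames(cm$X), function(f)
          partial_f(cm$X, cm$y, character(0), f, "enter")$p, numeric(1))
        expect_gte(min(ps), 0.05)
      }
    }
  })
})

test_that("stepwise trace agrees with the naive determinant oracle", {
  cm <- random_case_matrix(10, 6, shift = c(1.5, 1.2, 0, 0.8, 0, 0),
                           seed = 17)
  sel <- stepwise_select(cm$X, cm$y)
  expect_gt(length(sel$selected), 0)
  ## recompute every entry's lambda and F naively
  for (i in seq_len(nrow(sel$trace))) {
    tr <- sel$trace[i, ]
    if (tr$action != "enter") next
    upto <- sel$trace$feature[seq_len(i)][sel$trace$action[seq_len(i)] ==
                                            "enter"]
    expect_equal(tr$lambda, wilks_lambda(cm$X, cm$y, upto),
                 tolerance = 1e-9)
    prev <- upto[-length(upto)]
    pf <- partial_f(cm$X, cm$y, prev, tr$feature, "enter")
    expect_equal(tr$F, pf$F, tolerance = 1e-9)
  }
})

test_that("lambda decreases monotonically along entries", {
  cm <- random_case_matrix(10, 8, shift = runif(8, 0, 2), seed = 23)
  sel <- stepwise_select(cm$X, cm$y)
  entries <- sel$trace$lambda[sel$trace$action == "enter"]
  if (length(entries) > 1) {
    expect_true(all(diff(entries) < 1e-12))
  }
  expect_gt(length(sel$selected), 0)
})

test_that("selection and accuracies are invariant to feature rescaling", {
  sig <- simulate_bulk_hybridization(
    seed = 5, model = signal_model(n_features = 25, planted_index = 3))
  signals <- spike_in_normalize(apply_qc_flags(sig$signals))
  d1 <- reciprocal_dfa(signals, "DN1", "SD")
  scaled <- dplyr::mutate(signals, snr = ifelse(
    feature_id == "S003", snr * 1000, snr))
  d2 <- reciprocal_dfa(scaled, "DN1", "SD")
  expect_equal(d1$selected, d2$selected)
  expect_equal(d1$training_accuracy, d2$training_accuracy)
  expect_equal(d1$test_accuracy, d2$test_accuracy)
  expect_equal(d1$lambda, d2$lambda, tolerance = 1e-9)
})

test_that("classification functions recover centroids and midpoints", {
  X <- matrix(c(0, 0.5, -0.5, 4, 4.5, 3.5), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("a", "b"), each = 3))
  fit <- fit_classification_functions(X, y, "f")
  ## group-1 centroid classified to group 1
  expect_equal(predict(fit, matrix(0, 1, 1,
                                   dimnames = list(NULL, "f")))$group, "a")
  ## 1-D equal-variance boundary at the midpoint of the means
  eps <- 1e-6
  mid <- 2
  expect_equal(predict(fit, matrix(mid - eps, 1, 1,
                                   dimnames = list(NULL, "f")))$group, "a")
  expect_equal(predict(fit, matrix(mid + eps, 1, 1,
                                   dimnames = list(NULL, "f")))$group, "b")
  ## exact midpoint: tie flagged, assigned to first label
  tie <- predict(fit, matrix(mid, 1, 1, dimnames = list(NULL, "f")))
  expect_true(tie$tie)
  expect_equal(tie$group, "a")
})

test_that("reciprocal validation: a copied biological replicate gives equal
           train and test accuracy", {
  sig <- toy_signals(list(DN1 = list(c(10, 11, 12), c(10, 11, 12)),
                          SD = list(c(1, 2, 3), c(1, 2, 3))),
                     n_features = 2)
  d <- reciprocal_dfa(sig, "DN1", "SD")
  expect_equal(d$directions$training_accuracy,
               d$directions$test_accuracy)
  expect_equal(d$training_accuracy, 100)
})

test_that("linearly separable bulks give 100% training accuracy", {
  sig <- toy_signals(list(DN1 = list(c(20, 21, 22), c(19, 20, 23)),
                          SD = list(c(1, 2, 3), c(2, 3, 1))),
                     n_features = 2)
  d <- reciprocal_dfa(sig, "DN1", "SD")
  expect_equal(d$training_accuracy, 100)
  expect_equal(d$test_accuracy, 100)
})

test_that("tidy and glance expose the stepwise trace and summary", {
  sig <- toy_signals(list(DN1 = list(c(20, 21, 22), c(19, 20, 23)),
                          SD = list(c(1, 2, 3), c(2, 3, 1))))
  d <- reciprocal_dfa(sig, "DN1", "SD")
  td <- tidy(d)
  expect_true(all(c("step", "feature", "lambda", "p") %in% names(td)))
  gl <- glance(d)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$comparison, "DN1-SD")
})
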