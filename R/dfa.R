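#' Configuration for stepwise discriminant analysis
#'
#' Stepwise entry/removal is driven by the probability of the partial-F
#' statistic: a candidate enters when its entry p-value is below `p_enter`
#' and an entered feature is removed when its removal p-value exceeds
#' `p_remove` (the conventional stepwise defaults). `tolerance` excludes
#' candidates nearly collinear with the entered set (fraction of
#' within-group variance unexplained by the entered features).
#'
#' @param p_enter Entry probability threshold (default 0.05).
#' @param p_remove Removal probability threshold (default 0.10).
#' @param tolerance Collinearity pivot threshold (default 1e-8).
#' @param max_steps Upper bound on entered features (default 50).
#' @param select_on `"all"`: stepwise selection once on all cases, then
#'   per-direction validation (one feature set per comparison);
#'   `"training"`: selection repeated on each direction's training cases.
#' @param priors `"equal"` (default) or `"proportional"` group priors for
#'   the classification functions.
#' @return List of class `dfa_config`.
#' @export
dfa_config <- function(p_enter = 0.05, p_remove = 0.10, tolerance = 1e-8,
                       max_steps = 50L,
                       select_on = c("all", "training"),
                       priors = c("equal", "proportional")) {
  stopifnot(p_enter < p_remove, tolerance > 0, max_steps >= 1)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 tolerance = tolerance, max_steps = as.integer(max_steps),
                 select_on = match.arg(select_on),
                 priors = match.arg(priors)),
            class = "dfa_config")
}

## Pooled within-group (W) and total (T) scatter matrices on a feature
## subset. y must be a factor.
scatter_matrices <- function(X, y, subset) {
  Xs <- X[, subset, drop = FALSE]
  Tm <- crossprod(sweep(Xs, 2, colMeans(Xs)))
  W <- matrix(0, ncol(Xs), ncol(Xs))
  for (lev in levels(y)) {
    Xg <- Xs[y == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  list(W = W, T = Tm)
}

#' Wilks' lambda of a feature subset
#'
#' `det(W)/det(T)` with W the pooled within-group scatter and T the total
#' scatter on the subset. Values near 1 mean the groups are not separated
#' on these features; values near 0 mean nearly all variation is
#' between-group.
#'
#' @param X Numeric case-by-feature matrix (column names = feature ids).
#' @param y Two-level grouping (factor or coercible).
#' @param subset Column names or indices of the subset (default: all).
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda <- function(X, y, subset = colnames(X)) {
  y <- droplevels(as.factor(y))
  if (length(subset) == 0) return(1)
  sm <- scatter_matrices(X, y, subset)
  dT <- det(sm$T)
  if (!is.finite(dT) || dT <= 0) {
    abort("total scatter matrix is singular on this subset",
          class = "bsa_degenerate_data_error")
  }
  max(det(sm$W) / dT, 0)
}

#' Partial F-to-enter / F-to-remove for one candidate feature
#'
#' The partial-lambda F statistic comparing the model with and without the
#' candidate: `F = (n - g - p) * (lambda_small/lambda_large - 1) / (g - 1)`
#' with g groups and p the size of the smaller model, referred to an
#' F(g - 1, n - g - p) distribution.
#'
#' @inheritParams wilks_lambda
#' @param current_subset Feature ids already in the model.
#' @param candidate Feature id to enter (not in the model) or remove
#'   (in the model).
#' @param mode `"enter"` or `"remove"`.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
partial_f <- function(X, y, current_subset, candidate,
                      mode = c("enter", "remove")) {
  mode <- match.arg(mode)
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- nrow(X)
  if (mode == "enter") {
    small <- current_subset
    large <- c(current_subset, candidate)
  } else {
    small <- setdiff(current_subset, candidate)
    large <- current_subset
  }
  p_small <- length(small)
  df1 <- g - 1
  df2 <- n - g - p_small
  if (df2 < 1) {
    abort("insufficient cases for partial F (nonpositive residual df)",
          class = "bsa_insufficient_cases_error")
  }
  l_small <- wilks_lambda(X, y, small)
  l_large <- wilks_lambda(X, y, large)
  if (l_large <= 0) {
    Fv <- Inf
  } else {
    Fv <- df2 * (l_small / l_large - 1) / df1
  }
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

## Fraction of the candidate's within-group variance not explained by the
## entered features (SPSS-style tolerance, computed from W).
candidate_tolerance <- function(X, y, entered, candidate) {
  smc <- scatter_matrices(X, y, candidate)
  if (smc$T[1, 1] <= 0 || smc$W[1, 1] <= 0) return(0)
  if (length(entered) == 0) return(1)
  sm_all <- scatter_matrices(X, y, c(entered, candidate))
  sm_ent <- scatter_matrices(X, y, entered)
  d_ent <- det(sm_ent$W)
  if (!is.finite(d_ent) || d_ent <= 0) return(0)
  det(sm_all$W) / (d_ent * smc$W[1, 1])
}

#' Stepwise feature selection by Wilks' lambda
#'
#' Iteratively enters the candidate feature with the smallest entry
#' p-value while it is below `p_enter`, and after each entry removes any
#' entered feature whose removal p-value exceeds `p_remove`. Ties are
#' broken by the smaller p-value, then by lexicographic feature id.
#' Candidates whose tolerance falls below `config$tolerance` (collinear
#' with the entered set, or constant) are excluded.
#'
#' @inheritParams wilks_lambda
#' @param config A [dfa_config()].
#' @return List with `selected` (ordered feature ids), `trace` (tibble:
#'   step, action, feature, lambda, F, p) and final `lambda`.
#' @export
stepwise_select <- function(X, y, config = dfa_config()) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  if (min(table(y)) < 2) {
    abort("need at least 2 cases per group",
          class = "bsa_insufficient_cases_error")
  }
  features <- colnames(X)
  n <- nrow(X)
  ## Full within-group and total scatter matrices, computed once.
  ## All per-step quantities are Schur-complement (residual-variance)
  ## updates on these, so each step is one small solve, not a fresh
  ## determinant per candidate.
  Xc <- sweep(X, 2, colMeans(X))
  Tm <- crossprod(Xc)
  W <- matrix(0, ncol(X), ncol(X), dimnames = dimnames(Tm))
  for (lev in levels(y)) {
    Xg <- X[y == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  resid_on <- function(M, entered, cand_idx) {
    ## diag of the Schur complement of M over the entered block,
    ## restricted to the candidate columns
    dM <- diag(M)[cand_idx]
    if (length(entered) == 0) return(dM)
    A <- tryCatch(solve(M[entered, entered, drop = FALSE],
                        M[entered, cand_idx, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(A)) return(rep(NA_real_, length(cand_idx)))
    dM - colSums(M[entered, cand_idx, drop = FALSE] * A)
  }
  entered <- character(0)
  lambda <- 1
  trace <- list()
  step <- 0L
  repeat {
    if (length(entered) >= config$max_steps) break
    df2 <- n - 2 - length(entered)
    if (df2 < 1) break  # residual df exhausted
    if (lambda <= config$tolerance) break  # (near-)perfect separation
    cand_idx <- which(!(features %in% entered))
    if (length(cand_idx) == 0) break
    w_res <- resid_on(W, entered, cand_idx)
    t_res <- resid_on(Tm, entered, cand_idx)
    tol <- w_res / diag(W)[cand_idx]
    ok <- is.finite(w_res) & is.finite(t_res) & w_res > 0 & t_res > 0 &
      is.finite(tol) & tol >= config$tolerance
    if (!any(ok)) break
    ## lambda_{S+c} = lambda_S * w_res/t_res, so
    ## F = df2 * (lambda_S/lambda_{S+c} - 1) = df2 * (t_res/w_res - 1)
    Fv <- rep(NA_real_, length(cand_idx))
    Fv[ok] <- df2 * (t_res[ok] / w_res[ok] - 1)
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    ord <- order(pv, features[cand_idx], na.last = TRUE)
    best <- ord[1]
    if (!isTRUE(pv[best] < config$p_enter)) break
    lambda <- unname(lambda * w_res[best] / t_res[best])
    entered <- c(entered, features[cand_idx[best]])
    step <- step + 1L
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, action = "enter", feature = features[cand_idx[best]],
      lambda = lambda, F = unname(Fv[best]), p = unname(pv[best])
    )
    ## removal sweep: lambda_{S-v}/lambda_S = (W^-1)_vv / (T^-1)_vv
    repeat {
      if (length(entered) < 2) break
      df2r <- n - 2 - (length(entered) - 1)
      Winv <- tryCatch(solve(W[entered, entered, drop = FALSE]),
                       error = function(e) NULL)
      Tinv <- tryCatch(solve(Tm[entered, entered, drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(Winv) || is.null(Tinv)) break
      ratio <- diag(Winv) / diag(Tinv)  # lambda_{S-v}/lambda_S, >= 1
      Fr <- df2r * (ratio - 1)
      pr <- stats::pf(Fr, 1, df2r, lower.tail = FALSE)
      ordr <- order(-pr, entered)
      worst <- ordr[1]
      if (!isTRUE(pr[worst] > config$p_remove)) break
      lambda <- unname(lambda * ratio[worst])
      removed <- entered[worst]
      entered <- setdiff(entered, removed)
      step <- step + 1L
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = step, action = "remove", feature = removed,
        lambda = lambda, F = unname(Fr[worst]), p = unname(pr[worst])
      )
    }
  }
  final_lambda <- if (length(entered) > 0) wilks_lambda(X, y, entered) else 1
  list(selected = entered,
       trace = dplyr::bind_rows(trace),
       lambda = final_lambda)
}

#' Fisher's linear classification functions
#'
#' Per-group linear scores `c_k(x) = mu_k' S^-1 x - mu_k' S^-1 mu_k / 2 +
#' log(prior_k)` with S the pooled within-group covariance on the selected
#' features. A case is assigned to the group with the larger score; an
#' exact tie goes to the lexicographically first group label and is
#' flagged.
#'
#' @inheritParams wilks_lambda
#' @param selected Nonempty feature subset.
#' @param priors `"equal"` or `"proportional"`.
#' @return Object of class `bsa_classifier`: coefficients (feature x
#'   group), constants, group labels, selected features.
#' @export
fit_classification_functions <- function(X, y, selected,
                                         priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  if (length(selected) == 0) {
    abort("no selected features to fit classification functions on",
          class = "bsa_degenerate_data_error")
  }
  sm <- scatter_matrices(X, y, selected)
  n <- nrow(X)
  S <- sm$W / (n - g)
  Sinv <- tryCatch(solve(S), error = function(e) {
    abort("pooled within-group covariance is singular",
          class = "bsa_degenerate_data_error")
  })
  pri <- if (priors == "equal") rep(1 / g, g) else as.numeric(table(y)) / n
  coef <- matrix(NA_real_, length(selected), g,
                 dimnames = list(selected, levels(y)))
  const <- setNames(numeric(g), levels(y))
  for (k in seq_len(g)) {
    mu <- colMeans(X[y == levels(y)[k], selected, drop = FALSE])
    ck <- Sinv %*% mu
    coef[, k] <- ck
    const[k] <- -0.5 * sum(mu * ck) + log(pri[k])
  }
  structure(list(coefficients = coef, constants = const,
                 groups = levels(y), selected = selected),
            class = "bsa_classifier")
}

#' @rdname fit_classification_functions
#' @param object A `bsa_classifier`.
#' @param newdata Case-by-feature matrix containing the selected columns.
#' @param ... Unused.
#' @return For `predict`: tibble with `group` (assigned label), per-group
#'   scores, and `tie` flag.
#' @method predict bsa_classifier
#' @export
predict.bsa_classifier <- function(object, newdata, ...) {
  Xs <- newdata[, object$selected, drop = FALSE]
  scores <- Xs %*% object$coefficients +
    matrix(object$constants, nrow(Xs), length(object$groups), byrow = TRUE)
  tie <- abs(scores[, 1] - scores[, 2]) < 1e-12
  idx <- max.col(scores, ties.method = "first")
  ## ties go to the lexicographically first label
  idx[tie] <- which(object$groups == sort(object$groups)[1])[1]
  tibble::tibble(group = object$groups[idx],
                 score_1 = scores[, 1], score_2 = scores[, 2],
                 tie = tie)
}

## Build the case-by-feature matrix for one two-bulk comparison.
## Cases are technical replicates; features with any masked or missing
## cell among the comparison's cases are excluded.
comparison_matrix <- function(signals, group_dn, group_sd, features = NULL) {
  if (is.null(features)) {
    features <- unique(signals$feature_id[signals$category == "subtracted"])
  }
  sub <- dplyr::filter(signals, .data$target %in% c(group_dn, group_sd),
                       .data$feature_id %in% .env$features)
  usable <- dplyr::summarise(
    dplyr::group_by(sub, .data$feature_id),
    ok = !any(.data$masked),
    .groups = "drop"
  )
  keep <- usable$feature_id[usable$ok]
  sub <- dplyr::filter(sub, .data$feature_id %in% .env$keep)
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "target", "bio_rep", "tech_rep", "feature_id", "snr"),
    names_from = "feature_id", values_from = "snr"
  )
  X <- as.matrix(wide[, intersect(features, keep), drop = FALSE])
  list(X = X,
       y = factor(wide$target, levels = c(group_dn, group_sd)),
       bio_rep = wide$bio_rep)
}

#' Stepwise DFA with reciprocal biological-replicate validation
#'
#' Runs the two-group stepwise discriminant analysis for one bulk
#' comparison with the reciprocal train/test design: direction 1 trains on
#' the technical replicates of biological replicate 1 (both bulks) and
#' tests on biological replicate 2; direction 2 is the reciprocal. With
#' `select_on = "all"` (default) the feature set is selected once on all
#' cases, giving a single set per comparison; classification functions are
#' always fit on the direction's training cases only.
#'
#' @param signals Normalised long signal tibble (after QC).
#' @param group_dn,group_sd Targets of the two bulks being contrasted.
#' @param features Candidate features (default: all subtracted).
#' @param config A [dfa_config()].
#' @return Object of class `bsa_dfa`: comparison id, selected features with
#'   lambda trace, per-direction selections and accuracies, classifier fit
#'   on all cases, and config.
#' @export
reciprocal_dfa <- function(signals, group_dn, group_sd = "SD",
                           features = NULL, config = dfa_config()) {
  cm <- comparison_matrix(signals, group_dn, group_sd, features)
  bios <- sort(unique(cm$bio_rep))
  if (length(bios) < 2) {
    abort("reciprocal validation needs at least 2 biological replicates",
          class = "bsa_insufficient_cases_error")
  }
  sel_all <- stepwise_select(cm$X, cm$y, config)
  directions <- purrr::map(seq_along(bios[1:2]), function(d) {
    train_bio <- bios[d]
    test_bio <- bios[-d][1]
    tr <- cm$bio_rep == train_bio
    te <- cm$bio_rep == test_bio
    if (min(table(cm$y[tr])) < 2) {
      abort("fewer than 2 training cases in a group",
            class = "bsa_insufficient_cases_error")
    }
    sel <- if (config$select_on == "training") {
      stepwise_select(cm$X[tr, , drop = FALSE], droplevels(cm$y[tr]), config)
    } else {
      sel_all
    }
    if (length(sel$selected) == 0) {
      ## no discriminating feature: assign by tie-break rule
      first <- sort(levels(cm$y))[1]
      train_acc <- 100 * mean(cm$y[tr] == first)
      test_acc <- 100 * mean(cm$y[te] == first)
    } else {
      ## the training split can only support n_train - g - 1 features in a
      ## nonsingular pooled covariance; keep the earliest-entered ones
      max_feats <- max(sum(tr) - 3, 1)
      use <- head(sel$selected, max_feats)
      fit <- fit_classification_functions(cm$X[tr, , drop = FALSE],
                                          droplevels(cm$y[tr]),
                                          use, config$priors)
      train_acc <- 100 * mean(
        predict(fit, cm$X[tr, , drop = FALSE])$group == as.character(cm$y[tr]))
      test_acc <- 100 * mean(
        predict(fit, cm$X[te, , drop = FALSE])$group == as.character(cm$y[te]))
    }
    tibble::tibble(direction = d, train_bio = train_bio, test_bio = test_bio,
                   selected = list(sel$selected),
                   training_accuracy = train_acc, test_accuracy = test_acc)
  })
  directions <- dplyr::bind_rows(directions)
  classifier <- if (length(sel_all$selected) > 0) {
    fit_classification_functions(cm$X, cm$y, sel_all$selected, config$priors)
  } else {
    NULL
  }
  structure(list(
    comparison = paste0(group_dn, "-", group_sd),
    selected = sel_all$selected,
    trace = sel_all$trace,
    lambda = sel_all$lambda,
    directions = directions,
    training_accuracy = mean(directions$training_accuracy),
    test_accuracy = mean(directions$test_accuracy),
    classifier = classifier,
    n_cases = nrow(cm$X),
    config = config
  ), class = "bsa_dfa")
}

#' @export
print.bsa_dfa <- function(x, ...) {
  cat("Stepwise DFA:", x$comparison, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  Wilks' lambda: %.4f\n", x$lambda))
  cat(sprintf("  training accuracy: %.1f%%  test accuracy: %.1f%%\n",
              x$training_accuracy, x$test_accuracy))
  invisible(x)
}

#' @method tidy bsa_dfa
#' @export
tidy.bsa_dfa <- function(x, ...) {
  x$trace
}

#' @method glance bsa_dfa
#' @export
glance.bsa_dfa <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison,
    n_selected = length(x$selected),
    lambda = x$lambda,
    training_accuracy = x$training_accuracy,
    test_accuracy = x$test_accuracy,
    n_cases = x$n_cases
  )
}
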