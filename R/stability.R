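#' Stability feature selection with LASSO and elastic net
#'
#' Repeated regularized fits over random splits: in each iteration the
#' samples are divided into a 75% training part, the L1 (LASSO) and
#' elastic-net penalties are tuned by inner cross-validation on the training
#' part, and the features with nonzero coefficients at the tuned penalty are
#' recorded. After all iterations, features are ranked by appearance
#' frequency separately under the two methods; the top 25% of each ranking
#' (ceiling truncation, frequency ties broken by feature name) are
#' intersected to give the selected set.
#'
#' @param x A [labeled_matrix()] with binary labels.
#' @param n_iterations Number of random splits (default 10).
#' @param train_fraction Fraction of samples in the training part
#'   (default 0.75).
#' @param inner_folds Folds of the inner penalty-tuning CV (default 10).
#' @param top_fraction Fraction of the frequency ranking kept per method
#'   (default 0.25).
#' @param en_alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Seed for the splits.
#' @param max_retries Resampling attempts when a split leaves a single class
#'   in training (default 10 per iteration).
#' @return An object of class `selection_result` with `selected` (feature
#'   names), `freq_lasso`, `freq_en` (appearance frequencies) and the
#'   thresholds used.
#' @export
stability_select <- function(x, n_iterations = 10L, train_fraction = 0.75,
                             inner_folds = 10L, top_fraction = 0.25,
                             en_alpha = 0.5, seed = 1L, max_retries = 10L) {
  assert_that(inherits(x, "labeled_matrix") && !is.null(x$labels),
              "stability_select needs a labeled matrix")
  vals <- x$values
  y <- as.factor(x$labels)
  assert_that(nlevels(y) == 2, "need exactly two classes")
  p <- ncol(vals)
  features <- colnames(vals)
  set.seed(seed)

  hits_lasso <- stats::setNames(numeric(p), features)
  hits_en <- stats::setNames(numeric(p), features)
  n <- nrow(vals)
  n_train <- max(2L, round(train_fraction * n))

  nonzero_features <- function(xt, yt, mix) {
    cv <- glmnet::cv.glmnet(xt, yt, family = "binomial", alpha = mix,
                            nfolds = inner_folds)
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, , drop = FALSE]
    rownames(co)[co[, 1] != 0]
  }

  for (it in seq_len(n_iterations)) {
    idx <- NULL
    for (try in seq_len(max_retries)) {
      cand <- sample.int(n, n_train)
      if (nlevels(droplevels(y[cand])) == 2) { idx <- cand; break }
    }
    if (is.null(idx)) {
      stop("could not draw a training split containing both classes", call. = FALSE)
    }
    xt <- vals[idx, , drop = FALSE]
    yt <- y[idx]
    sel_l <- nonzero_features(xt, yt, 1)
    sel_e <- nonzero_features(xt, yt, en_alpha)
    hits_lasso[sel_l] <- hits_lasso[sel_l] + 1
    hits_en[sel_e] <- hits_en[sel_e] + 1
  }

  k <- ceiling(top_fraction * p)
  top_by_freq <- function(freq) {
    ord <- order(-freq, names(freq))
    names(freq)[ord][seq_len(k)]
  }
  selected <- intersect(top_by_freq(hits_lasso), top_by_freq(hits_en))
  structure(list(selected = selected,
                 freq_lasso = hits_lasso / n_iterations,
                 freq_en = hits_en / n_iterations,
                 top_fraction = top_fraction, k = k,
                 n_iterations = n_iterations),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected (top %d per method over %d iterations)\n",
              length(x$selected), x$k, x$n_iterations))
  invisible(x)
}
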