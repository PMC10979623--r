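#' Hyperparameter grid for the gradient-boosted classifier
#'
#' Histogram gradient boosting with the standard tuning grid: learning rates
#' 1e-4, 1e-3, 1e-2, 1 and 10 crossed with minimum samples per leaf 1, 10,
#' 25, 50 and 75, scored by 5-fold stratified cross-validated AUROC.
#'
#' @param learning_rates,min_samples_leaf Grid values.
#' @param folds CV folds (default 5).
#' @param nrounds Boosting rounds per fit (default 100).
#' @return An object of class `classifier_grid`.
#' @export
classifier_grid <- function(learning_rates = c(1e-4, 1e-3, 1e-2, 1, 10),
                            min_samples_leaf = c(1, 10, 25, 50, 75),
                            folds = 5L, nrounds = 100L) {
  assert_that(length(learning_rates) >= 1 && length(min_samples_leaf) >= 1,
              "grids must be non-empty")
  structure(list(learning_rates = learning_rates,
                 min_samples_leaf = min_samples_leaf,
                 folds = as.integer(folds), nrounds = as.integer(nrounds)),
            class = "classifier_grid")
}

#' Area under the ROC curve
#'
#' @param labels Binary labels (any two values).
#' @param scores Numeric classifier scores, higher = more positive.
#' @param positive The label value treated as positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores, positive = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  assert_that(length(lev) == 2, "auroc needs exactly two label values")
  if (is.null(positive)) positive <- lev[2]
  negative <- setdiff(lev, positive)
  as.numeric(pROC::auc(response = factor(labels, levels = c(negative, positive)),
                       predictor = scores, direction = "<", quiet = TRUE))
}

fit_gbm <- function(x, y01, eta, min_child_weight, nrounds) {
  # histogram gradient boosting (leaf-wise growth, 31 leaves) via xgboost
  dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eval_metric = "logloss",
                                   tree_method = "hist",
                                   grow_policy = "lossguide",
                                   max_leaves = 31, max_depth = 0,
                                   eta = eta,
                                   min_child_weight = min_child_weight,
                                   nthread = 1),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_gbm <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Tune the gradient-boosted classifier by stratified CV
#'
#' Grid search over [classifier_grid()] scored by mean AUROC across
#' stratified folds; ties return the first grid cell in grid order
#' (learning rate varying fastest). When a class has fewer samples than the
#' fold count, the folds are reduced with a warning.
#'
#' @param train A [labeled_matrix()] with both classes.
#' @param grid A [classifier_grid()].
#' @param seed Seed for the fold assignment.
#' @return A list `params` (`eta`, `min_child_weight`, `nrounds`),
#'   `cv_auroc` (matrix of grid scores) and `positive` (the positive class).
#' @export
tune_classifier <- function(train, grid = classifier_grid(), seed = 1L) {
  assert_that(!is.null(train$labels), "training data must be labeled")
  y <- as.character(train$labels)
  counts <- table(y)
  assert_that(length(counts) == 2, "need exactly two classes")
  k <- grid$folds
  if (min(counts) < k) {
    k <- max(2L, min(counts))
    warning("class too small for ", grid$folds, " folds; reduced to ", k,
            call. = FALSE)
  }
  positive <- names(counts)[which.min(counts)]
  y01 <- as.integer(y == positive)
  set.seed(seed)
  folds <- stratified_folds(y, k)
  cells <- expand.grid(eta = grid$learning_rates,
                       min_child_weight = grid$min_samples_leaf)
  scores <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_gbm(train$values[tr, , drop = FALSE], y01[tr],
                     cells$eta[i], cells$min_child_weight[i], grid$nrounds)
      pred <- predict_gbm(fit, train$values[!tr, , drop = FALSE])
      fold_auc[f] <- if (length(unique(y01[!tr])) < 2) NA_real_
                     else auroc(y01[!tr], pred, positive = "1")
    }
    scores[i] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(scores)   # which.max returns the first maximum: grid order
  list(params = list(eta = cells$eta[best],
                     min_child_weight = cells$min_child_weight[best],
                     nrounds = grid$nrounds),
       cv_auroc = cbind(cells, auroc = scores),
       positive = positive)
}

#' Run the repeated balanced-training validation protocol
#'
#' For each of `n_iterations` iterations the balanced training set is
#' regenerated with a fresh seed, the tuned classifier is fitted on it, and
#' AUROC is scored on the held-out validation set. Iterations whose
#' balancing fails are recorded and skipped; the run fails if more than 10%
#' do.
#'
#' @param real,validation Disjoint [labeled_matrix()] objects.
#' @param mode Balancing mode, see [apply_balancing()].
#' @param tuned Result of [tune_classifier()].
#' @param gans,transformer GAN-mode inputs, see [apply_balancing()].
#' @param n_iterations Number of repetitions (default 100).
#' @param multiplier Expansion multiplier (expand mode).
#' @param seed Master seed; each iteration derives its own stream.
#' @return An object of class `validation_report` with per-iteration AUROC
#'   values, their mean, sd and `auc_diff` (mean minus the 0.5 baseline).
#' @export
evaluate_balancing <- function(real, validation, mode, tuned,
                               gans = NULL, transformer = NULL,
                               n_iterations = 100L, multiplier = 1.0,
                               seed = 1L) {
  assert_that(!is.null(validation$labels), "validation data must be labeled")
  positive <- tuned$positive
  y_val <- as.integer(as.character(validation$labels) == positive)
  aurocs <- rep(NA_real_, n_iterations)
  for (it in seq_len(n_iterations)) {
    res <- tryCatch({
      balanced <- apply_balancing(real, mode, gans = gans,
                                  transformer = transformer,
                                  multiplier = multiplier,
                                  seed = derive_seed(seed, it))
      y01 <- as.integer(as.character(balanced$labels) == positive)
      fit <- fit_gbm(balanced$values, y01, tuned$params$eta,
                     tuned$params$min_child_weight, tuned$params$nrounds)
      pred <- predict_gbm(fit, validation$values)
      auroc(y_val, pred, positive = "1")
    }, error = function(e) NA_real_)
    aurocs[it] <- res
  }
  failed <- sum(is.na(aurocs))
  if (failed > 0.1 * n_iterations) {
    stop(sprintf("balancing failed in %d of %d iterations", failed, n_iterations),
         call. = FALSE)
  }
  ok <- aurocs[!is.na(aurocs)]
  structure(list(method = mode, aurocs = aurocs,
                 mean_auroc = mean(ok), sd_auroc = stats::sd(ok),
                 auc_diff = mean(ok) - 0.5,
                 n_iterations = n_iterations, n_failed = failed,
                 multiplier = if (mode == "gan_expand") multiplier else NA_real_),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s> mean auroc %.3f (sd %.3f), auc_diff %.3f over %d iterations\n",
              x$method, x$mean_auroc, x$sd_auroc, x$auc_diff,
              x$n_iterations - x$n_failed))
  invisible(x)
}

welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: both samples constant
    return(list(t = 0, df = NA_real_, p = if (mean(a) == mean(b)) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       degenerate = FALSE)
}

#' Pairwise Welch comparisons of validation reports
#'
#' All pairwise two-sided Welch (unequal variance) t-tests on the
#' per-iteration AUROC vectors, Benjamini-Hochberg adjusted across the pair
#' family.
#'
#' @param reports Named list of [evaluate_balancing()] reports (names are
#'   method labels; unnamed lists use each report's `method`).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A data frame with one row per method pair: `t`, `df`, `p_value`,
#'   `p_adjusted`, `significant`, `degenerate`.
#' @export
compare_methods <- function(reports, alpha = 0.05) {
  assert_that(length(reports) >= 2, "need at least two reports")
  if (is.null(names(reports))) {
    names(reports) <- vapply(reports, `[[`, character(1), "method")
  }
  pairs <- utils::combn(names(reports), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- reports[[pairs[1, j]]]$aurocs
    b <- reports[[pairs[2, j]]]$aurocs
    w <- welch_p(a[!is.na(a)], b[!is.na(b)])
    data.frame(method1 = pairs[1, j], method2 = pairs[2, j],
               t = w$t, df = w$df, p_value = w$p, degenerate = w$degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Pick the best dispersion-coefficient combination
#'
#' Given reports keyed by alpha combination (e.g. `"0/0"`, `"1/0"`,
#' `"1/1"`), returns the combination with the greatest mean AUROC; ties go
#' to the lower alpha values (sum, then string order).
#'
#' @param reports Named list of [evaluate_balancing()] reports.
#' @return A list with `combination` and `report`.
#' @export
select_alpha_combination <- function(reports) {
  assert_that(length(reports) >= 1, "need at least one report")
  means <- vapply(reports, `[[`, numeric(1), "mean_auroc")
  best <- max(means)
  winners <- names(reports)[means == best]
  if (length(winners) > 1) {
    sums <- vapply(strsplit(winners, "/"),
                   function(v) sum(as.numeric(v)), numeric(1))
    winners <- winners[order(sums, winners)]
  }
  list(combination = winners[1], report = reports[[winners[1]]])
}
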