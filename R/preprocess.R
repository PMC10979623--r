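#' D'Agostino skewness test
#'
#' Two-sided test of the null hypothesis that the sample comes from a
#' normally distributed population, based on the sample skewness
#' (D'Agostino's Z transformation of sqrt(b1)). Requires at least 8
#' observations for the normal approximation.
#'
#' @param x Numeric vector (n >= 8).
#' @return A list with `statistic` (Z), `p_value` (two-sided) and `skewness`
#'   (the biased moment estimator g1). For a constant vector the statistic is
#'   undefined and `p_value` is `NA`.
#' @export
skewness_test <- function(x) {
  n <- length(x)
  assert_that(n >= 8, "skewness test requires at least 8 observations")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, skewness = NA_real_))
  }
  g1 <- mean((x - mean(x))^3) / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z <- delta * asinh(y / alpha)
  list(statistic = Z, p_value = 2 * stats::pnorm(-abs(Z)), skewness = g1)
}

#' Choose a per-feature scaling method by skewness testing
#'
#' Each feature is tested against normality with [skewness_test()]; features
#' with a significant deviation (p < `alpha`) are assigned the Yeo-Johnson
#' power transform, the rest the robust scaler (or the standard scaler when
#' `nonskew_scaler = "standard"`). Constant features cannot be tested and
#' are assigned the non-skew scaler, flagged in the plan.
#'
#' @param x A [labeled_matrix()] or numeric matrix (>= 8 rows).
#' @param alpha Significance level (default 0.05).
#' @param nonskew_scaler Scaler for non-significant features: `"robust"`
#'   (default) or `"standard"`.
#' @return An object of class `scaler_plan`: per-feature `assignment`
#'   (`"power_transform"` or the non-skew scaler), `p_value`, `constant`
#'   flags, and `alpha`.
#' @export
choose_feature_transforms <- function(x, alpha = 0.05,
                                      nonskew_scaler = c("robust", "standard")) {
  nonskew_scaler <- match.arg(nonskew_scaler)
  vals <- if (inherits(x, "labeled_matrix")) x$values else as.matrix(x)
  assert_that(nrow(vals) >= 8, "need at least 8 samples per feature")
  nonskew <- paste0(nonskew_scaler, "_scale")
  tests <- apply(vals, 2, skewness_test)
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  constant <- is.na(p)
  assignment <- ifelse(!constant & p < alpha, "power_transform", nonskew)
  structure(list(assignment = stats::setNames(assignment, colnames(vals)),
                 p_value = stats::setNames(p, colnames(vals)),
                 constant = stats::setNames(constant, colnames(vals)),
                 alpha = alpha, nonskew_scaler = nonskew_scaler),
            class = "scaler_plan")
}

# --- Yeo-Johnson machinery ---------------------------------------------------

yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) < 1e-10) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (abs(lambda - 2) < 1e-10) {
    out[!pos] <- -log1p(-x[!pos])
  } else {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

yeo_johnson_inverse <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) < 1e-10) {
    out[pos] <- expm1(y[pos])
  } else {
    out[pos] <- (lambda * y[pos] + 1)^(1 / lambda) - 1
  }
  if (abs(lambda - 2) < 1e-10) {
    out[!pos] <- -expm1(-y[!pos])
  } else {
    out[!pos] <- 1 - (1 - (2 - lambda) * y[!pos])^(1 / (2 - lambda))
  }
  out
}

# Profile log-likelihood of the Yeo-Johnson parameter (normality of the
# transformed values), maximized over lambda in [-5, 5].
yj_fit_lambda <- function(x) {
  n <- length(x)
  const <- sum(sign(x) * log1p(abs(x)))
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    v <- stats::var(y) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lambda - 1) * const
  }
  stats::optimize(ll, c(-5, 5), maximum = TRUE)$maximum
}

#' Fit a column transformer from a scaler plan
#'
#' Fits, per feature, either the Yeo-Johnson power transform
#' (maximum-likelihood lambda, then standardization to zero mean / unit
#' variance) or scaling (`robust`: subtract median, divide by IQR;
#' `standard`: subtract mean, divide by sd) on a random subsample of
#' `n_fit_samples` rows (all rows by default). A feature with zero scale
#' falls back to unit scale with a warning.
#'
#' @param x A [labeled_matrix()] or matrix.
#' @param plan A [choose_feature_transforms()] plan covering all features.
#' @param n_fit_samples Number of random rows used for fitting (`Inf` = all).
#' @param seed Optional seed for the fitting subsample.
#' @return An object of class `fitted_transformer`.
#' @export
fit_transformer <- function(x, plan, n_fit_samples = Inf, seed = NULL) {
  vals <- if (inherits(x, "labeled_matrix")) x$values else as.matrix(x)
  assert_that(all(colnames(vals) %in% names(plan$assignment)),
              "plan does not cover all features")
  if (is.finite(n_fit_samples) && n_fit_samples < nrow(vals)) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals[sample.int(nrow(vals), n_fit_samples), , drop = FALSE]
  }
  params <- lapply(colnames(vals), function(f) {
    col <- vals[, f]
    method <- plan$assignment[[f]]
    if (method == "power_transform") {
      lambda <- yj_fit_lambda(col)
      y <- yeo_johnson(col, lambda)
      sc <- stats::sd(y)
      if (!is.finite(sc) || sc == 0) {
        warning("zero scale for feature ", f, "; using unit scale", call. = FALSE)
        sc <- 1
      }
      list(method = method, lambda = lambda, center = mean(y), scale = sc)
    } else if (method == "robust_scale") {
      q <- stats::quantile(col, c(0.25, 0.5, 0.75), names = FALSE)
      sc <- q[3] - q[1]
      if (sc == 0) {
        warning("zero IQR for feature ", f, "; using unit scale", call. = FALSE)
        sc <- 1
      }
      list(method = method, lambda = NA_real_, center = q[2], scale = sc)
    } else {
      sc <- stats::sd(col)
      if (!is.finite(sc) || sc == 0) {
        warning("zero sd for feature ", f, "; using unit scale", call. = FALSE)
        sc <- 1
      }
      list(method = method, lambda = NA_real_, center = mean(col), scale = sc)
    }
  })
  names(params) <- colnames(vals)
  structure(list(params = params, plan = plan,
                 feature_names = colnames(vals),
                 fingerprint = c(n = nrow(vals), p = ncol(vals),
                                 sum = sum(vals), ssq = sum(vals^2))),
            class = "fitted_transformer")
}

#' Apply / invert a fitted transformer
#'
#' `transform_data` maps data to the scaled space the GAN is trained on;
#' `inverse_transform_data` maps generated rows back to the original feature
#' scale. The two are inverse within numeric tolerance for in-range values.
#'
#' @param transformer A [fit_transformer()] result.
#' @param x Matrix or [labeled_matrix()] with the transformer's features.
#' @return A numeric matrix (or [labeled_matrix()] in = out).
#' @export
transform_data <- function(transformer, x) {
  is_lm <- inherits(x, "labeled_matrix")
  vals <- if (is_lm) x$values else as.matrix(x)
  out <- vals
  for (f in transformer$feature_names) {
    pr <- transformer$params[[f]]
    col <- vals[, f]
    if (pr$method == "power_transform") col <- yeo_johnson(col, pr$lambda)
    out[, f] <- (col - pr$center) / pr$scale
  }
  if (is_lm) labeled_matrix(out, labels = x$labels, feature_names = x$feature_names)
  else out
}

#' @rdname transform_data
#' @export
inverse_transform_data <- function(transformer, x) {
  is_lm <- inherits(x, "labeled_matrix")
  vals <- if (is_lm) x$values else as.matrix(x)
  if (is.null(colnames(vals))) colnames(vals) <- transformer$feature_names
  out <- vals
  for (j in seq_along(transformer$feature_names)) {
    f <- transformer$feature_names[j]
    pr <- transformer$params[[f]]
    col <- vals[, j] * pr$scale + pr$center
    if (pr$method == "power_transform") {
      # clamp to the domain of the inverse power transform; generated rows
      # can land slightly outside it
      col <- yeo_johnson_inverse(yj_clamp(col, pr$lambda), pr$lambda)
    }
    out[, j] <- col
  }
  if (is_lm) labeled_matrix(out, labels = x$labels, feature_names = x$feature_names)
  else out
}

# Restrict transformed values to the domain where the inverse Yeo-Johnson is
# defined: for lambda < 0 the positive branch is bounded above by -1/lambda,
# for lambda > 2 the negative branch is bounded below by -1/(lambda - 2).
yj_clamp <- function(y, lambda) {
  if (lambda < -1e-10) y <- pmin(y, -1 / lambda - 1e-8)
  if (lambda > 2 + 1e-10) y <- pmax(y, -1 / (lambda - 2) + 1e-8)
  y
}

#' Filter a ranked feature table to the top-k complete features
#'
#' Takes the `k` features with the smallest adjusted p-values (ties broken by
#' feature name for determinism), then removes any feature flagged as having
#' a missing value in any dataset.
#'
#' @param feature_table Data frame with columns `feature` and `adj_p`.
#' @param k Number of top features to take (capped at the table size with a
#'   warning).
#' @param missing_features Character vector of features with a missing value
#'   anywhere (removed after the top-k cut).
#' @return Character vector of surviving feature names, in rank order.
#' @export
filter_top_features <- function(feature_table, k, missing_features = character(0)) {
  assert_that(all(c("feature", "adj_p") %in% names(feature_table)),
              "feature_table needs 'feature' and 'adj_p' columns")
  if (k > nrow(feature_table)) {
    warning("k exceeds the number of available features; taking all", call. = FALSE)
    k <- nrow(feature_table)
  }
  ord <- order(feature_table$adj_p, feature_table$feature)
  top <- feature_table$feature[ord][seq_len(k)]
  setdiff(top, missing_features)
}
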