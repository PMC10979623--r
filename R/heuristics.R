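#' Per-epoch loss trace
#'
#' Critic and generator losses sampled at regular epochs during training.
#'
#' @param epochs Strictly increasing integer epoch indices.
#' @param critic_loss,generator_loss Numeric vectors, one value per sampled
#'   epoch.
#' @return An object of class `loss_trace`.
#' @export
loss_trace <- function(epochs, critic_loss, generator_loss = rep(NA_real_, length(epochs))) {
  assert_that(length(epochs) == length(critic_loss) &&
                length(epochs) == length(generator_loss),
              "trace components must have equal length")
  if (length(epochs) > 1) {
    assert_that(all(diff(epochs) > 0), "epochs must be strictly increasing")
  }
  structure(list(epochs = as.numeric(epochs),
                 critic_loss = as.numeric(critic_loss),
                 generator_loss = as.numeric(generator_loss)),
            class = "loss_trace")
}

#' @export
print.loss_trace <- function(x, ...) {
  cat(sprintf("<loss_trace> %d points, epochs %s..%s\n", length(x$epochs),
              if (length(x$epochs)) x$epochs[1] else "-",
              if (length(x$epochs)) x$epochs[length(x$epochs)] else "-"))
  invisible(x)
}

#' @export
length.loss_trace <- function(x) length(x$epochs)

trace_slice <- function(trace, idx) {
  loss_trace(trace$epochs[idx], trace$critic_loss[idx], trace$generator_loss[idx])
}

#' Truncate a loss trace at the first out-of-bounds critic loss
#'
#' Returns the prefix strictly before the first critic-loss value above
#' `upper` or below `lower`; the offending value itself is excluded. Used to
#' drop the diverged tail of a training run before any trace statistic is
#' computed.
#'
#' @param trace A [loss_trace()].
#' @param upper,lower Critic-loss bounds (defaults 15 and -10).
#' @return A (possibly empty) [loss_trace()].
#' @export
truncate_trace <- function(trace, upper = 15, lower = -10) {
  assert_that(upper > lower, "upper bound must exceed lower bound")
  bad <- which(trace$critic_loss > upper | trace$critic_loss < lower)
  if (length(bad) == 0) return(trace)
  trace_slice(trace, seq_len(bad[1] - 1L))
}

# Indices of the apexes of a series: all strict local extrema, with runs of
# equal values (plateaus) collapsed to a single apex, and the series endpoints
# counted as flanking extrema. A constant series has no apexes.
find_apexes <- function(y) {
  n <- length(y)
  if (n < 2) return(integer(0))
  keep <- c(TRUE, diff(y) != 0)           # collapse plateaus
  idx <- which(keep)
  z <- y[idx]
  m <- length(z)
  if (m < 2) return(integer(0))           # constant series
  if (m == 2) return(idx)
  d <- sign(diff(z))
  ext <- which(d[-1] != d[-(m - 1)]) + 1L # sign change of slope
  idx[c(1L, ext, m)]
}

#' Instability score of a critic-loss trace
#'
#' Locates the apexes (local maxima and minima) of the critic-loss series,
#' takes the absolute differences between consecutive apex values, and
#' returns the mean of the `top_k` greatest differences (the mean of all of
#' them when fewer exist). A trace with fewer than two apexes scores 0.
#'
#' @param trace A (pre-truncated) [loss_trace()].
#' @param top_k How many of the greatest apex-to-apex differences to average
#'   (default 50).
#' @return A non-negative scalar.
#' @export
instability_score <- function(trace, top_k = 50) {
  apex <- find_apexes(trace$critic_loss)
  if (length(apex) < 2) return(0)
  diffs <- abs(diff(trace$critic_loss[apex]))
  diffs <- sort(diffs, decreasing = TRUE)
  mean(diffs[seq_len(min(top_k, length(diffs)))])
}

#' Speed score of a critic-loss trace
#'
#' Mean critic loss over the first `window` epochs minus the mean over the
#' last `window` epochs; positive when the loss decreased.
#'
#' @param trace A [loss_trace()].
#' @param window Width of the head/tail windows in epochs (default 500).
#' @return A scalar.
#' @export
speed_score <- function(trace, window = 500) {
  assert_that(length(trace$epochs) > 0, "empty trace")
  e0 <- trace$epochs[1]
  e1 <- trace$epochs[length(trace$epochs)]
  head_idx <- trace$epochs < e0 + window
  tail_idx <- trace$epochs > e1 - window
  assert_that(!any(head_idx & tail_idx),
              "trace too short: the head and tail windows overlap")
  mean(trace$critic_loss[head_idx]) - mean(trace$critic_loss[tail_idx])
}

#' Select the phase-2 learning rate from candidate traces
#'
#' Each candidate trace is truncated, then scored by
#' `instab_constant * instability - speed`; the candidate with the smallest
#' score wins. Ties go to the smaller learning rate.
#'
#' @param candidate_traces Named list of [loss_trace()], names are the
#'   learning rates as written by `format()`.
#' @param instab_constant Weight of instability in the objective (default 3).
#' @param window Speed-score window in epochs (default 500).
#' @param top_k Instability top-k (default 50).
#' @return The selected learning rate (numeric).
#' @export
select_lr2 <- function(candidate_traces, instab_constant = 3, window = 500,
                       top_k = 50) {
  assert_that(length(candidate_traces) >= 1, "need at least one candidate")
  lrs <- as.numeric(names(candidate_traces))
  obj <- vapply(candidate_traces, function(tr) {
    tr <- truncate_trace(tr)
    if (length(tr) == 0) return(NA_real_)
    sp <- tryCatch(speed_score(tr, window), error = function(e) NA_real_)
    if (is.na(sp)) return(NA_real_)
    instab_constant * instability_score(tr, top_k) - sp
  }, numeric(1))
  if (all(is.na(obj))) stop("all candidate traces empty after truncation", call. = FALSE)
  best <- min(obj, na.rm = TRUE)
  winners <- lrs[!is.na(obj) & obj == best]
  min(winners)
}

#' Select the phase-1 learning rate from candidate traces
#'
#' For each candidate, the minimum recorded critic loss that is still above
#' `floor` is found; the learning rate with the smallest such value wins.
#' Candidates whose loss never exceeds the floor are ineligible unless all
#' candidates are, in which case the smallest final loss wins (with a
#' warning). Ties go to the smaller learning rate.
#'
#' @param candidate_traces Named list of [loss_trace()] keyed by learning
#'   rate.
#' @param floor Critic-loss floor (default 3).
#' @return The selected learning rate (numeric).
#' @export
select_lr1 <- function(candidate_traces, floor = 3) {
  assert_that(length(candidate_traces) >= 1, "need at least one candidate")
  lrs <- as.numeric(names(candidate_traces))
  min_above <- vapply(candidate_traces, function(tr) {
    above <- tr$critic_loss[tr$critic_loss > floor]
    if (length(above) == 0) NA_real_ else min(above)
  }, numeric(1))
  if (all(is.na(min_above))) {
    warning("no candidate's critic loss exceeded the floor; ",
            "falling back to smallest final loss", call. = FALSE)
    final <- vapply(candidate_traces, function(tr) {
      if (length(tr$critic_loss) == 0) return(NA_real_)   # diverged candidate
      tr$critic_loss[length(tr$critic_loss)]
    }, numeric(1))
    if (all(is.na(final))) stop("all candidates diverged", call. = FALSE)
    best <- min(final, na.rm = TRUE)
    return(min(lrs[!is.na(final) & final == best]))
  }
  best <- min(min_above, na.rm = TRUE)
  min(lrs[!is.na(min_above) & min_above == best])
}

# Evaluate the fitted decay and return the sampled epoch nearest the knee of
# the curve (maximum deviation from the chord after min-max normalization).
kneedle_epoch <- function(epochs, fitted) {
  n <- length(epochs)
  x <- (epochs - epochs[1]) / (epochs[n] - epochs[1])
  rng <- range(fitted)
  if (diff(rng) <= 0) return(NA_real_)
  y <- (fitted - rng[1]) / diff(rng)
  chord <- y[1] + (y[n] - y[1]) * x
  dev <- chord - y        # positive where the curve sags below the chord
  k <- which.max(dev)
  # a near-linear curve has no meaningful knee: require genuine curvature
  if (dev[k] <= 0.02 || k == 1L || k == n) return(NA_real_)
  epochs[k]
}

#' Select the stopping epoch from a critic-loss trace
#'
#' Fits the three-parameter exponential decay `a * exp(-b * t) + c` to the
#' (pre-truncated) critic-loss series by nonlinear least squares, then
#' returns the sampled epoch at the knee of the fitted curve (maximum chord
#' deviation after normalization). If the fit fails or the fitted curve has
#' no knee, falls back to the epoch of minimum critic loss with a warning.
#'
#' @param trace A truncated [loss_trace()] with at least 4 points.
#' @return The selected epoch (one of `trace$epochs`).
#' @export
select_epoch <- function(trace) {
  assert_that(length(trace) >= 4, "need at least 4 trace points")
  ep <- trace$epochs
  y <- trace$critic_loss
  t <- ep - ep[1]
  fit <- tryCatch({
    span <- max(t[length(t)], 1)
    start <- list(a = y[1] - y[length(y)], b = 2 / span, c = y[length(y)])
    minpack.lm::nlsLM(y ~ a * exp(-b * t) + c,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  knee <- NA_real_
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf["b"]) && cf["b"] > 0 && cf["a"] > 0) {
      fitted_curve <- cf["a"] * exp(-cf["b"] * t) + cf["c"]
      knee <- kneedle_epoch(ep, fitted_curve)
    }
  }
  if (is.na(knee)) {
    warning("no knee found; falling back to the epoch of minimum critic loss",
            call. = FALSE)
    return(ep[which.min(y)])
  }
  knee
}
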