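test_that("truncation drops everything from the first out-of-bounds loss", {
  tr <- loss_trace(1:4, c(1, 2, 16, 3))
  expect_equal(truncate_trace(tr)$critic_loss, c(1, 2))
  tr2 <- loss_trace(1:4, c(1, 2, 3, 4))
  expect_identical(truncate_trace(tr2), tr2)
  tr3 <- loss_trace(1:3, c(-11, 0, 1))
  expect_length(truncate_trace(tr3), 0L)
  tr4 <- loss_trace(1:4, c(1, -20, 16, 3))
  expect_equal(truncate_trace(tr4)$critic_loss, 1)
})

test_that("instability scores match hand-computed apex differences", {
  expect_equal(instability_score(make_loss_trace_fixture("constant", 50, list(value = 2))), 0)
  saw <- make_loss_trace_fixture("sawtooth", 40, list(level = 0, amplitude = 1))
  expect_equal(instability_score(saw), 2)
  bump <- loss_trace(1:10, c(0, 5, rep(0, 8)))
  expect_equal(instability_score(bump), 5)
  # top-k restriction: two large early swings dominate when k = 2
  spiky <- loss_trace(1:7, c(0, 10, 0, 1, 0, 1, 0))
  expect_equal(instability_score(spiky, top_k = 2), 10)
  expect_equal(instability_score(spiky, top_k = 100), mean(c(10, 10, 1, 1, 1, 1)))
})

test_that("instability agrees with a brute-force extrema oracle on random traces", {
  brute_instability <- function(y, top_k = 50) {
    # collapse plateaus, then scan every point (including endpoints) for a
    # slope sign change
    keep <- c(TRUE, diff(y) != 0)
    z <- y[keep]
    m <- length(z)
    if (m < 2) return(0)
    apex <- z[1]
    if (m > 2) {
      for (i in 2:(m - 1)) {
        if ((z[i] - z[i - 1]) * (z[i + 1] - z[i]) < 0) apex <- c(apex, z[i])
      }
    }
    apex <- c(apex, z[m])
    if (length(apex) < 2) return(0)
    d <- sort(abs(diff(apex)), decreasing = TRUE)
    mean(d[seq_len(min(top_k, length(d)))])
  }
  set.seed(41)
  for (i in 1:25) {
    y <- round(stats::rnorm(sample(5:60, 1)), 1)   # rounding makes plateaus likely
    tr <- loss_trace(seq_along(y), y)
    expect_equal(instability_score(tr, top_k = 7), brute_instability(y, 7))
  }
})

test_that("speed score equals the head-window minus tail-window mean", {
  con <- make_loss_trace_fixture("constant", 100, list(value = 3))
  expect_equal(speed_score(con, window = 30), 0)
  # linear decay 10 -> 0 over 5000 epochs: head mean ~ 9.5, tail ~ 0.5
  lin <- loss_trace(seq(20, 5000, by = 20), seq(10, 0, length.out = 250))
  expect_equal(speed_score(lin, window = 500), 9, tolerance = 0.05)
  inc <- loss_trace(1:100, seq(0, 5, length.out = 100))
  expect_lt(speed_score(inc, window = 20), 0)
  short <- loss_trace(1:10, rnorm(10))
  expect_error(speed_score(short, window = 500), "overlap")
})

test_that("lr2 selection minimizes the instability/speed objective", {
  # candidate A: instability 1, speed ~9 (objective ~ -6)
  # candidate B: instability 3, speed ~2 (objective ~ 7)
  mk <- function(drop_to, amp, n = 300) {
    base <- seq(10, 10 - drop_to, length.out = n)
    noise <- amp / 2 * rep_len(c(1, -1), n)
    loss_trace(seq_len(n) * 10, base + noise)
  }
  a <- mk(9, 1)
  b <- mk(2, 3)
  traces <- list("0.001" = b, "0.0001" = a)
  expect_equal(select_lr2(traces, window = 500), 1e-4)
  # single candidate returns itself
  expect_equal(select_lr2(list("0.01" = a), window = 500), 0.01)
  # tie -> smaller learning rate
  ties <- list("0.002" = a, "0.001" = a)
  expect_equal(select_lr2(ties, window = 500), 0.001)
  # truncation applies before scoring: a diverged tail is ignored
  div <- a
  div$critic_loss[250:300] <- 99
  expect_equal(select_lr2(list("0.001" = div, "0.0001" = a), window = 500), 1e-4)
})

test_that("lr1 selection picks the smallest critic loss above the floor", {
  mk <- function(min_above) {
    loss_trace(1:50, c(seq(10, min_above, length.out = 40), rep(min_above, 10)))
  }
  traces <- list("0.0005" = mk(5), "0.0001" = mk(3.2), "0.001" = mk(4))
  expect_equal(select_lr1(traces, floor = 3), 1e-4)
  expect_equal(select_lr1(list("0.01" = mk(7))), 0.01)
  # all candidates dip below the floor -> smallest final loss, with warning
  below <- list("0.0005" = loss_trace(1:10, seq(2.9, 1, length.out = 10)),
                "0.0001" = loss_trace(1:10, seq(2.5, 0.5, length.out = 10)))
  expect_warning(sel <- select_lr1(below, floor = 3), "falling back")
  expect_equal(sel, 1e-4)
})

test_that("epoch selection finds the knee of a noiseless decay", {
  tr <- make_loss_trace_fixture("decay", 250, list(a = 10, b = 0.01, c = 1),
                                rate_save = 20L)
  # brute-force chord-deviation oracle on the true curve
  ep <- tr$epochs
  t <- ep - ep[1]
  y <- 10 * exp(-0.01 * t) + 1
  xn <- (ep - ep[1]) / (ep[length(ep)] - ep[1])
  yn <- (y - min(y)) / diff(range(y))
  chord <- yn[1] + (yn[length(yn)] - yn[1]) * xn
  oracle <- ep[which.max(chord - yn)]
  expect_equal(select_epoch(tr), oracle)
  # small noise moves the knee by at most one sampling step
  trn <- make_loss_trace_fixture("decay", 250,
                                 list(a = 10, b = 0.01, c = 1, noise_sd = 0.05),
                                 seed = 4L, rate_save = 20L)
  expect_lte(abs(select_epoch(trn) - oracle), 20L)
})

test_that("epoch selection falls back to the minimum-loss epoch without a knee", {
  lin <- loss_trace(seq(10, 1000, by = 10), seq(10, 1, length.out = 100))
  expect_warning(ep <- select_epoch(lin), "falling back")
  expect_equal(ep, 1000)
  expect_error(select_epoch(loss_trace(1:3, c(3, 2, 1))), "at least 4")
})

test_that("training runs are reproducible and replay as prefixes", {
  set.seed(50)
  data <- matrix(rnorm(40 * 4), 40, 4)
  sched <- network_schedule(4, c(5L, 6L), active_stage = 2L)
  gen <- build_generator(4, sched); cri <- build_critic(4, sched)
  h <- tiny_hyper()
  r1 <- train_gan(gen, cri, data, 40, 1e-4, h, rate_save = 10L, seed = 9)
  r2 <- train_gan(gen, cri, data, 40, 1e-4, h, rate_save = 10L, seed = 9)
  expect_identical(r1$generator$layers, r2$generator$layers)
  expect_identical(r1$trace$critic_loss, r2$trace$critic_loss)
  # prefix replay: 20 epochs of the same stream reproduce the first half
  r3 <- train_gan(gen, cri, data, 20, 1e-4, h, rate_save = 10L, seed = 9)
  expect_identical(r3$trace$critic_loss, r1$trace$critic_loss[1:2])
})

test_that("critic losses mostly shrink on an easy toy problem", {
  set.seed(51)
  data <- matrix(rnorm(60 * 2), 60, 2)
  sched <- network_schedule(2, c(4L), active_stage = 1L)
  wins <- 0L
  for (s in 1:10) {
    gen <- build_generator(2, sched); cri <- build_critic(2, sched)
    r <- train_gan(gen, cri, data, 80, 5e-4,
                   gan_hyperparams(batch_size = 15L, iter_critic = 2L,
                                   dropout_prob = 0, momentum = 0),
                   rate_save = 1L, seed = s)
    tr <- r$trace$critic_loss
    expect_true(all(is.finite(tr)))
    if (mean(abs(tr[76:80])) < mean(abs(tr[1:5]))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("pretraining grows progressively and forces alpha to zero", {
  set.seed(52)
  ext <- labeled_matrix(matrix(rnorm(80 * 6), 80, 6))
  res <- suppressWarnings(
    pretrain_progressive(ext, tiny_pretrain_cfg(),
                         gan_hyperparams(alpha = 1), seed = 3,
                         hidden_sizes = tiny_hidden))
  expect_equal(res$generator$schedule$active_stage, 3L)
  expect_length(res$stages, 3L)
  for (s in res$stages) {
    expect_true(all(is.finite(s$trace$critic_loss)))
    expect_true(s$lr2 %in% tiny_pretrain_cfg()$lr2_candidates)
  }
  # the recorded generator losses carry no dispersion term: recompute from
  # the classic form is impossible post hoc, but alpha is forced inside, so
  # rerunning with alpha 0 explicitly gives identical traces
  res0 <- suppressWarnings(
    pretrain_progressive(ext, tiny_pretrain_cfg(),
                         gan_hyperparams(alpha = 0), seed = 3,
                         hidden_sizes = tiny_hidden))
  expect_identical(res$stages[[3]]$trace$critic_loss,
                   res0$stages[[3]]$trace$critic_loss)
})

test_that("class retraining yields class-specific generators deterministically", {
  set.seed(53)
  blobs <- two_blob_data(n_per_class = 30, p = 4, shift = 6, seed = 8)
  # make classes imbalanced: drop some cases
  keep <- c(1:18, 31:60)
  real_raw <- labeled_matrix(blobs$values[keep, ], labels = blobs$labels[keep],
                             feature_names = blobs$feature_names)
  tf <- fit_transformer(real_raw, choose_feature_transforms(real_raw))
  real <- transform_data(tf, real_raw)
  ext <- transform_data(tf, labeled_matrix(blobs$values))
  pre <- suppressWarnings(
    pretrain_progressive(ext, tiny_pretrain_cfg(n_epochs_2 = 200L),
                         gan_hyperparams(), seed = 4,
                         hidden_sizes = tiny_hidden))
  cfg <- tiny_retrain_cfg(max_epochs_1 = 60L, n_epochs_2 = 1200L,
                          lr1_candidates = c(1e-3, 5e-4),
                          lr2_candidates = c(5e-4, 2e-4),
                          rate_save = 20L, diff_epochs = 300L)
  pair <- suppressWarnings(
    retrain_class_gans(pre, real, cfg, gan_hyperparams(),
                       alpha_under = 0, alpha_over = 0, seed = 5))
  expect_s3_class(pair, "class_gan_pair")
  expect_equal(pair$under_class, "case")
  s_under <- generate_samples(pair$under$generator, 150, seed = 11)
  s_over <- generate_samples(pair$over$generator, 150, seed = 11)
  # the two generators target different clusters: their output distributions
  # differ (two-sample test on the first feature)
  pv <- stats::ks.test(s_under$values[, 1], s_over$values[, 1])$p.value
  expect_lt(pv, 0.05)
  # and each generator tracks its own class centroid more closely
  d_match <- sum((colMeans(s_under$values) -
                    colMeans(real$values[real$labels == "case", ]))^2)
  d_cross <- sum((colMeans(s_under$values) -
                    colMeans(real$values[real$labels == "control", ]))^2)
  expect_lt(d_match, d_cross)
  # fixed seed -> identical selections
  pair2 <- suppressWarnings(
    retrain_class_gans(pre, real, cfg, gan_hyperparams(),
                       alpha_under = 0, alpha_over = 0, seed = 5))
  expect_identical(c(pair$under$lr1, pair$under$lr2, pair$under$epoch),
                   c(pair2$under$lr1, pair2$under$lr2, pair2$under$epoch))
  expect_identical(pair$over$generator$layers, pair2$over$generator$layers)
})

test_that("the classic ablation trains full-depth networks without transfer", {
  set.seed(54)
  real <- two_blob_data(n_per_class = 20, p = 4, shift = 5, seed = 9)
  pair <- suppressWarnings(
    retrain_class_gans(NULL, real, tiny_retrain_cfg(), gan_hyperparams(),
                       alpha_under = 1, alpha_over = 1, seed = 6,
                       classic = TRUE))
  expect_true(pair$classic)
  expect_equal(pair$under$generator$schedule$active_stage, 3L)
  expect_equal(pair$under$alpha, 0)    # classic mode forces alpha 0
  expect_equal(pair$over$alpha, 0)
})

test_that("the dispersion term does not shrink generated batches", {
  set.seed(55)
  data <- matrix(rnorm(60 * 3), 60, 3)
  sched <- network_schedule(3, c(5L), active_stage = 1L)
  norms <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    for (j in 1:2) {
      alpha <- c(0, 1)[j]
      set.seed(100 + s)
      gen <- build_generator(3, sched); cri <- build_critic(3, sched)
      r <- train_gan(gen, cri, data, 150, 1e-3,
                     gan_hyperparams(alpha = alpha, batch_size = 15L,
                                     iter_critic = 2L, dropout_prob = 0),
                     rate_save = 50L, seed = 200 + s)
      smp <- generate_samples(r$generator, 200, seed = 300 + s)
      norms[s, j] <- sqrt(sum(smp$values^2))
    }
  }
  expect_gte(mean(norms[, 2]), mean(norms[, 1]))
})
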