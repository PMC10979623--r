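#' Training configuration (one stage: pretraining or retraining)
#'
#' Collects the training-control settings: epoch budgets, learning-rate
#' candidate grids, trace sampling rate, truncation bounds, and the
#' instability weighting. Two constructors give the standard defaults for
#' the two stages of the workflow.
#'
#' @param max_epochs_1 Epoch budget of the phase-1 (large learning rate) runs.
#' @param max_loss_1 Critic-loss floor used by [select_lr1()].
#' @param n_epochs_2 Epoch budget of the phase-2 (small learning rate) runs.
#' @param lr1_candidates,lr2_candidates Learning-rate candidate grids.
#' @param rate_save Record losses every `rate_save` epochs.
#' @param diff_epochs Window (epochs) of the [speed_score()].
#' @param max_loss_2,min_loss_2 Trace truncation bounds.
#' @param instab_constant Instability weight in the [select_lr2()] objective.
#' @param top_k_apex_diffs Top-k of [instability_score()] (default 50).
#' @param batch_size Batch rows (pretraining) or named vector
#'   `c(under = , over = )` (retraining).
#' @param iter_critic Critic updates per generator update.
#' @param dropout_prob Alpha-dropout probability.
#' @param stage3_stabilize Pretraining only: on reaching the third hidden
#'   layer, switch to `iter_critic = 2` and `dropout_prob = 0.7` (the
#'   stabilization change kept for all subsequent retraining).
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_epochs_1 = 500L, max_loss_1 = 3,
                            n_epochs_2 = 1000L,
                            lr1_candidates = c(5e-4, 1e-4, 1e-3),
                            lr2_candidates = c(1e-5, 5e-5, 1e-4),
                            rate_save = 20L, diff_epochs = 500L,
                            max_loss_2 = 15, min_loss_2 = -10,
                            instab_constant = 3, top_k_apex_diffs = 50L,
                            batch_size = 30L, iter_critic = 4L,
                            dropout_prob = 0.5, stage3_stabilize = TRUE) {
  assert_that(max_loss_2 > min_loss_2, "max_loss_2 must exceed min_loss_2")
  assert_that(length(lr1_candidates) >= 1 && length(lr2_candidates) >= 1,
              "candidate lists must be non-empty")
  structure(list(max_epochs_1 = as.integer(max_epochs_1), max_loss_1 = max_loss_1,
                 n_epochs_2 = as.integer(n_epochs_2),
                 lr1_candidates = lr1_candidates, lr2_candidates = lr2_candidates,
                 rate_save = as.integer(rate_save),
                 diff_epochs = as.integer(diff_epochs),
                 max_loss_2 = max_loss_2, min_loss_2 = min_loss_2,
                 instab_constant = instab_constant,
                 top_k_apex_diffs = as.integer(top_k_apex_diffs),
                 batch_size = batch_size, iter_critic = as.integer(iter_critic),
                 dropout_prob = dropout_prob, stage3_stabilize = stage3_stabilize),
            class = "training_config")
}

#' @rdname training_config
#' @export
pretrain_config <- function(...) {
  training_config(...)
}

#' @rdname training_config
#' @export
retrain_config <- function(max_epochs_1 = 500L, max_loss_1 = 3,
                           n_epochs_2 = 5000L,
                           lr1_candidates = c(5e-4, 1e-4),
                           lr2_candidates = c(1e-5, 5e-5),
                           rate_save = 10L, diff_epochs = 500L,
                           max_loss_2 = 15, min_loss_2 = -15,
                           instab_constant = 3,
                           batch_size = c(under = 10L, over = 20L),
                           iter_critic = 2L, dropout_prob = 0.7, ...) {
  training_config(max_epochs_1 = max_epochs_1, max_loss_1 = max_loss_1,
                  n_epochs_2 = n_epochs_2, lr1_candidates = lr1_candidates,
                  lr2_candidates = lr2_candidates, rate_save = rate_save,
                  diff_epochs = diff_epochs, max_loss_2 = max_loss_2,
                  min_loss_2 = min_loss_2, instab_constant = instab_constant,
                  batch_size = batch_size, iter_critic = iter_critic,
                  dropout_prob = dropout_prob, ...)
}

sample_batch <- function(data, batch_size) {
  n <- nrow(data)
  idx <- sample.int(n, batch_size, replace = batch_size > n)
  data[idx, , drop = FALSE]
}

#' Train a generator/critic pair for a fixed number of epochs
#'
#' One epoch = `iter_critic` critic updates (each on a fresh real batch and a
#' fresh generated batch) followed by one generator update. Losses are
#' recorded every `rate_save` epochs. The run is deterministic given `seed`,
#' and a rerun with the same seed and a smaller `n_epochs` replays an exact
#' prefix — this is how a selected stopping epoch is materialized.
#'
#' @param generator,critic `gan_model` objects of matching schedule.
#' @param data Numeric matrix of (already transformed) training rows.
#' @param n_epochs Number of epochs to train.
#' @param lr Learning rate.
#' @param hyper A [gan_hyperparams()].
#' @param rate_save Trace sampling interval (epochs).
#' @param seed Seed set at entry; controls batching, noise, dropout and
#'   interpolation draws.
#' @return A list with `generator`, `critic` and the recorded [loss_trace()].
#' @export
train_gan <- function(generator, critic, data, n_epochs, lr,
                      hyper = gan_hyperparams(), rate_save = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- generator$schedule$n_features
  bs <- hyper$batch_size
  gen_state <- NULL
  cri_state <- NULL
  rec_epochs <- integer(0); rec_c <- numeric(0); rec_g <- numeric(0)
  last_c <- NA_real_
  diverged <- FALSE
  finite_grads <- function(g) {
    all(vapply(g, function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
               logical(1)))
  }
  for (e in seq_len(n_epochs)) {
    for (k in seq_len(hyper$iter_critic)) {
      x_R <- sample_batch(data, bs)
      noise <- matrix(stats::rnorm(bs * p), bs, p)
      x_F <- gan_forward(generator, noise, training = TRUE,
                         dropout_prob = hyper$dropout_prob)$out
      if (!all(is.finite(x_F))) { diverged <- TRUE; break }
      cache_F <- gan_forward(critic, x_F, training = TRUE,
                             dropout_prob = hyper$dropout_prob)
      cache_R <- gan_forward(critic, x_R, training = TRUE,
                             dropout_prob = hyper$dropout_prob)
      if (!all(is.finite(cache_F$out)) || !all(is.finite(cache_R$out))) {
        diverged <- TRUE; break
      }
      gF <- gan_backward(critic, cache_F, matrix(1 / bs, bs, 1L))$grads
      gR <- gan_backward(critic, cache_R, matrix(-1 / bs, bs, 1L))$grads
      grads <- add_grads(gF, gR)
      pen <- 0
      if (hyper$use_gradient_penalty && hyper$penalty_coefficient > 0) {
        eps <- stats::runif(bs)
        xh <- eps * x_R + (1 - eps) * x_F
        pg <- penalty_param_grads(critic, xh, hyper$penalty_coefficient)
        pen <- pg$value
        grads <- add_grads(grads, pg$grads)
      }
      if (!finite_grads(grads)) { diverged <- TRUE; break }
      stepped <- sgd_step(critic, grads, lr, hyper$momentum, cri_state)
      critic <- stepped$model; cri_state <- stepped$state
      if (!hyper$use_gradient_penalty) critic <- clip_weights(critic, hyper$clip_value)
      last_c <- critic_loss(cache_F$out, cache_R$out, pen)
    }
    if (diverged || !is.finite(last_c)) { diverged <- TRUE; break }
    # generator update
    noise <- matrix(stats::rnorm(bs * p), bs, p)
    gcache <- gan_forward(generator, noise, training = TRUE,
                          dropout_prob = hyper$dropout_prob)
    x_F <- gcache$out
    if (!all(is.finite(x_F))) break
    ccache <- gan_forward(critic, x_F, training = TRUE,
                          dropout_prob = hyper$dropout_prob)
    if (!all(is.finite(ccache$out))) break
    dxF <- gan_backward(critic, ccache, matrix(-1 / bs, bs, 1L))$dx
    if (hyper$alpha > 0) {
      nrm <- frobenius_norm(x_F)
      if (nrm > 0) {
        dxF <- dxF - if (hyper$log_norm_penalty) hyper$alpha * x_F / nrm^2
                     else hyper$alpha * x_F / nrm
      }
    }
    ggrads <- gan_backward(generator, gcache, dxF)$grads
    if (!finite_grads(ggrads)) { diverged <- TRUE; break }
    stepped <- sgd_step(generator, ggrads, lr, hyper$momentum, gen_state)
    generator <- stepped$model; gen_state <- stepped$state
    if (e %% rate_save == 0) {
      rec_epochs <- c(rec_epochs, e)
      rec_c <- c(rec_c, last_c)
      rec_g <- c(rec_g, generator_loss(ccache$out, x_F, hyper$alpha,
                                       hyper$log_norm_penalty))
    }
  }
  generator$trained <- TRUE
  critic$trained <- TRUE
  list(generator = generator, critic = critic, diverged = diverged,
       trace = loss_trace(rec_epochs, rec_c, rec_g))
}

# Two-phase learning-rate-tuned training from a given model state:
#  phase 1: train each lr1 candidate for max_epochs_1 epochs, keep the winner;
#  phase 2: train each lr2 candidate for n_epochs_2 epochs from the winner
#  state, pick by the instability/speed objective, select the knee epoch of
#  the winning trace, and replay the winner to exactly that epoch.
train_stage <- function(generator, critic, data, config, hyper, seed,
                        epoch_select = TRUE) {
  lr1_traces <- list(); lr1_states <- list()
  for (i in seq_along(config$lr1_candidates)) {
    lr <- config$lr1_candidates[i]
    res <- train_gan(generator, critic, data, config$max_epochs_1, lr, hyper,
                     rate_save = config$rate_save, seed = derive_seed(seed, i))
    key <- format(lr, scientific = FALSE)
    lr1_traces[[key]] <- res$trace
    lr1_states[[key]] <- res
  }
  lr1 <- select_lr1(lr1_traces, floor = config$max_loss_1)
  base <- lr1_states[[format(lr1, scientific = FALSE)]]

  lr2_traces <- list(); lr2_seeds <- list()
  for (i in seq_along(config$lr2_candidates)) {
    lr <- config$lr2_candidates[i]
    s <- derive_seed(seed, 100L + i)
    res <- train_gan(base$generator, base$critic, data, config$n_epochs_2, lr,
                     hyper, rate_save = config$rate_save, seed = s)
    key <- format(lr, scientific = FALSE)
    lr2_traces[[key]] <- res$trace
    lr2_seeds[[key]] <- s
  }
  lr2 <- select_lr2(lr2_traces, instab_constant = config$instab_constant,
                    window = config$diff_epochs, top_k = config$top_k_apex_diffs)
  key <- format(lr2, scientific = FALSE)
  winner_trace <- truncate_trace(lr2_traces[[key]],
                                 upper = config$max_loss_2,
                                 lower = config$min_loss_2)
  if (length(winner_trace) == 0) {
    stop("training diverged: trace empty after truncation", call. = FALSE)
  }
  epoch <- if (epoch_select && length(winner_trace) >= 4) {
    select_epoch(winner_trace)
  } else {
    winner_trace$epochs[length(winner_trace$epochs)]
  }
  final <- train_gan(base$generator, base$critic, data, epoch, lr2, hyper,
                     rate_save = config$rate_save, seed = lr2_seeds[[key]])
  list(generator = final$generator, critic = final$critic,
       lr1 = lr1, lr2 = lr2, epoch = epoch,
       trace = lr2_traces[[key]], lr1_traces = lr1_traces,
       lr2_traces = lr2_traces)
}

#' Progressive pre-training on unlabeled external data
#'
#' Grows the generator/critic pair one hidden layer at a time (stages
#' 1 to 3), running the full two-phase learning-rate tuning and knee-point
#' epoch selection within each stage before growing. The dispersion
#' coefficient alpha is forced to 0 throughout pre-training. When
#' `config$stage3_stabilize` is set, the critic:generator ratio drops to 2:1
#' and dropout rises to 0.7 at the third stage.
#'
#' @param external A [labeled_matrix()] (labels ignored) of
#'   already-transformed external data.
#' @param config A [training_config()] (pretraining defaults).
#' @param hyper A [gan_hyperparams()]; `alpha` is overridden to 0.
#' @param seed Master seed.
#' @param hidden_sizes Progressive hidden widths (default 50/100/200).
#' @return A list with the pre-trained `generator`, `critic`, per-stage
#'   summaries and traces.
#' @export
pretrain_progressive <- function(external, config = pretrain_config(),
                                 hyper = gan_hyperparams(), seed = 1L,
                                 hidden_sizes = c(50L, 100L, 200L)) {
  data <- if (inherits(external, "labeled_matrix")) external$values else as.matrix(external)
  p <- ncol(data)
  hyper$alpha <- 0                         # no dispersion term during pre-training
  hyper$batch_size <- as.integer(config$batch_size[1])
  hyper$iter_critic <- config$iter_critic
  hyper$dropout_prob <- config$dropout_prob
  set.seed(derive_seed(seed, 0L))
  sched <- network_schedule(p, hidden_sizes, active_stage = 1L)
  generator <- build_generator(p, sched, hyper)
  critic <- build_critic(p, sched, hyper)
  stages <- list()
  for (stage in seq_along(hidden_sizes)) {
    if (stage > 1) {
      generator <- grow_model(generator)
      critic <- grow_model(critic)
    }
    if (stage == 3 && isTRUE(config$stage3_stabilize)) {
      hyper$iter_critic <- 2L
      hyper$dropout_prob <- 0.7
    }
    res <- train_stage(generator, critic, data, config, hyper,
                       seed = derive_seed(seed, stage))
    generator <- res$generator
    critic <- res$critic
    stages[[stage]] <- list(lr1 = res$lr1, lr2 = res$lr2, epoch = res$epoch,
                            trace = res$trace)
  }
  list(generator = generator, critic = critic, stages = stages,
       hidden_sizes = hidden_sizes, n_features = p)
}

#' Re-train the pre-trained GAN per class of the labeled real data
#'
#' Transfer learning: two copies of the pre-trained generator/critic pair are
#' re-trained, one on each class of the real data, with batch sizes 10
#' (under-represented class) and 20 (over-represented class), learning rates
#' chosen by [select_lr1()]/[select_lr2()] and the stopping epoch by
#' [select_epoch()]. Per-class dispersion coefficients come from
#' `alpha_under` / `alpha_over`.
#'
#' With `classic = TRUE` the same entry point trains a plain
#' gradient-penalized Wasserstein GAN ablation: no pre-training ancestry
#' (fresh full-depth networks, all layers initialized together, no growing)
#' and both alphas 0.
#'
#' @param pretrained Result of [pretrain_progressive()] (ignored when
#'   `classic = TRUE`, may be `NULL` then).
#' @param real A [labeled_matrix()] of already-transformed real data with
#'   both classes present.
#' @param config A [training_config()] (retraining defaults).
#' @param hyper A [gan_hyperparams()] for shared settings (penalty, momentum).
#' @param alpha_under,alpha_over Dispersion coefficients for the two class
#'   GANs.
#' @param seed Master seed.
#' @param classic Train the no-transfer, no-growing ablation instead.
#' @return An object of class `class_gan_pair`: per-class generators plus
#'   training metadata.
#' @export
retrain_class_gans <- function(pretrained, real, config = retrain_config(),
                               hyper = gan_hyperparams(), alpha_under = 0,
                               alpha_over = 0, seed = 1L, classic = FALSE) {
  assert_that(!is.null(real$labels), "real data must be labeled")
  counts <- table(real$labels)
  assert_that(length(counts) == 2, "real data must contain exactly two classes")
  under_class <- names(counts)[which.min(counts)]
  over_class <- setdiff(names(counts), under_class)
  bs <- config$batch_size
  if (length(bs) == 1) bs <- c(under = bs, over = bs)

  train_one <- function(class_name, role, alpha, offset) {
    data <- real$values[real$labels == class_name, , drop = FALSE]
    h <- hyper
    h$alpha <- alpha
    h$batch_size <- as.integer(bs[[role]])
    h$iter_critic <- config$iter_critic
    h$dropout_prob <- config$dropout_prob
    if (classic) {
      set.seed(derive_seed(seed, 900L + offset))
      p <- ncol(real$values)
      sched <- network_schedule(p, c(50L, 100L, 200L))
      generator <- build_generator(p, sched, h)
      critic <- build_critic(p, sched, h)
      h$alpha <- 0
    } else {
      generator <- pretrained$generator
      critic <- pretrained$critic
    }
    res <- train_stage(generator, critic, data, config, h,
                       seed = derive_seed(seed, 10L + offset))
    list(generator = res$generator, critic = res$critic, class = class_name,
         alpha = h$alpha, lr1 = res$lr1, lr2 = res$lr2, epoch = res$epoch,
         trace = res$trace)
  }

  under <- train_one(under_class, "under", if (classic) 0 else alpha_under, 1L)
  over <- train_one(over_class, "over", if (classic) 0 else alpha_over, 2L)
  structure(list(under = under, over = over,
                 under_class = under_class, over_class = over_class,
                 classic = classic),
            class = "class_gan_pair")
}

#' @export
print.class_gan_pair <- function(x, ...) {
  cat(sprintf("<class_gan_pair>%s under='%s' (alpha=%g, lr2=%g, epoch=%d), over='%s' (alpha=%g, lr2=%g, epoch=%d)\n",
              if (x$classic) " [classic ablation]" else "",
              x$under_class, x$under$alpha, x$under$lr2, x$under$epoch,
              x$over_class, x$over$alpha, x$over$lr2, x$over$epoch))
  invisible(x)
}
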