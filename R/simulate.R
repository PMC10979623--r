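#' Configuration for the two-cluster microarray simulator
#'
#' The simulator emulates a clustered microarray engine with a fully
#' specified hierarchical model: features are partitioned into latent blocks,
#' each cluster shifts the block means, samples add a shared within-block
#' deviation (giving correlated features), and every value receives
#' independent additive gamma noise.
#'
#' @param n_features Number of features (default 150, a post-feature-selection
#'   microarray panel size).
#' @param n_validation Samples reserved for the validation split (default 700).
#' @param n_external Samples reserved for the unlabeled "external" split
#'   (default 300).
#' @param cluster_separation Effect-size scale (log-expression units) of the
#'   between-cluster block-mean shifts. The default 0.3 (modest fold changes
#'   spread over many blocks) keeps the two clusters imperfectly separable
#'   (linear-classifier ceiling around 0.93) so that balancing matters.
#' @param block_size Number of correlated features per latent block
#'   (default 10).
#' @param block_sd Standard deviation of the shared within-block deviation
#'   (default 0.5).
#' @param prop_case Cluster mixing proportion of the case cluster in the
#'   full simulated population (default 0.5).
#' @param noise_shape,noise_scale Gamma noise parameters (defaults 2 and 0.5,
#'   i.e. mean 1 and variance 0.5).
#' @param seed Integer seed controlling all simulator randomness.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 150, n_validation = 700,
                              n_external = 300, cluster_separation = 0.3,
                              block_size = 10, block_sd = 0.5,
                              prop_case = 0.5,
                              noise_shape = 2, noise_scale = 0.5, seed = 1L) {
  assert_that(n_features >= 2, "n_features must be at least 2")
  assert_that(noise_shape > 0 && noise_scale > 0,
              "gamma noise parameters must be positive")
  assert_that(n_validation > 0 && n_external > 0 && block_size > 0,
              "counts must be positive")
  assert_that(prop_case > 0 && prop_case < 1, "prop_case must be in (0, 1)")
  structure(list(n_features = as.integer(n_features),
                 n_validation = as.integer(n_validation),
                 n_external = as.integer(n_external),
                 cluster_separation = cluster_separation,
                 block_size = as.integer(block_size),
                 block_sd = block_sd,
                 prop_case = prop_case,
                 noise_shape = noise_shape,
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Experiment design: control count and class imbalance
#'
#' The case count is the control count multiplied by the imbalance ratio
#' (round-half-up; exact for the standard grid).
#'
#' @param n_controls Number of control (majority) samples.
#' @param class_imbalance Ratio in (0, 1); multiplied by `n_controls` to give
#'   the case count.
#' @param experiment_id Optional integer identifier.
#' @return An object of class `experiment_design` with the derived `n_cases`.
#' @export
experiment_design <- function(n_controls, class_imbalance, experiment_id = NA_integer_) {
  assert_that(n_controls > 0, "n_controls must be positive")
  assert_that(class_imbalance > 0 && class_imbalance < 1,
              "class_imbalance must be in (0, 1)")
  n_cases <- as.integer(round_half_up(n_controls * class_imbalance))
  assert_that(n_cases < n_controls, "cases must be fewer than controls")
  structure(list(experiment_id = experiment_id,
                 n_controls = as.integer(n_controls),
                 class_imbalance = class_imbalance,
                 n_cases = n_cases),
            class = "experiment_design")
}

#' The standard nine-experiment design grid
#'
#' Control counts 40/80/120 crossed with imbalance ratios 0.4/0.5/0.6.
#'
#' @return A list of nine [experiment_design()] objects.
#' @export
experiment_grid <- function() {
  grid <- expand.grid(n_controls = c(40L, 80L, 120L),
                      class_imbalance = c(0.4, 0.5, 0.6))
  lapply(seq_len(nrow(grid)), function(i) {
    experiment_design(grid$n_controls[i], grid$class_imbalance[i], experiment_id = i)
  })
}

#' Simulate a two-cluster microarray dataset
#'
#' Generates `n` samples from the hierarchical two-cluster model described in
#' [simulation_config()]: per-feature baselines on a log-expression scale,
#' cluster-specific block-mean shifts of magnitude controlled by
#' `cluster_separation`, a shared N(0, block_sd^2) deviation per (sample,
#' block) inducing within-block correlation, and independent additive
#' gamma(shape, scale) noise.
#'
#' @param n Total number of samples to draw.
#' @param config A [simulation_config()].
#' @return A [labeled_matrix()] with labels `"case"` / `"control"`.
#' @export
simulate_two_cluster_dataset <- function(n, config = simulation_config()) {
  assert_that(n > 0, "n must be positive")
  p <- config$n_features
  set.seed(config$seed)
  n_blocks <- ceiling(p / config$block_size)
  block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(p)]

  # population-level structure, drawn once per config seed
  baseline <- stats::rnorm(p, mean = 7, sd = 1)
  block_shift <- stats::rnorm(n_blocks, mean = 0, sd = config$cluster_separation)
  # case cluster gets +shift/2 per block, control cluster -shift/2
  mu_case <- baseline + (block_shift / 2)[block_of]
  mu_control <- baseline - (block_shift / 2)[block_of]

  labels <- ifelse(stats::runif(n) < config$prop_case, "case", "control")
  mu <- matrix(0, n, p)
  mu[labels == "case", ] <- matrix(mu_case, sum(labels == "case"), p, byrow = TRUE)
  mu[labels == "control", ] <- matrix(mu_control, sum(labels == "control"), p, byrow = TRUE)

  block_dev <- matrix(stats::rnorm(n * n_blocks, sd = config$block_sd), n, n_blocks)
  noise <- matrix(stats::rgamma(n * p, shape = config$noise_shape,
                                scale = config$noise_scale), n, p)
  values <- mu + block_dev[, block_of, drop = FALSE] + noise
  labeled_matrix(values, labels = labels,
                 feature_names = sprintf("gene_%03d", seq_len(p)))
}

#' Split a simulated dataset into real / external / validation sets
#'
#' The validation and external splits are carved from the head of the dataset
#' so that they are identical across designs for a fixed simulated dataset;
#' only the "real" split (sized by the design) varies. The external split has
#' its labels stripped (it is a mixture of the two clusters at the dataset's
#' own proportions); the validation split keeps its labels.
#'
#' @param dataset A [labeled_matrix()] from [simulate_two_cluster_dataset()].
#' @param design An [experiment_design()].
#' @param config The [simulation_config()] used for the dataset.
#' @param seed Seed controlling which rows enter the "real" split.
#' @return A list with elements `real`, `external`, `validation`.
#' @export
split_experiment <- function(dataset, design, config = simulation_config(),
                             seed = config$seed) {
  n <- nrow(dataset$values)
  need <- config$n_validation + config$n_external + design$n_controls + design$n_cases
  assert_that(n >= need,
              sprintf("dataset has %d samples but the splits require %d", n, need))
  idx_val <- seq_len(config$n_validation)
  idx_ext <- config$n_validation + seq_len(config$n_external)
  pool <- setdiff(seq_len(n), c(idx_val, idx_ext))

  eid <- design$experiment_id
  if (is.null(eid) || is.na(eid)) eid <- 0L
  set.seed(derive_seed(seed, eid))
  pool_lab <- dataset$labels[pool]
  ctrl_pool <- pool[pool_lab == "control"]
  case_pool <- pool[pool_lab == "case"]
  assert_that(length(ctrl_pool) >= design$n_controls &&
                length(case_pool) >= design$n_cases,
              "not enough samples of each class left for the real split")
  idx_real <- c(sample(ctrl_pool, design$n_controls),
                sample(case_pool, design$n_cases))

  external <- lm_subset(dataset, idx_ext)
  external$labels <- NULL
  list(real = lm_subset(dataset, idx_real),
       external = external,
       validation = lm_subset(dataset, idx_val))
}

#' Synthetic loss traces for exercising the training heuristics
#'
#' Builds deterministic critic/generator loss traces of a given shape:
#' `"decay"` is `a * exp(-b * t) + c` with optional additive normal noise,
#' `"sawtooth"` oscillates around a level with a given amplitude,
#' `"diverging"` ramps linearly so that it first exceeds `bound` at a known
#' epoch, and `"constant"` is flat.
#'
#' @param kind One of `"decay"`, `"sawtooth"`, `"diverging"`, `"constant"`.
#' @param n_epochs Number of sampled epochs.
#' @param params Named list of shape parameters: `a`, `b`, `c`, `noise_sd`
#'   (decay); `level`, `amplitude` (sawtooth); `start`, `bound`,
#'   `cross_at` (diverging); `value` (constant).
#' @param seed Seed for the optional decay noise.
#' @param rate_save Epoch spacing of the sampled points (default 1).
#' @return A [loss_trace()].
#' @export
make_loss_trace_fixture <- function(kind, n_epochs, params = list(), seed = 1L,
                                    rate_save = 1L) {
  assert_that(n_epochs > 0, "n_epochs must be positive")
  epochs <- seq_len(n_epochs) * rate_save
  t <- epochs - epochs[1]
  critic <- switch(kind,
    decay = {
      a <- params$a %||% 10; b <- params$b %||% 0.01; c0 <- params$c %||% 1
      y <- a * exp(-b * t) + c0
      if (!is.null(params$noise_sd) && params$noise_sd > 0) {
        set.seed(seed)
        y <- y + stats::rnorm(n_epochs, sd = params$noise_sd)
      }
      y
    },
    sawtooth = {
      level <- params$level %||% 0; amp <- params$amplitude %||% 1
      level + amp * rep_len(c(1, -1), n_epochs)
    },
    diverging = {
      start <- params$start %||% 0
      bound <- params$bound %||% 15
      cross_at <- params$cross_at %||% ceiling(n_epochs / 2)
      # linear ramp calibrated so the first value > bound is at index cross_at
      step <- (bound - start) / (cross_at - 1)
      start + step * (seq_len(n_epochs) - 1) + ifelse(seq_len(n_epochs) >= cross_at,
                                                      1e-6, 0)
    },
    constant = rep(params$value %||% 0, n_epochs),
    stop("unknown loss-trace kind: ", kind)
  )
  loss_trace(epochs = epochs, critic_loss = critic,
             generator_loss = rep(0, n_epochs))
}
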