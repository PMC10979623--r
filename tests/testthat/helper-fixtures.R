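# Shared fixtures for the test suite. Everything is generated in code; the
# GAN fixtures use deliberately small networks and epoch budgets so that the
# behavioural properties (convergence direction, transfer contracts,
# determinism) can be checked quickly.

tiny_hidden <- c(6L, 8L, 10L)

tiny_hyper <- function(...) {
  gan_hyperparams(batch_size = 12L, iter_critic = 2L, dropout_prob = 0.2, ...)
}

tiny_pretrain_cfg <- function(...) {
  args <- list(max_epochs_1 = 30L, n_epochs_2 = 80L,
               lr1_candidates = c(5e-4, 1e-4),
               lr2_candidates = c(1e-4, 5e-5),
               rate_save = 10L, diff_epochs = 30L,
               batch_size = 12L, iter_critic = 2L, dropout_prob = 0.2)
  do.call(pretrain_config, utils::modifyList(args, list(...)))
}

tiny_retrain_cfg <- function(...) {
  args <- list(max_epochs_1 = 30L, n_epochs_2 = 80L,
               lr1_candidates = c(5e-4, 1e-4),
               lr2_candidates = c(1e-4, 5e-5),
               rate_save = 10L, diff_epochs = 30L,
               batch_size = c(under = 8L, over = 12L),
               iter_critic = 2L, dropout_prob = 0.2)
  do.call(retrain_config, utils::modifyList(args, list(...)))
}

# Two well-separated Gaussian clusters in few dimensions, as a labeled matrix.
two_blob_data <- function(n_per_class = 60, p = 4, shift = 4, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n_per_class * p), n_per_class, p)
  b <- matrix(stats::rnorm(n_per_class * p, mean = shift), n_per_class, p)
  labeled_matrix(rbind(a, b),
                 labels = rep(c("case", "control"), each = n_per_class),
                 feature_names = paste0("f", seq_len(p)))
}

# Numerical gradient of a scalar function of a gan_model's parameters.
numeric_param_grad <- function(model, f, l, idx, what = "W", eps = 1e-6) {
  up <- model; dn <- model
  up$layers[[l]][[what]][idx] <- up$layers[[l]][[what]][idx] + eps
  dn$layers[[l]][[what]][idx] <- dn$layers[[l]][[what]][idx] - eps
  (f(up) - f(dn)) / (2 * eps)
}

# A small imbalanced two-class dataset.
make_imbalanced <- function(n_minor = 6, n_major = 15, p = 3, seed = 2) {
  set.seed(seed)
  labeled_matrix(matrix(stats::rnorm((n_minor + n_major) * p), ncol = p),
                 labels = rep(c("case", "control"), c(n_minor, n_major)),
                 feature_names = paste0("f", seq_len(p)))
}

# Exactly separable data for a histogram tree learner: the first feature is
# two-valued by class (a held-out value always equals a training bin edge),
# the rest is uninformative noise.
two_level_data <- function(n_per_class = 25, p = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  x[, 1] <- rep(c(0, 10), each = n_per_class)
  labeled_matrix(x, labels = rep(c("case", "control"), each = n_per_class),
                 feature_names = paste0("f", seq_len(p)))
}
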