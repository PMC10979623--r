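# SELU constants (Klambauer et al. self-normalizing networks)
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) {
  out <- SELU_LAMBDA * x
  neg <- which(x <= 0)        # which() drops NaN: divergence propagates safely
  out[neg] <- SELU_LAMBDA * SELU_ALPHA * expm1(x[neg])
  out
}

selu_prime <- function(x) {
  out <- array(SELU_LAMBDA, dim = dim(x))
  neg <- which(x <= 0)
  out[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(x[neg])
  out
}

selu_second <- function(x) {
  out <- array(0, dim = dim(x))
  neg <- which(x <= 0)
  out[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(x[neg])
  out
}

# Alpha-dropout affine constants for drop probability p.
alpha_dropout_consts <- function(p) {
  ap <- -SELU_LAMBDA * SELU_ALPHA    # value dropped units are set to
  q <- 1 - p
  a <- (q + ap^2 * q * p)^(-0.5)
  list(ap = ap, a = a, b = -a * p * ap)
}

#' Network schedule for progressive growing
#'
#' Hidden-layer widths in generator order; the critic uses the same widths
#' reversed. `active_stage` gives how many hidden layers are currently
#' enabled.
#'
#' @param n_features Input/output dimensionality (feature count).
#' @param hidden_sizes Ordered hidden widths (default `c(50, 100, 200)`).
#' @param active_stage Number of enabled hidden layers (default all).
#' @return An object of class `network_schedule`.
#' @export
network_schedule <- function(n_features, hidden_sizes = c(50L, 100L, 200L),
                             active_stage = length(hidden_sizes)) {
  assert_that(n_features > 0, "n_features must be positive")
  assert_that(active_stage >= 1 && active_stage <= length(hidden_sizes),
              "active_stage must index into hidden_sizes")
  structure(list(n_features = as.integer(n_features),
                 hidden_sizes = as.integer(hidden_sizes),
                 active_stage = as.integer(active_stage)),
            class = "network_schedule")
}

#' GAN hyperparameters
#'
#' @param alpha Dispersion coefficient multiplying the log Frobenius norm of
#'   the generated batch in the generator loss (default 0).
#' @param penalty_coefficient Weight of the Lipschitz gradient penalty
#'   (default 10).
#' @param dropout_prob Alpha-dropout probability per hidden layer.
#' @param iter_critic Critic updates per generator update.
#' @param batch_size Rows per training batch.
#' @param momentum Classical SGD momentum (default 0.9). The stated
#'   learning-rate grids are small enough that momentum-free SGD makes no
#'   practical progress within the epoch budgets; 0.9 is the standard value
#'   for the momentum slot of SGD.
#' @param log_norm_penalty Use `log` of the Frobenius norm (default TRUE);
#'   disable for the raw-norm variant.
#' @param use_gradient_penalty If FALSE, enforce the Lipschitz constraint by
#'   plain weight clipping at `clip_value` instead of the gradient penalty.
#' @param clip_value Weight-clipping bound (used only when
#'   `use_gradient_penalty = FALSE`).
#' @return An object of class `gan_hyperparams`.
#' @export
gan_hyperparams <- function(alpha = 0, penalty_coefficient = 10,
                            dropout_prob = 0.5, iter_critic = 4L,
                            batch_size = 30L, momentum = 0.9,
                            log_norm_penalty = TRUE,
                            use_gradient_penalty = TRUE, clip_value = 0.01) {
  assert_that(alpha >= 0, "alpha must be non-negative")
  assert_that(penalty_coefficient >= 0, "penalty_coefficient must be non-negative")
  assert_that(dropout_prob >= 0 && dropout_prob < 1, "dropout_prob must be in [0, 1)")
  structure(list(alpha = alpha, penalty_coefficient = penalty_coefficient,
                 dropout_prob = dropout_prob, iter_critic = as.integer(iter_critic),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 log_norm_penalty = log_norm_penalty,
                 use_gradient_penalty = use_gradient_penalty,
                 clip_value = clip_value),
            class = "gan_hyperparams")
}

init_layer <- function(fan_in, fan_out) {
  # Kaiming-normal weights, zero biases
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                  fan_in, fan_out),
       b = rep(0, fan_out))
}

model_widths <- function(role, schedule) {
  s <- schedule$active_stage
  active <- schedule$hidden_sizes[seq_len(s)]
  if (role == "generator") {
    c(schedule$n_features, active, schedule$n_features)
  } else {
    c(schedule$n_features, rev(active), 1L)
  }
}

new_gan_model <- function(role, schedule) {
  widths <- model_widths(role, schedule)
  layers <- lapply(seq_len(length(widths) - 1L), function(l) {
    init_layer(widths[l], widths[l + 1L])
  })
  structure(list(role = role, schedule = schedule, layers = layers,
                 trained = FALSE),
            class = "gan_model")
}

#' Build a generator network
#'
#' Fully connected stack from an `n_features`-dimensional standard-normal
#' noise input through the active hidden layers to an `n_features` output.
#' SELU activation between layers, Kaiming-normal initialization,
#' alpha-dropout during training, no batch normalization and no output
#' activation (generated data live on an unbounded transformed scale).
#'
#' @param n_features Feature count (input and output width).
#' @param schedule A [network_schedule()]; defaults to the standard
#'   50/100/200 schedule at full depth.
#' @param hyper A [gan_hyperparams()] (records the dropout probability).
#' @return A `gan_model` object.
#' @export
build_generator <- function(n_features,
                            schedule = network_schedule(n_features),
                            hyper = gan_hyperparams()) {
  assert_that(n_features > 0, "n_features must be positive")
  new_gan_model("generator", schedule)
}

#' Build a critic network
#'
#' Mirror of [build_generator()] with the hidden widths reversed and a single
#' unbounded scalar output (no output activation).
#'
#' @inheritParams build_generator
#' @return A `gan_model` object.
#' @export
build_critic <- function(n_features,
                         schedule = network_schedule(n_features),
                         hyper = gan_hyperparams()) {
  assert_that(n_features > 0, "n_features must be positive")
  new_gan_model("critic", schedule)
}

#' @export
print.gan_model <- function(x, ...) {
  widths <- model_widths(x$role, x$schedule)
  cat(sprintf("<gan_model: %s> stage %d/%d, widths %s, %d parameters\n",
              x$role, x$schedule$active_stage, length(x$schedule$hidden_sizes),
              paste(widths, collapse = "->"), n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `gan_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Grow a model by one progressive stage
#'
#' Enables the next hidden layer. For the generator the trained hidden chain
#' is preserved bit-exactly and a fresh hidden layer plus a fresh output head
#' are appended; for the critic the trained deeper chain (towards the scalar
#' output) is preserved and a fresh input block is prepended. Layers whose
#' dimensions change at a growth event are re-initialized.
#'
#' @param model A `gan_model`.
#' @return The grown `gan_model`.
#' @export
grow_model <- function(model) {
  sched <- model$schedule
  assert_that(sched$active_stage < length(sched$hidden_sizes),
              "model is already at full depth")
  s <- sched$active_stage
  new_sched <- network_schedule(sched$n_features, sched$hidden_sizes, s + 1L)
  h <- sched$hidden_sizes
  if (model$role == "generator") {
    kept <- model$layers[seq_len(s)]                  # noise -> h1 -> ... -> h_s
    new_hidden <- init_layer(h[s], h[s + 1L])
    new_head <- init_layer(h[s + 1L], sched$n_features)
    layers <- c(kept, list(new_hidden, new_head))
  } else {
    kept <- model$layers[-1L]                         # everything after the input block
    new_input <- init_layer(sched$n_features, h[s + 1L])
    new_link <- init_layer(h[s + 1L], h[s])
    layers <- c(list(new_input, new_link), kept)
  }
  model$schedule <- new_sched
  model$layers <- layers
  model
}

# Forward pass. training = TRUE samples alpha-dropout masks after each hidden
# SELU activation and returns a cache for backpropagation.
gan_forward <- function(model, x, training = FALSE, dropout_prob = 0) {
  L <- length(model$layers)
  h <- vector("list", L)       # h[[l]] = input to layer l
  z <- vector("list", L - 1L)  # pre-activations of hidden layers
  drop <- vector("list", L - 1L)
  cur <- x
  use_drop <- training && dropout_prob > 0
  dc <- if (use_drop) alpha_dropout_consts(dropout_prob)
  for (l in seq_len(L - 1L)) {
    h[[l]] <- cur
    zl <- cur %*% model$layers[[l]]$W +
      matrix(model$layers[[l]]$b, nrow(cur), length(model$layers[[l]]$b), byrow = TRUE)
    z[[l]] <- zl
    a <- selu(zl)
    if (use_drop) {
      mask <- matrix(stats::runif(length(a)) >= dropout_prob, nrow(a), ncol(a))
      cur <- dc$a * (a * mask + dc$ap * (!mask)) + dc$b
      drop[[l]] <- dc$a * mask   # d(layer output)/d(activation)
    } else {
      cur <- a
    }
  }
  h[[L]] <- cur
  out <- cur %*% model$layers[[L]]$W +
    matrix(model$layers[[L]]$b, nrow(cur), length(model$layers[[L]]$b), byrow = TRUE)
  list(out = out, h = h, z = z, drop = drop)
}

# Derivative factor of hidden layer l output w.r.t. its pre-activation:
# dropout factor (a * mask, or 1) times selu'(z).
layer_dfactor <- function(cache, l) {
  d <- selu_prime(cache$z[[l]])
  if (!is.null(cache$drop[[l]])) d <- d * cache$drop[[l]]
  d
}

# Backpropagate an adjoint `dout` (n x out_dim) through the cached forward
# pass; returns per-layer parameter gradients and the input gradient.
gan_backward <- function(model, cache, dout) {
  L <- length(model$layers)
  grads <- vector("list", L)
  d <- dout
  grads[[L]] <- list(W = crossprod(cache$h[[L]], d), b = colSums(d))
  e <- d %*% t(model$layers[[L]]$W)
  for (l in rev(seq_len(L - 1L))) {
    d <- e * layer_dfactor(cache, l)
    grads[[l]] <- list(W = crossprod(cache$h[[l]], d), b = colSums(d))
    e <- d %*% t(model$layers[[l]]$W)
  }
  list(grads = grads, dx = e)
}

# Gradient of the critic output w.r.t. its input, per sample (n x F).
critic_input_grad <- function(model, cache) {
  gan_backward(model, cache,
               matrix(1, nrow(cache$out), 1L))$dx
}

zero_grads <- function(model) {
  lapply(model$layers, function(l) list(W = array(0, dim = dim(l$W)),
                                        b = rep(0, length(l$b))))
}

add_grads <- function(a, b) {
  Map(function(x, y) list(W = x$W + y$W, b = x$b + y$b), a, b)
}

scale_grads <- function(g, s) {
  lapply(g, function(x) list(W = x$W * s, b = x$b * s))
}

# --- stochastic gradient descent with optional classical momentum ----------

sgd_init <- function(model) zero_grads(model)

sgd_step <- function(model, grads, lr, momentum = 0, state = NULL) {
  if (is.null(state)) state <- sgd_init(model)
  for (l in seq_along(model$layers)) {
    state[[l]]$W <- momentum * state[[l]]$W + grads[[l]]$W
    state[[l]]$b <- momentum * state[[l]]$b + grads[[l]]$b
    model$layers[[l]]$W <- model$layers[[l]]$W - lr * state[[l]]$W
    model$layers[[l]]$b <- model$layers[[l]]$b - lr * state[[l]]$b
  }
  list(model = model, state = state)
}

clip_weights <- function(model, clip_value) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W <- pmin(pmax(model$layers[[l]]$W, -clip_value), clip_value)
    model$layers[[l]]$b <- pmin(pmax(model$layers[[l]]$b, -clip_value), clip_value)
  }
  model
}

#' Draw samples from a trained generator
#'
#' Feeds standard-normal noise of dimension `n_features` through the
#' generator in evaluation mode (dropout off) and, when a fitted transformer
#' is supplied, inverse-transforms the result back to the original feature
#' scale.
#'
#' @param generator A trained `gan_model` with role `"generator"`.
#' @param n Number of samples to draw.
#' @param transformer Optional [fit_transformer()] result used to map
#'   generated rows back to the data scale.
#' @param seed Optional seed; the draw is deterministic given the seed.
#' @return A [labeled_matrix()] without labels.
#' @export
generate_samples <- function(generator, n, transformer = NULL, seed = NULL) {
  assert_that(inherits(generator, "gan_model") && generator$role == "generator",
              "generator must be a gan_model with role 'generator'")
  assert_that(isTRUE(generator$trained),
              "generator has not been trained")
  assert_that(n > 0, "n must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- generator$schedule$n_features
  noise <- matrix(stats::rnorm(n * p), n, p)
  out <- gan_forward(generator, noise, training = FALSE)$out
  if (!is.null(transformer)) out <- inverse_transform_data(transformer, out)
  colnames(out) <- if (!is.null(transformer)) transformer$feature_names
  labeled_matrix(out, feature_names = colnames(out))
}
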