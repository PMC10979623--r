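test_that("generator and critic have the prescribed shapes and parameter counts", {
  set.seed(1)
  gen <- build_generator(150, network_schedule(150))
  # closed-form dense-layer arithmetic for 150 -> 50 -> 100 -> 200 -> 150
  expect_equal(n_parameters(gen),
               (150 * 50 + 50) + (50 * 100 + 100) + (100 * 200 + 200) +
                 (200 * 150 + 150))
  cri <- build_critic(150, network_schedule(150))
  widths <- vapply(cri$layers, function(l) nrow(l$W), integer(1))
  expect_equal(widths, c(150L, 200L, 100L, 50L))       # reversed hidden order
  expect_equal(ncol(cri$layers[[4]]$W), 1L)            # scalar output

  gen1 <- build_generator(150, network_schedule(150, active_stage = 1L))
  expect_length(gen1$layers, 2L)                       # first hidden + head
  expect_equal(dim(gen1$layers[[1]]$W), c(150L, 50L))
  expect_equal(dim(gen1$layers[[2]]$W), c(50L, 150L))

  expect_error(build_generator(0), "positive")
})

test_that("forward passes are finite and deterministic in evaluation mode", {
  set.seed(2)
  cri <- build_critic(10, network_schedule(10, tiny_hidden))
  x <- matrix(rnorm(50), 5, 10)
  y1 <- gan_forward(cri, x)$out
  y2 <- gan_forward(cri, x)$out
  expect_true(all(is.finite(y1)))
  expect_identical(y1, y2)
})

test_that("growing preserves the trained layers bit-exactly", {
  set.seed(3)
  sched <- network_schedule(8, tiny_hidden, active_stage = 2L)
  gen <- build_generator(8, sched)
  cri <- build_critic(8, sched)
  gen3 <- grow_model(gen)
  cri3 <- grow_model(cri)
  # generator: the hidden chain (layers 1..stage) is preserved
  expect_identical(gen3$layers[[1]], gen$layers[[1]])
  expect_identical(gen3$layers[[2]], gen$layers[[2]])
  expect_length(gen3$layers, 4L)
  # critic: everything after the input block is preserved
  expect_identical(gen3$schedule$active_stage, 3L)
  expect_identical(cri3$layers[[3]], cri$layers[[2]])
  expect_identical(cri3$layers[[4]], cri$layers[[3]])
  # frozen earlier generator layers produce identical intermediate output
  x <- matrix(rnorm(4 * 8), 4, 8)
  h_old <- gan_forward(gen, x)$h[[2]]
  h_new <- gan_forward(gen3, x)$h[[2]]
  expect_identical(h_old, h_new)
  expect_error(grow_model(gen3), "full depth")
})

test_that("loss identities hold for arbitrary finite batches", {
  expect_equal(critic_loss(c(1), c(0)), 1)
  expect_equal(critic_loss(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(critic_loss(c(0.2, 0.4), c(1.0, 0.0), penalty_term = 0.7), 0.5)
  expect_error(critic_loss(numeric(0), 1), "non-empty")

  expect_equal(generator_loss(c(1, 1), matrix(1, 2, 2), alpha = 0), -1)
  # alpha = 1, Frobenius norm of a 2x2 matrix of ones is 2
  expect_equal(generator_loss(0.5, matrix(1, 2, 2), alpha = 1), -0.5 - log(2))
  # property: identities against independent arithmetic on random batches
  set.seed(11)
  for (i in 1:20) {
    yf <- rnorm(sample(1:8, 1)); yr <- rnorm(sample(1:8, 1))
    pen <- runif(1)
    expect_equal(critic_loss(yf, yr, pen), sum(yf) / length(yf) - sum(yr) / length(yr) + pen)
    xf <- matrix(rnorm(12), 3, 4)
    a <- runif(1)
    expect_equal(generator_loss(yf, xf, a),
                 -mean(yf) - a * log(sqrt(sum(xf^2))))
  }
})

test_that("alpha = 0 reduces to the classic Wasserstein generator loss", {
  set.seed(12)
  yf <- rnorm(10); xf <- matrix(rnorm(40), 10, 4)
  expect_identical(generator_loss(yf, xf, alpha = 0), -mean(yf))
})

test_that("the generator loss strictly decreases as batch dispersion grows", {
  yf <- c(0.3, -0.2)
  xf <- matrix(rnorm(20), 5, 4)
  l1 <- generator_loss(yf, xf, alpha = 0.5)
  l2 <- generator_loss(yf, xf * 2, alpha = 0.5)
  expect_lt(l2, l1)
  expect_error(generator_loss(1, matrix(0, 2, 2), alpha = 1), "degenerate")
})

test_that("the gradient penalty matches its closed form for linear critics", {
  x_r <- matrix(rnorm(30), 10, 3)
  x_f <- matrix(rnorm(30), 10, 3)
  # unit-norm linear critic: gradient norm 1 everywhere -> zero penalty
  w <- c(1, 0, 0)
  expect_equal(lipschitz_penalty(linear_critic(w), x_r, x_f, lambda = 10, seed = 1), 0)
  # norm-3 linear critic: penalty = lambda * (3 - 1)^2
  w3 <- c(3, 0, 0)
  expect_equal(lipschitz_penalty(linear_critic(w3), x_r, x_f, lambda = 10, seed = 1), 40)
  expect_equal(lipschitz_penalty(linear_critic(w3), x_r, x_f, lambda = 0), 0)
  expect_error(lipschitz_penalty(linear_critic(w), x_r, x_f, lambda = -1),
               "non-negative")
})

test_that("penalty parameter gradients agree with finite differences", {
  set.seed(21)
  cri <- build_critic(3, network_schedule(3, c(4L, 5L)))
  x <- matrix(rnorm(18), 6, 3)
  lam <- 10
  pg <- ganbalance:::penalty_param_grads(cri, x, lam)
  pen_value <- function(model) {
    cache <- ganbalance:::gan_forward(model, x)
    g <- ganbalance:::critic_input_grad(model, cache)
    lam * mean((sqrt(rowSums(g^2)) - 1)^2)
  }
  expect_equal(pg$value, pen_value(cri))
  for (l in seq_along(cri$layers)) {
    nW <- length(cri$layers[[l]]$W)
    for (idx in sample(nW, min(4, nW))) {
      num <- numeric_param_grad(cri, pen_value, l, idx, "W")
      expect_equal(pg$grads[[l]]$W[idx], num, tolerance = 1e-5)
    }
    for (idx in seq_along(cri$layers[[l]]$b)) {
      num <- numeric_param_grad(cri, pen_value, l, idx, "b")
      expect_equal(pg$grads[[l]]$b[idx], num, tolerance = 1e-5)
    }
  }
})

test_that("plain backpropagation agrees with finite differences", {
  set.seed(22)
  cri <- build_critic(4, network_schedule(4, c(5L, 6L)))
  x <- matrix(rnorm(24), 6, 4)
  cache <- ganbalance:::gan_forward(cri, x)
  bp <- ganbalance:::gan_backward(cri, cache, matrix(1 / 6, 6, 1))
  f <- function(model) mean(ganbalance:::gan_forward(model, x)$out)
  for (l in seq_along(cri$layers)) {
    nW <- length(cri$layers[[l]]$W)
    for (idx in sample(nW, min(4, nW))) {
      expect_equal(bp$grads[[l]]$W[idx],
                   numeric_param_grad(cri, f, l, idx, "W"), tolerance = 1e-5)
    }
  }
  # input gradient against finite differences
  g <- ganbalance:::critic_input_grad(cri, cache)
  eps <- 1e-6
  x1 <- x; x1[2, 3] <- x1[2, 3] + eps
  x2 <- x; x2[2, 3] <- x2[2, 3] - eps
  num <- (ganbalance:::gan_forward(cri, x1)$out[2] -
            ganbalance:::gan_forward(cri, x2)$out[2]) / (2 * eps)
  expect_equal(g[2, 3], num, tolerance = 1e-5)
})

test_that("generated samples are finite, shaped, and seed-deterministic", {
  set.seed(30)
  gen <- build_generator(6, network_schedule(6, tiny_hidden))
  expect_error(generate_samples(gen, 5), "not been trained")
  gen$trained <- TRUE
  s1 <- generate_samples(gen, 30, seed = 7)
  s2 <- generate_samples(gen, 30, seed = 7)
  expect_equal(dim(s1$values), c(30L, 6L))
  expect_true(all(is.finite(s1$values)))
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, generate_samples(gen, 30, seed = 8)$values))
})

test_that("an identity generator exposes the inverse-transform path", {
  # a pass-through "generator" (identity weights) turns generate_samples into
  # inverse_transform(noise): verifies the scaling path composition
  set.seed(31)
  x <- cbind(a = rnorm(100, 5, 2), b = rexp(100))
  plan <- choose_feature_transforms(x)
  tf <- fit_transformer(x, plan)
  sched <- network_schedule(2, c(2L), active_stage = 1L)
  gen <- build_generator(2, sched)
  # identity map: SELU is identity for positive inputs scaled by lambda;
  # use weights that undo the SELU gain
  gen$layers[[1]]$W <- diag(2) / ganbalance:::SELU_LAMBDA
  gen$layers[[1]]$b <- c(10, 10)      # push pre-activations positive
  gen$layers[[2]]$W <- diag(2)
  gen$layers[[2]]$b <- rep(-10 * ganbalance:::SELU_LAMBDA, 2)
  gen$trained <- TRUE
  out <- generate_samples(gen, 50, transformer = tf, seed = 3)
  set.seed(3)
  noise <- matrix(rnorm(50 * 2), 50, 2)
  expected <- inverse_transform_data(tf, noise)
  expect_equal(unname(out$values), unname(expected), tolerance = 1e-6)
})
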