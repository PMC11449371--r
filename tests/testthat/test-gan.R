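# Hand-constructed critics for closed-form checks: a single linear
# layer D(x) = x %*% w + b.
linear_critic <- function(w, b = 0) {
  w <- matrix(w, ncol = 1)
  list(W = list(w), b = list(b), sizes = c(nrow(w), 1L))
}

test_that("gradient penalty matches hand-computed critics", {
  set.seed(1)
  xr <- matrix(rnorm(12), 3, 4)
  xf <- matrix(rnorm(12), 3, 4)
  # unit-norm gradient everywhere -> penalty 0
  w <- c(1, 0, 0, 0)
  expect_equal(gradient_penalty(linear_critic(w), xr, xf, seed = 2), 0)
  # D = 0 -> (0 - 1)^2 = 1
  expect_equal(gradient_penalty(linear_critic(rep(0, 4)), xr, xf, seed = 2), 1)
  # D = 3 x1 -> (3 - 1)^2 = 4
  expect_equal(gradient_penalty(linear_critic(c(3, 0, 0, 0)), xr, xf,
                                seed = 2), 4)
  expect_error(gradient_penalty(linear_critic(w), xr, xf[1:2, ]),
               "identical shapes")
})

test_that("WGAN-GP losses satisfy their algebraic identities", {
  set.seed(2)
  xr <- matrix(rnorm(20), 4, 5)
  # D = 0, lambda 10: critic loss = 10 * 1, generator loss = 0
  l <- wgan_gp_loss(linear_critic(rep(0, 5)), xr, xr + rnorm(20),
                    lambda_gp = 10, seed = 1)
  expect_equal(l$critic_loss, 10)
  expect_equal(l$generator_loss, 0)
  # unit-norm linear critic on identical batches: all terms vanish
  w <- rep(1 / sqrt(5), 5)
  l2 <- wgan_gp_loss(linear_critic(w), xr, xr, lambda_gp = 10, seed = 1)
  expect_equal(l2$critic_loss, 0)
  # identical batches cancel the Wasserstein terms under any critic
  set.seed(3)
  net <- ganex:::mlp_init(c(5, 7, 1), seed = 4)
  l3 <- wgan_gp_loss(net, xr, xr, lambda_gp = 10, seed = 1)
  expect_equal(l3$critic_loss, 10 * l3$penalty, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(5)
  net <- ganex:::mlp_init(c(3, 5, 4, 1), seed = 6)
  X <- matrix(rnorm(4 * 3), 4, 3)
  h <- 1e-6

  # plain backward pass on f(theta) = sum D(X)
  cache <- ganex:::mlp_forward(net, X)
  g <- ganex:::mlp_backward(net, cache, matrix(1, 4, 1))
  f <- function(n) sum(ganex:::mlp_forward(n, X)$out)
  for (l in 1:3) {
    i <- sample(length(net$W[[l]]), 1)
    n2 <- net; n2$W[[l]][i] <- n2$W[[l]][i] + h
    expect_equal((f(n2) - f(net)) / h, g$W[[l]][i], tolerance = 1e-4)
  }

  # input gradient agrees with perturbing one input coordinate
  gi <- ganex:::mlp_input_grad(net, cache)
  X2 <- X; X2[2, 3] <- X2[2, 3] + h
  expect_equal((f_row <- (ganex:::mlp_forward(net, X2)$out[2] -
                            cache$out[2]) / h), gi[2, 3], tolerance = 1e-4)

  # double-backprop penalty gradient
  pg <- ganex:::mlp_penalty_grads(net, X)
  pen <- function(n) {
    cc <- ganex:::mlp_forward(n, X)
    G <- ganex:::mlp_input_grad(n, cc)
    mean((sqrt(rowSums(G^2)) - 1)^2)
  }
  for (l in 1:3) {
    i <- sample(length(net$W[[l]]), 1)
    n2 <- net; n2$W[[l]][i] <- n2$W[[l]][i] + h
    expect_equal((pen(n2) - pg$penalty) / h, pg$W[[l]][i], tolerance = 1e-4)
    j <- sample(length(net$b[[l]]), 1)
    n3 <- net; n3$b[[l]][j] <- n3$b[[l]][j] + h
    expect_equal((pen(n3) - pg$penalty) / h, pg$b[[l]][j], tolerance = 1e-4)
  }
})

test_that("training runs to completion with finite losses and checkpoints", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_s3_class(fit, "wgan")
  expect_length(fit$generators, 3L)
  expect_true(all(is.finite(fit$log$critic_loss)))
  expect_true(all(is.finite(fit$log$gen_loss)))
  expect_true(all(fit$log$penalty >= 0))
  out <- simulate(fit, nsim = 5, seed = 1)
  expect_equal(dim(out), c(5L, 40L))
  expect_true(all(is.finite(out)))
  # every checkpoint generator produces finite output of gene length
  for (cp in seq_along(fit$generators)) {
    o <- simulate(fit, nsim = 2, seed = 2, checkpoint = cp)
    expect_true(all(is.finite(o)))
    expect_equal(ncol(o), 40L)
  }
})

test_that("training is bitwise reproducible under a fixed seed", {
  x <- tiny_expr(n_genes = 12, per_group = 3, seed = 8)
  f1 <- wgan(x, latent_dim = 3, hidden = 8, total_steps = 40,
             batch_size = 6, n_checkpoints = 2, seed = 99)
  f2 <- wgan(x, latent_dim = 3, hidden = 8, total_steps = 40,
             batch_size = 6, n_checkpoints = 2, seed = 99)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$generators, f2$generators)
})

test_that("generation quality reports the best-match gate faithfully", {
  tf <- tiny_fit()
  fit <- tf$fit
  # a generated profile used as the "real" target recovers r = 1
  target <- simulate(fit, nsim = 50, seed = 7)[17, ]
  q <- generation_quality(fit, matrix(target, ncol = 1), n_draws = 50,
                          seed = 7)
  expect_equal(unname(q$best_r), 1, tolerance = 1e-12)
  # Pearson best-match is invariant to affine rescaling of the target
  q1 <- generation_quality(fit, tf$x, n_draws = 100, seed = 3)
  resc <- tf$x
  resc$values <- 3 * resc$values + 7
  q2 <- generation_quality(fit, resc, n_draws = 100, seed = 3)
  expect_equal(q1$best_r, q2$best_r, tolerance = 1e-12)
  expect_true(is.finite(q1$mean_cor) && is.finite(q1$var_cor))
})
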