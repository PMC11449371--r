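test_that("latent interpolation is exact for a linear generator", {
  set.seed(1)
  W <- matrix(rnorm(3 * 8), 3, 8)
  fit <- linear_fit(W)
  z_sn <- rnorm(3); z_cn <- rnorm(3)
  traj <- interpolate_pair(fit, z_sn, z_cn, steps = 99)
  expect_equal(dim(traj), c(101L, 8L))
  g_sn <- drop(matrix(z_sn, 1) %*% W)
  g_cn <- drop(matrix(z_cn, 1) %*% W)
  # row i is the exact feature-space convex combination
  for (i in c(0, 1, 37, 50, 99, 100)) {
    f <- i / 100
    expect_equal(unname(traj[as.character(i), ]),
                 (1 - f) * g_sn + f * g_cn, tolerance = 1e-12)
  }
  # endpoints are exactly the generated anchors
  expect_equal(unname(traj["0", ]), g_sn)
  expect_equal(unname(traj["100", ]), g_cn)
  # zero delta: all rows identical
  same <- interpolate_pair(fit, z_sn, z_sn)
  expect_true(all(abs(sweep(same, 2, same[1, ])) < 1e-12))
  expect_error(interpolate_pair(fit, z_sn, rnorm(2)), "length")
})

test_that("resembled fakes recover a planted latent for an invertible map", {
  set.seed(2)
  # orthonormal-column W: Pearson(G(z), G(z*)) peaks near z = z*
  W <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  fit <- linear_fit(t(W))            # latent dim 2, genes 20
  z_star <- c(1.2, -0.7)
  target <- drop(matrix(z_star, 1) %*% t(W))
  rf <- resembled_fake(fit, target, n_candidates = 5000, k = 5,
                       threshold = 0.9, seed = 3)
  expect_gte(rf$achieved_r, 0.97)
  expect_true(all(rf$contributing_r >= 0.9))
  # degenerate parameters: k = 1, no threshold -> the single best candidate
  rf1 <- resembled_fake(fit, target, n_candidates = 500, k = 1,
                        threshold = 0, seed = 4)
  expect_equal(unname(rf1$achieved_r), unname(rf1$contributing_r[1]),
               tolerance = 1e-12)
  # determinism
  rf2 <- resembled_fake(fit, target, n_candidates = 500, k = 1,
                        threshold = 0, seed = 4)
  expect_identical(rf1$z_bar, rf2$z_bar)
  # an unreachable threshold fails loudly with the best r attained
  expect_error(resembled_fake(fit, target * 0 + seq_len(20),
                              n_candidates = 50, k = 5, threshold = 0.9999,
                              max_retries = 1, seed = 5),
               "best r attained")
})

test_that("trajectory averaging honors pair combinatorics and endpoints", {
  set.seed(6)
  W <- matrix(rnorm(4 * 12), 4, 12)
  fit <- linear_fit(W, checkpoints = 2)
  vals <- t(rbind(matrix(rnorm(2 * 4), 2) %*% W + 0.01 * rnorm(24),
                  matrix(rnorm(3 * 4), 3) %*% W + 2 + 0.01 * rnorm(36)))
  dimnames(vals) <- list(fit$gene_ids, paste0("s", 1:5))
  x <- expr_matrix(vals, group = c("SN", "SN", "CN", "CN", "CN"))
  st <- average_profile(fit, x, n_candidates = 3000, k = 3, threshold = 0,
                        seed = 8)
  expect_equal(dim(st$stack), c(2L, 101L, 12L))
  expect_equal(nrow(st$fakes), 2 * 5)      # per checkpoint, per sample
  # 2 SN x 3 CN pairs enter each repeat
  expect_equal(length(st$pairs$sn) * length(st$pairs$cn), 6L)
  # pair-replica mode: repeat axis = pairs, same mean profile
  st2 <- average_profile(fit, x, n_candidates = 3000, k = 3, threshold = 0,
                         repeat_axis = "pair", seed = 8)
  expect_equal(dim(st2$stack), c(6L, 101L, 12L))
  expect_equal(st2$profile, st$profile, tolerance = 1e-10)
  # linear generator: endpoint rows equal the group means of the fakes
  fk <- st$fakes[st$fakes$checkpoint == 1, ]
  expect_true(all(fk$achieved_r > 0.9))
})

test_that("a single pair reduces to plain interpolation", {
  set.seed(9)
  W <- matrix(rnorm(3 * 10), 3, 10)
  fit <- linear_fit(W)
  vals <- t(matrix(rnorm(2 * 3), 2) %*% W)
  dimnames(vals) <- list(fit$gene_ids, c("a", "b"))
  x <- expr_matrix(vals, group = c("SN", "CN"))
  st <- average_profile(fit, x, n_candidates = 2000, k = 2, threshold = 0,
                        seed = 10)
  expect_equal(dim(st$stack)[1], 1L)
  # the repeat equals interpolate_pair of the two fake latents, bit-exact
  fks <- ganex:::resembled_fakes_at(fit, x$values, 1, 2000, 2, 0, 5,
                                    ganex:::child_seed(10, 1))$fakes
  traj <- interpolate_pair(fit, fks[["a"]]$z_bar, fks[["b"]]$z_bar)
  expect_equal(st$profile, traj, tolerance = 1e-12)
})

test_that("a trained nonlinear generator departs from feature-space interpolation", {
  tf <- tiny_fit()
  x <- tf$x
  st <- average_profile(tf$fit, x, n_candidates = 4000, k = 3,
                        threshold = 0, seed = 11)
  # feature-space linear interpolation of the profile's own endpoints
  prof <- averaged_profile(st)
  lin <- sapply(seq_len(ncol(prof)), function(j)
    seq(prof[1, j], prof[101, j], length.out = 101))
  expect_gt(max(abs(prof - lin)), 1e-3)
})
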