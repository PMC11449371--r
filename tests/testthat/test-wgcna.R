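test_that("adjacency matches the brute-force correlation power", {
  set.seed(1)
  X <- matrix(rnorm(15 * 12), 15, 12)
  A <- adjacency(X, beta = 6)
  # two-pass brute force per pair
  for (i in 1:12) for (j in 1:12) {
    xi <- X[, i]; xj <- X[, j]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expected <- if (i == j) 1 else abs(r)^6
    expect_equal(A[i, j], expected, tolerance = 1e-12)
  }
  # perfectly anticorrelated pair is fully connected in unsigned mode
  Y <- cbind(a = 1:7, b = -(1:7) + 0.5)
  expect_equal(adjacency(Y, beta = 6)["a", "b"], 1)
  # ... and disconnected in signed mode
  expect_lt(adjacency(Y, beta = 6, type = "signed")["a", "b"], 1e-10)
  expect_error(adjacency(cbind(1:5, rep(1, 5)), 6), "zero-variance")
  # independent noise decays to zero under large powers
  set.seed(2)
  N <- matrix(rnorm(50 * 40), 50, 40)
  An <- adjacency(N, beta = 12)
  expect_lt(max(An[upper.tri(An)]), 0.05)
})

test_that("topological overlap equals the triple-loop definition", {
  # isolated nodes
  A0 <- diag(4)
  expect_equal(tom(A0), diag(4))
  # fully connected triangle with unit adjacencies
  A1 <- matrix(1, 3, 3)
  expect_equal(tom(A1)[1, 2], 1)
  # random symmetric adjacency vs brute force
  set.seed(3)
  n <- 20
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  W <- tom(A)
  Wb <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    Wb[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  expect_lt(max(abs(W - Wb)), 1e-10)
  expect_true(all(W >= 0 & W <= 1 + 1e-12))
  expect_error(tom(matrix(runif(9), 3)), "symmetric")
})

test_that("soft-threshold selection falls back sanely and k decreases in beta", {
  syn <- make_synthetic(seed = 1)
  prof <- truth_profile(syn$truth, seed = 2)
  sft <- pick_soft_threshold(prof)
  expect_true(sft$beta %in% sft$fit_table$power)
  expect_gte(sft$beta, if (sft$met_target) 1L else 6L)
  expect_true(all(diff(sft$fit_table$mean_k) <= 1e-8))
  # all-identical profiles: adjacency is 1 everywhere, degenerate fit
  ident <- matrix(rep(sin(1:20), 12), 20) +
    matrix(rnorm(240, sd = 1e-8), 20)
  sft2 <- suppressWarnings(pick_soft_threshold(
    ident, network_config(network_type = "unsigned")))
  expect_false(sft2$met_target)
  expect_gte(sft2$beta, 6L)
})

test_that("module detection separates blocks and respects size thresholds", {
  # block-diagonal similarity: two perfect blocks
  W <- diag(20) * 0 + kronecker(diag(2), matrix(1, 10, 10)) * 0.95
  diag(W) <- 1
  dimnames(W) <- list(paste0("g", 1:20), paste0("g", 1:20))
  mods <- detect_modules(W, network_config(min_module_size = 5))
  expect_equal(length(mods$sizes), 2L)
  expect_equal(unname(as.integer(mods$sizes)), c(10L, 10L))
  expect_true(all(mods$module[1:10] == mods$module[1]))
  expect_true(all(mods$module[11:20] == mods$module[11]))
  expect_true(mods$module[1] != mods$module[11])
  # threshold dominance: min size above all blocks leaves all unassigned
  mods0 <- detect_modules(W, network_config(min_module_size = 11))
  expect_true(all(mods0$module == 0L))
  # permutation equivariance
  perm <- sample(20)
  mp <- detect_modules(W[perm, perm], network_config(min_module_size = 5))
  expect_equal(unname(mp$module[colnames(W)]), unname(mods$module))
})

test_that("planted modules are recovered on the trajectory profile", {
  syn <- make_synthetic(seed = 7)
  prof <- truth_profile(syn$truth, noise_sd = 0.1, seed = 1)
  cfg <- network_config()
  sft <- pick_soft_threshold(prof, cfg)
  mods <- detect_modules(tom(adjacency(prof, sft$beta, cfg$network_type)),
                         cfg)
  ari <- rand_adjusted(syn$truth$module_of_gene, mods$module)
  expect_gte(ari, 0.9)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(syn$truth$module_of_gene,
                                                mods$module),
                 tolerance = 1e-12)
  }
})

test_that("eigengenes agree with a full decomposition and orient coherently", {
  # rank-1 block: eigengene proportional to the latent activity
  set.seed(7)
  u <- sin(seq(0, 3, length.out = 30))
  v <- runif(8, 0.5, 1.5)
  X <- outer(u, v)
  colnames(X) <- paste0("g", 1:8)
  assign <- setNames(rep(1L, 8), colnames(X))
  eg <- module_eigengenes(X, assign)
  expect_equal(eg$var_explained[["ME1"]], 1, tolerance = 1e-12)
  expect_gt(abs(cor(eg$eigengenes[, 1], u)), 1 - 1e-10)
  # orientation: correlates non-negatively with the module mean
  expect_gte(cor(eg$eigengenes[, 1], rowMeans(scale(X))), 0)
  # full-decomposition oracle (eigen of the correlation matrix)
  Xn <- X + matrix(rnorm(240, sd = 0.3), 30)
  eg2 <- module_eigengenes(Xn, assign)
  Z <- scale(Xn)
  ev <- eigen(crossprod(Z))
  scores <- Z %*% ev$vectors[, 1]
  scores <- scores / sd(scores)
  expect_lt(min(max(abs(eg2$eigengenes[, 1] - scores)),
                max(abs(eg2$eigengenes[, 1] + scores))), 1e-8)
  # negating every gene flips the oriented eigengene coherently
  eg3 <- module_eigengenes(-Xn, assign)
  expect_equal(eg3$eigengenes[, 1], -eg2$eigengenes[, 1], tolerance = 1e-8)
  # single-gene module: the standardized gene itself
  eg1 <- module_eigengenes(Xn[, 1, drop = FALSE],
                           setNames(1L, colnames(Xn)[1]))
  expect_equal(unname(eg1$eigengenes[, 1]), as.numeric(scale(Xn[, 1])))
})

test_that("trait alignment applies the stated criteria and guards", {
  syn <- make_synthetic(seed = 8)
  prof <- truth_profile(syn$truth, seed = 9)
  cfg <- network_config()
  sft <- pick_soft_threshold(prof, cfg)
  mods <- detect_modules(tom(adjacency(prof, sft$beta, cfg$network_type)),
                         cfg)
  eig <- module_eigengenes(prof, mods)
  al <- module_trait_alignment(mods, syn$expr, syn$traits,
                               sim_loadings = eig)
  expect_true(all(abs(al$r) <= 1))
  expect_true(all(al$p >= 0 & al$p <= 1))
  expect_equal(al$passes, al$p < 0.05 & abs(al$r) > 0.5)
  # the module carrying the planted trait module passes
  tm_genes <- names(syn$truth$module_of_gene)[
    syn$truth$module_of_gene == syn$truth$trait_module]
  ov <- table(mods$module[tm_genes])
  best <- as.integer(names(ov)[which.max(ov)])
  expect_true(al$passes[al$module == best])
  # degenerate trait is an error, not NaN
  expect_error(module_trait_alignment(mods, syn$expr,
                                      setNames(rep(0, 24),
                                               syn$expr$sample_ids)),
               "zero variance")
  few <- ganex:::subset_samples(syn$expr, 1:3)
  expect_error(module_trait_alignment(mods, few, syn$traits), "at least 4")
})

test_that("the correlation p-value follows the exact t transform", {
  # r = 0 gives p = 1; build a trait exactly orthogonal to the eigengene
  set.seed(10)
  n <- 10
  g <- rnorm(n)
  tr0 <- runif(n, 1, 3)
  gc <- g - mean(g)
  tr_orth <- tr0 - gc * sum(gc * (tr0 - mean(tr0))) / sum(gc^2)
  tr <- setNames(tr_orth, paste0("s", 1:n))
  vals <- rbind(g1 = g, g2 = g) + 5
  colnames(vals) <- names(tr)
  x <- expr_matrix(vals, group = rep(c("SN", "CN"), each = 5))
  al <- module_trait_alignment(setNames(c(1L, 1L), c("g1", "g2")), x, tr)
  expect_equal(al$p, 2 * pt(-abs(al$r * sqrt(8) / sqrt(1 - al$r^2)), 8),
               tolerance = 1e-12)
  expect_equal(al$r, 0, tolerance = 1e-10)
  expect_gt(al$p, 1 - 1e-8)
})
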