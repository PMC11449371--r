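# Shared fixtures, built in code.

# Small two-group expression matrix with an obvious structure.
tiny_expr <- function(n_genes = 30, per_group = 4, seed = 1) {
  set.seed(seed)
  grp <- rep(c("SN", "CN"), each = per_group)
  shift <- ifelse(grp == "CN", 2, 0)
  vals <- matrix(rnorm(n_genes * length(grp), mean = 5), n_genes,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_along(grp))))
  k <- min(10, n_genes)
  vals[seq_len(k), ] <- vals[seq_len(k), ] + rep(shift, each = k)
  expr_matrix(vals, group = grp)
}

# A small trained WGAN-GP on structured toy data, trained once per test
# run and memoized (several test files probe it).
tiny_fit_cache <- new.env()
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    x <- tiny_expr(n_genes = 40, per_group = 6, seed = 3)
    aug <- linear_augment(x, fold = 5, seed = 4)
    tiny_fit_cache$fit <- wgan(aug, latent_dim = 4, hidden = c(16, 16),
                               total_steps = 300, batch_size = 16,
                               n_checkpoints = 3, seed = 5)
    tiny_fit_cache$x <- x
  }
  list(fit = tiny_fit_cache$fit, x = tiny_fit_cache$x)
}

# A "wgan" object wrapping an exactly linear generator G(z) = z %*% W,
# for closed-form interpolation oracles.
linear_fit <- function(W, checkpoints = 1) {
  d <- nrow(W); g <- ncol(W)
  net <- list(W = list(W), b = list(rep(0, g)), sizes = c(d, g))
  structure(list(
    generators = rep(list(net), checkpoints),
    critic = NULL,
    log = data.frame(),
    config = list(latent_dim = d, hidden = integer(), lambda_gp = 10,
                  critic_steps = 5L, lr = 1e-4, total_steps = 0L,
                  batch_size = 1L, checkpoint_steps = seq_len(checkpoints),
                  quality_threshold = 0.95, standardize = FALSE, seed = 1L),
    center = rep(0, g), scale = rep(1, g),
    gene_ids = paste0("g", seq_len(g)), n_genes = g), class = "wgan")
}

# Adjusted Rand index between two labelings (used to score recovery of
# the planted partition against an external implementation-free formula).
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
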