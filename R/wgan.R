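#' Fit a WGAN-GP generative model of expression profiles
#'
#' Trains a Wasserstein generative adversarial network with gradient
#' penalty on (typically augmented) log-scale expression profiles.  The
#' critic is updated `critic_steps` times per generator update using the
#' loss `mean D(fake) - mean D(real) + lambda_gp * penalty`, where the
#' penalty is the squared deviation from 1 of the critic's gradient norm
#' at random interpolates between real and fake batches; the generator
#' maximizes `mean D(fake)`.  Both networks are fully connected with
#' tanh hidden layers, optimized with RMSprop.  Generator snapshots are
#' kept at `checkpoint_steps` (by default 10 evenly spaced steps over
#' the second half of training) and later serve as the independent
#' repeats of the trajectory simulation.
#'
#' Profiles are standardized gene-wise before training by default
#' (generated output is returned in original units); this keeps the
#' network inputs/outputs in a numerically comfortable range regardless
#' of the expression scale.
#'
#' @param x an [expr_matrix()] or a genes x samples numeric matrix, on a
#'   log scale, usually after [linear_augment()].
#' @param latent_dim dimension of the latent prior `z ~ N(0, I)`.
#' @param hidden integer vector of hidden-layer widths shared by the
#'   generator and critic.
#' @param lambda_gp gradient-penalty weight.
#' @param critic_steps critic updates per generator update.
#' @param lr RMSprop learning rate.
#' @param total_steps number of generator updates.
#' @param batch_size minibatch size (capped at the sample count).
#' @param checkpoint_steps generator steps at which snapshots are kept;
#'   default `round(seq(0.5, 1, length.out = n_checkpoints) * total_steps)`.
#' @param n_checkpoints number of default checkpoints.
#' @param quality_threshold Pearson gate used downstream when matching
#'   generated profiles to real samples.
#' @param standardize standardize genes before training.
#' @param seed integer seed; the full run is reproducible.
#' @param verbose print progress every 10% of training.
#'
#' @return An object of class `"wgan"`: list with `generators` (one
#'   parameter set per checkpoint), `critic`, `log` (per-step losses),
#'   `config`, `center`/`scale`, `gene_ids`.
#' @seealso [simulate.wgan()], [generation_quality()], [average_profile()]
#' @export
wgan <- function(x, latent_dim = 32L, hidden = c(128L, 128L), lambda_gp = 10,
                 critic_steps = 5L, lr = 1e-4, total_steps = 2000L,
                 batch_size = 32L, checkpoint_steps = NULL,
                 n_checkpoints = 10L, quality_threshold = 0.95,
                 standardize = TRUE, seed = 1L, verbose = FALSE) {
  vals <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (latent_dim < 2L) stopf("latent_dim must be >= 2")
  if (lambda_gp <= 0) stopf("lambda_gp must be > 0")
  if (quality_threshold <= 0 || quality_threshold > 1)
    stopf("quality_threshold must be in (0, 1]")
  n_genes <- nrow(vals)
  n_samp <- ncol(vals)
  if (n_samp < 2L) stopf("need at least 2 training samples")
  batch_size <- min(as.integer(batch_size), n_samp)
  checkpoint_steps <- as.integer(checkpoint_steps %||%
    unique(round(seq(0.5, 1, length.out = n_checkpoints) * total_steps)))
  if (is.unsorted(checkpoint_steps)) stopf("checkpoint_steps must be ascending")
  if (max(checkpoint_steps) > total_steps)
    stopf("checkpoint_steps exceed total_steps")

  X <- t(vals)                               # samples in rows
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ < 1e-8] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  } else {
    center <- rep(0, n_genes); scale_ <- rep(1, n_genes)
  }

  with_seed(seed, {
    G <- mlp_init(c(latent_dim, hidden, n_genes))
    D <- mlp_init(c(n_genes, hidden, 1L))
    stG <- rmsprop_init(G)
    stD <- rmsprop_init(D)
    log_step <- integer(total_steps)
    log_c <- log_g <- log_p <- numeric(total_steps)
    gens <- vector("list", length(checkpoint_steps))
    names(gens) <- checkpoint_steps

    for (step in seq_len(total_steps)) {
      closs <- pen <- NA_real_
      for (k in seq_len(critic_steps)) {
        idx <- sample.int(n_samp, batch_size, replace = batch_size > n_samp)
        xr <- X[idx, , drop = FALSE]
        z <- matrix(stats::rnorm(batch_size * latent_dim), batch_size)
        xf <- mlp_forward(G, z)$out
        # Wasserstein terms: one pass over [fake; real] with signed dout
        both <- rbind(xf, xr)
        cache <- mlp_forward(D, both)
        dout <- matrix(c(rep(1 / batch_size, batch_size),
                         rep(-1 / batch_size, batch_size)), ncol = 1L)
        gD <- mlp_backward(D, cache, dout)
        epsm <- stats::runif(batch_size)
        xhat <- epsm * xr + (1 - epsm) * xf
        pg <- mlp_penalty_grads(D, xhat)
        gD <- add_grads(gD, pg, scale = lambda_gp)
        pen <- pg$penalty
        sc <- cache$out
        closs <- mean(sc[seq_len(batch_size)]) -
          mean(sc[batch_size + seq_len(batch_size)]) + lambda_gp * pen
        if (!is.finite(closs))
          stopf("critic loss diverged (non-finite) at step %d", step)
        upd <- rmsprop_step(D, gD, stD, lr)
        D <- upd$net; stD <- upd$state
      }
      # generator update: minimize -mean D(G(z))
      z <- matrix(stats::rnorm(batch_size * latent_dim), batch_size)
      gc_ <- mlp_forward(G, z)
      dc <- mlp_forward(D, gc_$out)
      dxf <- mlp_backward(D, dc,
                          matrix(-1 / batch_size, batch_size, 1L))$dx
      gG <- mlp_backward(G, gc_, dxf)
      gloss <- -mean(dc$out)
      if (!is.finite(gloss))
        stopf("generator loss diverged (non-finite) at step %d", step)
      upd <- rmsprop_step(G, gG, stG, lr)
      G <- upd$net; stG <- upd$state

      log_step[step] <- step
      log_c[step] <- closs; log_g[step] <- gloss; log_p[step] <- pen
      if (step %in% checkpoint_steps)
        gens[[as.character(step)]] <- G
      if (verbose && step %% max(1L, total_steps %/% 10L) == 0L)
        msgf(TRUE, "step %d/%d critic %.4f gen %.4f penalty %.4f",
             step, total_steps, closs, gloss, pen)
    }

    structure(list(
      generators = gens, critic = D,
      log = data.frame(step = log_step, critic_loss = log_c,
                       gen_loss = log_g, penalty = log_p),
      config = list(latent_dim = as.integer(latent_dim), hidden = hidden,
                    lambda_gp = lambda_gp, critic_steps = critic_steps,
                    lr = lr, total_steps = as.integer(total_steps),
                    batch_size = batch_size,
                    checkpoint_steps = checkpoint_steps,
                    quality_threshold = quality_threshold,
                    standardize = standardize, seed = seed),
      center = center, scale = scale_,
      gene_ids = rownames(vals) %||% paste0("gene", seq_len(n_genes)),
      n_genes = n_genes), class = "wgan")
  })
}

#' @export
print.wgan <- function(x, ...) {
  cat(sprintf(
    "wgan fit: %d genes, latent dim %d, hidden (%s)\n%d generator steps (%d critic steps each), %d checkpoints\n",
    x$n_genes, x$config$latent_dim, paste(x$config$hidden, collapse = ", "),
    x$config$total_steps, x$config$critic_steps, length(x$generators)))
  tail_log <- utils::tail(x$log, 1L)
  cat(sprintf("final losses: critic %.4f, generator %.4f, penalty %.4f\n",
              tail_log$critic_loss, tail_log$gen_loss, tail_log$penalty))
  invisible(x)
}

#' @export
summary.wgan <- function(object, ...) {
  s <- list(config = object$config,
            n_checkpoints = length(object$generators),
            loss_tail = utils::tail(object$log, 5L))
  class(s) <- "summary.wgan"
  s
}

#' @export
print.summary.wgan <- function(x, ...) {
  cat("WGAN-GP fit\n")
  cat(sprintf("  latent dim %d, lambda_gp %g, lr %g, batch %d\n",
              x$config$latent_dim, x$config$lambda_gp, x$config$lr,
              x$config$batch_size))
  cat(sprintf("  checkpoints at steps: %s\n",
              paste(x$config$checkpoint_steps, collapse = ", ")))
  cat("  last 5 steps:\n")
  print(x$loss_tail, row.names = FALSE)
  invisible(x)
}

#' @export
plot.wgan <- function(x, ...) {
  graphics::matplot(x$log$step,
                    cbind(x$log$critic_loss, x$log$gen_loss),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "generator step", ylab = "loss", ...)
  graphics::legend("topright", c("critic", "generator"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

# Pick one generator checkpoint (default: the last).
get_generator <- function(fit, checkpoint = NULL) {
  stopifnot(inherits(fit, "wgan"))
  checkpoint <- checkpoint %||% length(fit$generators)
  fit$generators[[checkpoint]]
}

# Generate profiles (rows) in original expression units from latent rows z.
generate_from <- function(fit, net, z) {
  out <- mlp_forward(net, z)$out
  out <- sweep(sweep(out, 2, fit$scale, "*"), 2, fit$center, "+")
  colnames(out) <- fit$gene_ids
  out
}

#' Generate expression profiles from a fitted generator
#'
#' @param object a [wgan()] fit.
#' @param z matrix of latent row vectors (columns = latent dimension).
#' @param checkpoint index into the stored generator checkpoints
#'   (default: last).
#' @param ... unused.
#' @return matrix of generated profiles, one row per row of `z`, in
#'   original expression units.
#' @export
predict.wgan <- function(object, z, checkpoint = NULL, ...) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(z) != object$config$latent_dim)
    stopf("z has %d columns; latent_dim is %d", ncol(z),
          object$config$latent_dim)
  generate_from(object, get_generator(object, checkpoint), z)
}

#' Draw random generated profiles
#'
#' @param object a [wgan()] fit.
#' @param nsim number of profiles.
#' @param seed integer seed.
#' @param checkpoint generator checkpoint index (default: last).
#' @param ... unused.
#' @return `nsim` x genes matrix of generated profiles.
#' @export
simulate.wgan <- function(object, nsim = 1L, seed = NULL,
                          checkpoint = NULL, ...) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(nsim * object$config$latent_dim), nsim)
    predict.wgan(object, z, checkpoint = checkpoint)
  })
}

#' Gradient penalty of a critic on interpolated batches
#'
#' Computes the WGAN-GP penalty `mean_b (||grad_x D(xhat_b)||_2 - 1)^2`
#' where `xhat_b = eps_b x_real_b + (1 - eps_b) x_fake_b` and
#' `eps_b ~ U(0, 1)` per row.
#'
#' @param critic a critic network (as stored in `fit$critic`, or built
#'   with internal helpers in tests).
#' @param x_real,x_fake batches with samples in rows, equal shapes.
#' @param seed integer seed for the interpolation draws.
#' @return non-negative scalar penalty.
#' @export
gradient_penalty <- function(critic, x_real, x_fake, seed = NULL) {
  x_real <- as.matrix(x_real); x_fake <- as.matrix(x_fake)
  if (!all(dim(x_real) == dim(x_fake)))
    stopf("x_real and x_fake must have identical shapes")
  with_seed(seed, {
    epsm <- stats::runif(nrow(x_real))
    xhat <- epsm * x_real + (1 - epsm) * x_fake
    cache <- mlp_forward(critic, xhat)
    G <- mlp_input_grad(critic, cache)
    mean((sqrt(rowSums(G^2)) - 1)^2)
  })
}

#' WGAN-GP critic and generator losses
#'
#' `critic_loss = mean D(x_fake) - mean D(x_real) + lambda_gp * penalty`
#' and `generator_loss = -mean D(x_fake)`.
#'
#' @inheritParams gradient_penalty
#' @param lambda_gp penalty weight.
#' @return list with `critic_loss`, `generator_loss`, `penalty`.
#' @export
wgan_gp_loss <- function(critic, x_real, x_fake, lambda_gp = 10,
                         seed = NULL) {
  x_real <- as.matrix(x_real); x_fake <- as.matrix(x_fake)
  if (!all(dim(x_real) == dim(x_fake)))
    stopf("x_real and x_fake must have identical shapes")
  pen <- gradient_penalty(critic, x_real, x_fake, seed = seed)
  dr <- mlp_forward(critic, x_real)$out
  df <- mlp_forward(critic, x_fake)$out
  list(critic_loss = mean(df) - mean(dr) + lambda_gp * pen,
       generator_loss = -mean(df), penalty = pen)
}

#' Quantitative generation-quality report
#'
#' Draws `n_draws` latent vectors, generates profiles, and reports for
#' every real sample the best Pearson correlation against the generated
#' set (the quantity gated at the 0.95 threshold downstream), plus a
#' distributional summary: the correlation between real and generated
#' per-gene means and per-gene variances.
#'
#' @param fit a [wgan()] fit.
#' @param x_real an [expr_matrix()] or genes x samples matrix.
#' @param n_draws number of generated profiles.
#' @param seed integer seed.
#' @param checkpoint generator checkpoint index (default: last).
#' @return list of class `"generation_quality"` with `best_r` (named per
#'   sample), `passes` (vs the fit's quality threshold), `mean_cor`,
#'   `var_cor`.
#' @export
generation_quality <- function(fit, x_real, n_draws = 1000L, seed = 1L,
                               checkpoint = NULL) {
  vals <- if (inherits(x_real, "expr_matrix")) x_real$values else
    as.matrix(x_real)
  fake <- simulate.wgan(fit, nsim = n_draws, seed = seed,
                        checkpoint = checkpoint)
  ft <- t(fake)                              # genes x draws
  best <- vapply(seq_len(ncol(vals)), function(j) {
    max(cor_with(ft, vals[, j]))
  }, numeric(1))
  names(best) <- colnames(vals)
  out <- list(best_r = best,
              passes = all(best >= fit$config$quality_threshold),
              threshold = fit$config$quality_threshold,
              mean_cor = stats::cor(rowMeans(ft), rowMeans(vals)),
              var_cor = stats::cor(apply(ft, 1, stats::var),
                                   apply(vals, 1, stats::var)))
  class(out) <- "generation_quality"
  out
}

#' @export
print.generation_quality <- function(x, ...) {
  cat(sprintf(
    "generation quality: best-match Pearson per real sample\n  min %.4f / median %.4f / max %.4f (gate %.2f: %s)\n",
    min(x$best_r), stats::median(x$best_r), max(x$best_r), x$threshold,
    if (x$passes) "pass" else "FAIL"))
  cat(sprintf("  per-gene mean cor %.4f, per-gene variance cor %.4f\n",
              x$mean_cor, x$var_cor))
  invisible(x)
}
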