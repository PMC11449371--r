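#' Construct a resembled fake for one real sample
#'
#' A resembled fake anchors a real sample in the generator's latent
#' space: `n_candidates` latent vectors are drawn from the standard
#' normal prior, ranked by the Pearson correlation between the generated
#' profile and the target sample, and the `k` nearest latents -- all
#' required to meet the correlation `threshold` -- are averaged into
#' `z_bar`.  The achieved correlation is then recomputed on
#' `G(z_bar)` (averaging latents does not preserve the selection
#' correlations) and must itself meet the threshold.  If selection or
#' the recomputed gate fails, the draw is repeated with a shifted seed
#' up to `max_retries` times.
#'
#' @param fit a [wgan()] fit.
#' @param x_target numeric vector of the real sample's expression (same
#'   gene order as the training data).
#' @param n_candidates latent draws per attempt.
#' @param k number of nearest latents averaged.
#' @param threshold minimum Pearson correlation for selection and for
#'   the recomputed `achieved_r` (default: the fit's quality threshold).
#' @param max_retries attempts before giving up.
#' @param checkpoint generator checkpoint index (default: last).
#' @param seed integer seed; retry `r` uses `seed + r`.
#' @return object of class `"resembled_fake"`: `z_bar`, `achieved_r`,
#'   `contributing_r` (the `k` selection correlations), `seed_used`,
#'   `n_candidates`, `k`, `retries`.
#' @export
resembled_fake <- function(fit, x_target, n_candidates = 35000L, k = 10L,
                           threshold = NULL, max_retries = 20L,
                           checkpoint = NULL, seed = 1L) {
  stopifnot(inherits(fit, "wgan"))
  threshold <- threshold %||% fit$config$quality_threshold
  if (k > n_candidates) stopf("k must be <= n_candidates")
  net <- get_generator(fit, checkpoint)
  x_target <- as.numeric(x_target)
  if (length(x_target) != fit$n_genes)
    stopf("x_target length %d does not match gene count %d",
          length(x_target), fit$n_genes)
  best_seen <- -Inf
  for (r in 0:max_retries) {
    seed_r <- as.integer((as.double(seed) + r) %% 2147483647)
    cand <- with_seed(seed_r, {
      z <- matrix(stats::rnorm(n_candidates * fit$config$latent_dim),
                  n_candidates)
      f <- generate_from(fit, net, z)
      rr <- cor_with(t(f), x_target)
      list(z = z, r = rr)
    })
    ord <- order(cand$r, decreasing = TRUE)[seq_len(k)]
    sel_r <- cand$r[ord]
    best_seen <- max(best_seen, sel_r[1L])
    if (sel_r[k] < threshold) next
    z_bar <- colMeans(cand$z[ord, , drop = FALSE])
    achieved <- stats::cor(as.numeric(generate_from(
      fit, net, matrix(z_bar, 1L))), x_target)
    best_seen <- max(best_seen, achieved)
    if (achieved >= threshold) {
      return(structure(list(z_bar = z_bar, achieved_r = achieved,
                            contributing_r = sel_r, seed_used = seed_r,
                            n_candidates = as.integer(n_candidates),
                            k = as.integer(k), retries = r),
                       class = "resembled_fake"))
    }
  }
  stopf("resembled fake failed after %d retries (best r attained %.4f, threshold %.2f)",
        max_retries, best_seen, threshold)
}

#' @export
print.resembled_fake <- function(x, ...) {
  cat(sprintf(
    "resembled fake: achieved r %.4f (k = %d of %d candidates, %d retries)\n",
    x$achieved_r, x$k, x$n_candidates, x$retries))
  invisible(x)
}

#' Latent-space interpolation between two anchored samples
#'
#' With `delta = z_cn - z_sn`, generates the trajectory
#' `G(z_sn + delta * i / (steps + 1))` for `i = 1..steps` and prepends/
#' appends the endpoint profiles `G(z_sn)` and `G(z_cn)`, giving
#' `steps + 2` rows (101 timesteps on the default 0..100 axis).
#'
#' @param fit a [wgan()] fit.
#' @param z_sn,z_cn latent vectors of the control and treated anchors
#'   (equal length), e.g. `z_bar` of two [resembled_fake()]s.
#' @param steps number of intermediate latents (default 99).
#' @param checkpoint generator checkpoint index (default: last).
#' @return `(steps + 2)` x genes matrix; row names are timesteps
#'   `0..(steps + 1)`.
#' @export
interpolate_pair <- function(fit, z_sn, z_cn, steps = 99L,
                             checkpoint = NULL) {
  z_sn <- as.numeric(z_sn); z_cn <- as.numeric(z_cn)
  if (length(z_sn) != length(z_cn))
    stopf("latent vectors differ in length (%d vs %d)",
          length(z_sn), length(z_cn))
  net <- get_generator(fit, checkpoint)
  frac <- (0:(steps + 1L)) / (steps + 1L)
  Z <- outer(rep(1, length(frac)), z_sn) + outer(frac, z_cn - z_sn)
  out <- generate_from(fit, net, Z)
  rownames(out) <- 0:(steps + 1L)
  out
}

# Resembled fakes for every column of a genes x samples matrix at one
# checkpoint, sharing one candidate pool across samples for speed;
# samples whose selection fails on the shared pool fall back to the
# per-sample retry path of resembled_fake().
resembled_fakes_at <- function(fit, vals, checkpoint, n_candidates, k,
                               threshold, max_retries, seed) {
  net <- get_generator(fit, checkpoint)
  pool <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_candidates * fit$config$latent_dim),
                n_candidates)
    f <- generate_from(fit, net, z)
    fc <- f - rowMeans(f)
    list(z = z, fc = fc, fn = sqrt(rowSums(fc^2)))
  })
  xc <- sweep(vals, 2, colMeans(vals))
  xn <- sqrt(colSums(xc^2))
  rmat <- (pool$fc %*% xc) / outer(pool$fn, xn)   # candidates x samples
  out <- vector("list", ncol(vals))
  names(out) <- colnames(vals)
  failures <- character(0)
  for (j in seq_len(ncol(vals))) {
    ord <- order(rmat[, j], decreasing = TRUE)[seq_len(k)]
    sel_r <- rmat[ord, j]
    ok <- sel_r[k] >= threshold
    if (ok) {
      z_bar <- colMeans(pool$z[ord, , drop = FALSE])
      achieved <- stats::cor(as.numeric(generate_from(
        fit, net, matrix(z_bar, 1L))), vals[, j])
      if (achieved >= threshold) {
        out[[j]] <- structure(list(z_bar = z_bar, achieved_r = achieved,
                                   contributing_r = sel_r,
                                   seed_used = seed,
                                   n_candidates = as.integer(n_candidates),
                                   k = as.integer(k), retries = 0L),
                              class = "resembled_fake")
        next
      }
    }
    res <- tryCatch(
      resembled_fake(fit, vals[, j], n_candidates = n_candidates, k = k,
                     threshold = threshold, max_retries = max_retries,
                     checkpoint = checkpoint,
                     seed = child_seed(seed, j)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", colnames(vals)[j],
                                      conditionMessage(res)))
      out[[j]] <- NULL
    } else out[[j]] <- res
  }
  list(fakes = out, failures = failures)
}

#' Simulate the averaged intermediate expression profile
#'
#' The full trajectory-simulation stage: at every stored generator
#' checkpoint, resembled fakes are constructed for all real samples,
#' latent interpolation is run for every SN x CN pair, and the resulting
#' trajectories are averaged over pairs, giving one timestep x gene
#' matrix per checkpoint (the "repeat").  The stack of repeats and its
#' mean -- the averaged profile consumed by network construction and the
#' serial differential test -- are returned together with a per-sample
#' log of the resembled-fake protocol (candidate draws, nearest-latent
#' count, achieved correlation, retries).
#'
#' @param fit a [wgan()] fit with at least one checkpoint.
#' @param x an [expr_matrix()] with at least one SN and one CN sample.
#' @param n_candidates,k,threshold,max_retries see [resembled_fake()].
#' @param steps intermediate timesteps per pair (default 99, i.e. 101
#'   rows with endpoints).
#' @param repeat_axis what the repeat axis of the stack indexes:
#'   `"checkpoint"` (default; each repeat is one generator checkpoint's
#'   pair-averaged trajectory) or `"pair"` (each repeat is one SN x CN
#'   pair's checkpoint-averaged trajectory).  The overall mean profile
#'   is identical either way; the choice defines the replica unit of
#'   the serial differential test.
#' @param seed integer seed.
#' @param verbose log per-checkpoint progress.
#' @return object of class `"trajectory_stack"`: `stack` (repeat x
#'   timestep x gene array), `profile` (timestep x gene mean over
#'   repeats), `fakes` (per checkpoint/sample log data frame),
#'   `timesteps`, `gene_ids`, `pairs` (SN/CN ids).
#' @export
average_profile <- function(fit, x, n_candidates = 35000L, k = 10L,
                            threshold = NULL, max_retries = 20L,
                            steps = 99L,
                            repeat_axis = c("checkpoint", "pair"),
                            seed = 1L, verbose = FALSE) {
  repeat_axis <- match.arg(repeat_axis)
  stopifnot(inherits(fit, "wgan"), inherits(x, "expr_matrix"))
  threshold <- threshold %||% fit$config$quality_threshold
  sn <- which(x$group == "SN")
  cn <- which(x$group == "CN")
  if (!length(sn) || !length(cn))
    stopf("need at least one SN and one CN sample")
  if (!identical(rownames(x$values), fit$gene_ids))
    stopf("gene ids of x do not match the fit")
  n_cp <- length(fit$generators)
  n_t <- steps + 2L
  frac <- (0:(steps + 1L)) / (steps + 1L)
  n_pairs_all <- length(sn) * length(cn)
  n_rep <- if (repeat_axis == "checkpoint") n_cp else n_pairs_all
  stack <- array(if (repeat_axis == "checkpoint") NA_real_ else 0,
                 dim = c(n_rep, n_t, fit$n_genes),
                 dimnames = list(NULL, 0:(steps + 1L), fit$gene_ids))
  logs <- vector("list", n_cp)
  for (cp in seq_len(n_cp)) {
    rf <- resembled_fakes_at(fit, x$values, checkpoint = cp,
                             n_candidates = n_candidates, k = k,
                             threshold = threshold,
                             max_retries = max_retries,
                             seed = child_seed(seed, cp))
    if (length(rf$failures))
      stopf("resembled-fake construction failed at checkpoint %d for:\n  %s",
            cp, paste(rf$failures, collapse = "\n  "))
    fakes <- rf$fakes
    logs[[cp]] <- data.frame(
      checkpoint = cp, sample_id = names(fakes),
      group = x$group,
      achieved_r = vapply(fakes, `[[`, numeric(1), "achieved_r"),
      n_candidates = vapply(fakes, `[[`, integer(1), "n_candidates"),
      k = vapply(fakes, `[[`, integer(1), "k"),
      retries = vapply(fakes, `[[`, integer(1), "retries"),
      seed_used = vapply(fakes, function(f) as.double(f$seed_used),
                         numeric(1)),
      row.names = NULL)
    zs <- t(vapply(fakes, `[[`, numeric(fit$config$latent_dim), "z_bar"))
    # all pair trajectories in one forward pass, then mean over pairs
    pairs <- expand.grid(sn = sn, cn = cn)
    Z <- matrix(NA_real_, nrow(pairs) * n_t, fit$config$latent_dim)
    for (p in seq_len(nrow(pairs))) {
      zsn <- zs[pairs$sn[p], ]
      zcn <- zs[pairs$cn[p], ]
      Z[(p - 1L) * n_t + seq_len(n_t), ] <-
        outer(rep(1, n_t), zsn) + outer(frac, zcn - zsn)
    }
    out <- generate_from(fit, get_generator(fit, cp), Z)
    if (repeat_axis == "checkpoint") {
      grpi <- rep(seq_len(n_t), times = nrow(pairs))
      stack[cp, , ] <- rowsum(out, grpi) / nrow(pairs)
    } else {
      for (p in seq_len(nrow(pairs)))
        stack[p, , ] <- stack[p, , ] +
          out[(p - 1L) * n_t + seq_len(n_t), ] / n_cp
    }
    msgf(verbose, "checkpoint %d/%d: %d fakes, %d pair trajectories",
         cp, n_cp, length(fakes), nrow(pairs))
  }
  profile <- apply(stack, c(2, 3), mean)
  dimnames(profile) <- list(0:(steps + 1L), fit$gene_ids)
  structure(list(stack = stack, profile = profile,
                 fakes = do.call(rbind, logs),
                 timesteps = 0:(steps + 1L), gene_ids = fit$gene_ids,
                 pairs = list(sn = x$sample_ids[sn],
                              cn = x$sample_ids[cn])),
            class = "trajectory_stack")
}

#' @export
print.trajectory_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf(
    "trajectory stack: %d repeats x %d timesteps x %d genes\n%d SN x %d CN pairs; achieved r range %.4f - %.4f\n",
    d[1], d[2], d[3], length(x$pairs$sn), length(x$pairs$cn),
    min(x$fakes$achieved_r), max(x$fakes$achieved_r)))
  invisible(x)
}

#' Averaged profile of a trajectory stack
#'
#' @param stack a `"trajectory_stack"` from [average_profile()].
#' @return timestep x gene matrix (mean over repeats).
#' @export
averaged_profile <- function(stack) {
  stopifnot(inherits(stack, "trajectory_stack"))
  stack$profile
}
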