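# Empirical-Bayes variance moderation, implemented from the standard
# hierarchical model: gene-wise variances s2 with df degrees of freedom
# are assumed scaled-inverse-chi-square around a prior (d0, s0^2); the
# posterior variance is s2_post = (d0 s0^2 + df s2) / (d0 + df) and
# moderated t statistics gain d0 extra degrees of freedom.  The prior is
# estimated by method of moments on log(s2).

trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderate gene-wise variances toward a common prior
#'
#' Method-of-moments empirical-Bayes shrinkage: with `z = log(s2)`,
#' `e = z - digamma(df/2) + log(df/2)` has mean `log(s0^2) +
#' digamma(d0/2) - log(d0/2)` and excess variance `trigamma(d0/2)`
#' beyond `trigamma(df/2)`; inverting the trigamma gives the prior
#' degrees of freedom `d0` (infinite when the observed variances are no
#' more dispersed than chi-square sampling alone) and the prior variance
#' `s0^2`.  Posterior variances are the precision-weighted blend.
#'
#' @param s2 gene-wise sample variances.
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @return list with `var_post`, `df_prior`, `var_prior`.
#' @export
squeeze_variance <- function(s2, df) {
  if (df <= 0) stopf("df must be positive")
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
    post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(var_post = post, df_prior = d0, var_prior = s02)
}

# Moderated paired/one-sample test of column means of a replicate x gene
# difference matrix.
moderated_mean_test <- function(D, df_prior = NULL) {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- apply(D, 2, stats::var)
  df <- n - 1
  if (is.null(df_prior)) {
    sq <- squeeze_variance(s2, df)
  } else {
    # explicit prior df (df_prior = 0 recovers the ordinary t-test)
    if (df_prior == 0) sq <- list(var_post = s2, df_prior = 0)
    else stopf("only df_prior = 0 or NULL supported")
  }
  df_tot <- df + sq$df_prior
  tt <- m / sqrt(sq$var_post / n)
  p <- 2 * stats::pt(-abs(tt), df = min(df_tot, 1e6))
  list(estimate = m, t = tt, p = p, var_post = sq$var_post,
       df_prior = sq$df_prior, df_total = df_tot)
}

#' Serial differential expression over simulated timesteps
#'
#' Treats the per-repeat trajectories of a [average_profile()] stack as
#' biological replicas and, for every timestep `t >= 1`, tests each
#' gene's expression against timestep 0: the log2 fold change is the
#' mean over repeats of `x_t - x_0` and the p-value comes from a
#' moderated t-test (empirical-Bayes variance shrinkage across genes,
#' see [squeeze_variance()]), paired across repeats by default since
#' repeats share a generator checkpoint.  No multiplicity correction is
#' applied across timesteps or genes; the significance thresholds are
#' raw `|log2FC| >= fc_threshold` and `p <= p_threshold` per timestep.
#'
#' @param stack a `"trajectory_stack"` or a repeat x timestep x gene
#'   array (log2-scale values; at least 3 repeats).
#' @param fc_threshold,p_threshold the per-timestep significance
#'   thresholds (defaults 0.2 and 0.05).
#' @param paired pair repeats between `t` and 0 (default); otherwise an
#'   unpaired moderated two-sample test is used.
#' @param moderated use variance shrinkage; `FALSE` gives the ordinary
#'   t-test (the `d0 -> 0` limit).
#' @return object of class `"rdeg_serial"`: `log2fc` and `p` (timestep x
#'   gene matrices for t = 1..T), `significant` (logical matrix under
#'   the thresholds), `genes`, `timesteps`, `thresholds`.
#' @export
serial_deg <- function(stack, fc_threshold = 0.2, p_threshold = 0.05,
                       paired = TRUE, moderated = TRUE) {
  arr <- if (inherits(stack, "trajectory_stack")) stack$stack else stack
  if (length(dim(arr)) != 3L) stopf("stack must be a 3-d array")
  if (any(!is.finite(arr))) stopf("stack contains non-finite values")
  n_rep <- dim(arr)[1L]
  if (n_rep < 3L) stopf("need at least 3 repeats for replica variance")
  tsteps <- as.numeric(dimnames(arr)[[2L]] %||% (seq_len(dim(arr)[2L]) - 1))
  genes <- dimnames(arr)[[3L]] %||% paste0("gene", seq_len(dim(arr)[3L]))
  n_t <- dim(arr)[2L]
  x0 <- arr[, 1L, ]
  fc <- p <- matrix(NA_real_, n_t - 1L, length(genes),
                    dimnames = list(tsteps[-1L], genes))
  for (ti in 2:n_t) {
    xt <- arr[, ti, ]
    if (paired) {
      res <- moderated_mean_test(xt - x0,
                                 df_prior = if (moderated) NULL else 0)
      fc[ti - 1L, ] <- res$estimate
      p[ti - 1L, ] <- res$p
    } else {
      m <- colMeans(xt) - colMeans(x0)
      s2 <- (apply(xt, 2, stats::var) + apply(x0, 2, stats::var)) / 2
      df <- 2 * (n_rep - 1)
      sq <- if (moderated) squeeze_variance(s2, df) else
        list(var_post = s2, df_prior = 0)
      tt <- m / sqrt(sq$var_post * 2 / n_rep)
      fc[ti - 1L, ] <- m
      p[ti - 1L, ] <- 2 * stats::pt(-abs(tt),
                                    df = min(df + sq$df_prior, 1e6))
    }
  }
  structure(list(log2fc = fc, p = p,
                 significant = abs(fc) >= fc_threshold & p <= p_threshold,
                 genes = genes, timesteps = tsteps[-1L],
                 thresholds = c(fc = fc_threshold, p = p_threshold)),
            class = "rdeg_serial")
}

#' @export
print.rdeg_serial <- function(x, ...) {
  cat(sprintf(
    "serial DEG: %d genes x %d timesteps; %d genes significant at >= 1 timestep (|log2FC| >= %.2g, p <= %.2g)\n",
    ncol(x$p), nrow(x$p), sum(apply(x$significant, 2, any)),
    x$thresholds["fc"], x$thresholds["p"]))
  invisible(x)
}

#' Conventional endpoint differential expression
#'
#' Two-sample comparison of CN vs SN in the real samples: per-gene log2
#' fold change `mean(CN) - mean(SN)` (values already on log2 scale) and
#' a moderated two-sample t-test with pooled variance and empirical-
#' Bayes shrinkage across genes.
#'
#' @param x_real an [expr_matrix()] with >= 2 samples per group.
#' @param fc_threshold,p_threshold significance thresholds (defaults 0.2
#'   and 0.05).
#' @param moderated use variance shrinkage.
#' @return data.frame with `gene`, `log2fc`, `p`, `significant`.
#' @export
conventional_deg <- function(x_real, fc_threshold = 0.2,
                             p_threshold = 0.05, moderated = TRUE) {
  stopifnot(inherits(x_real, "expr_matrix"))
  sn <- x_real$group == "SN"
  cn <- x_real$group == "CN"
  if (sum(sn) < 2L || sum(cn) < 2L)
    stopf("need at least 2 samples per group")
  Xs <- x_real$values[, sn, drop = FALSE]
  Xc <- x_real$values[, cn, drop = FALSE]
  n1 <- ncol(Xs); n2 <- ncol(Xc)
  m <- rowMeans(Xc) - rowMeans(Xs)
  s2 <- ((n1 - 1) * apply(Xs, 1, stats::var) +
           (n2 - 1) * apply(Xc, 1, stats::var)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  sq <- if (moderated) squeeze_variance(s2, df) else
    list(var_post = s2, df_prior = 0)
  tt <- m / sqrt(sq$var_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df = min(df + sq$df_prior, 1e6))
  data.frame(gene = x_real$gene_ids, log2fc = m, p = p,
             significant = abs(m) >= fc_threshold & p <= p_threshold,
             row.names = NULL)
}

#' Rescue intermediate-stage differential genes
#'
#' Combines the serial (simulated time course) and conventional
#' (endpoint) tests: a gene is an `rdeg` when significant at one or more
#' simulated timesteps, and `rescued` when it is an rdeg that the
#' conventional endpoint comparison missed -- typically genes whose fold
#' change rises and falls inside the time course.
#'
#' @param serial an `"rdeg_serial"` from [serial_deg()].
#' @param endpoint data.frame from [conventional_deg()] on the same gene
#'   universe.
#' @return data.frame sorted by minimum serial p-value: `gene`,
#'   `min_p`, `min_p_timestep`, `peak_log2fc`, `peak_fc_timestep`,
#'   `conventional_deg`, `rdeg`, `rescued`.
#' @export
rescue <- function(serial, endpoint) {
  stopifnot(inherits(serial, "rdeg_serial"))
  if (!setequal(serial$genes, endpoint$gene)) {
    bad <- c(setdiff(serial$genes, endpoint$gene),
             setdiff(endpoint$gene, serial$genes))
    stopf("gene universes differ: %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  endpoint <- endpoint[match(serial$genes, endpoint$gene), ]
  min_i <- apply(serial$p, 2, which.min)
  pk_i <- apply(abs(serial$log2fc), 2, which.max)
  out <- data.frame(
    gene = serial$genes,
    min_p = serial$p[cbind(min_i, seq_along(serial$genes))],
    min_p_timestep = serial$timesteps[min_i],
    peak_log2fc = serial$log2fc[cbind(pk_i, seq_along(serial$genes))],
    peak_fc_timestep = serial$timesteps[pk_i],
    conventional_deg = endpoint$significant,
    rdeg = apply(serial$significant, 2, any),
    row.names = NULL)
  out$rescued <- out$rdeg & !out$conventional_deg
  out[order(out$min_p), ]
}
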