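#' Configuration for co-expression network construction
#'
#' @param beta_grid candidate soft-threshold powers (ascending).
#' @param rsq_target scale-free topology fit R^2 required to accept a
#'   power; if no power reaches it the fallback takes the power with the
#'   maximal fit index, floored at `beta_floor` (mirroring data sets
#'   where the conventional criterion cannot be met).
#' @param beta_floor lower bound for the fallback power; `NULL` (the
#'   default) resolves to the field convention of 6 for unsigned and 12
#'   for signed networks.
#' @param min_module_size clusters smaller than this are left unassigned
#'   (module 0).  The default (10) suits the few-hundred-gene problems
#'   this package targets by default; genome-scale analyses
#'   conventionally use 30.
#' @param cut_height_fraction static tree-cut height as a fraction of
#'   the maximal merge height.
#' @param network_type `"signed"` (default) maps correlation r to
#'   `((1 + r)/2)^beta` so anticorrelated genes land in different
#'   modules; `"unsigned"` uses `|r|^beta`, the classic tutorial choice,
#'   which merges mirror-image trajectories into one module.
#' @param merge_corr eigengene correlation above which detected modules
#'   are merged when `merge = TRUE`.
#' @param merge merge highly correlated modules after detection.
#' @return list of class `"network_config"`.
#' @export
network_config <- function(beta_grid = 1:20, rsq_target = 0.8,
                           beta_floor = NULL, min_module_size = 10L,
                           cut_height_fraction = 0.99,
                           network_type = c("signed", "unsigned"),
                           merge_corr = 0.75, merge = FALSE) {
  if (!length(beta_grid) || is.unsorted(beta_grid))
    stopf("beta_grid must be nonempty and ascending")
  if (rsq_target <= 0 || rsq_target >= 1)
    stopf("rsq_target must be in (0, 1)")
  if (cut_height_fraction <= 0 || cut_height_fraction >= 1)
    stopf("cut_height_fraction must be in (0, 1)")
  network_type <- match.arg(network_type)
  beta_floor <- as.integer(beta_floor %||%
                             (if (network_type == "signed") 12L else 6L))
  structure(list(beta_grid = as.integer(beta_grid),
                 rsq_target = rsq_target, beta_floor = beta_floor,
                 min_module_size = as.integer(min_module_size),
                 cut_height_fraction = cut_height_fraction,
                 network_type = network_type,
                 merge_corr = merge_corr, merge = merge),
            class = "network_config")
}

drop_constant_genes <- function(X, warn = TRUE) {
  sds <- apply(X, 2, stats::sd)
  const <- sds < 1e-12 | !is.finite(sds)
  if (any(const)) {
    if (warn) warnf("dropping %d constant gene(s) before network construction",
                    sum(const))
    X <- X[, !const, drop = FALSE]
  }
  X
}

#' Soft-threshold adjacency between gene profiles
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned) or
#' `a_ij = ((1 + cor(x_i, x_j))/2)^beta` (signed), with unit diagonal.
#'
#' @param X conditions x genes matrix (rows are timesteps or samples).
#' @param beta soft-threshold power (>= 1).
#' @param type `"unsigned"` or `"signed"`.
#' @return symmetric genes x genes matrix in \[0, 1\].
#' @export
adjacency <- function(X, beta = 6, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stopf("beta must be >= 1")
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- colnames(X)[sds < 1e-12] %||% which(sds < 1e-12)
    stopf("zero-variance gene(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  r <- stats::cor(X)
  A <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' For adjacency `A` with unit diagonal, connectivity
#' `k_i = sum_{u != i} a_iu` and shared-neighbor weight
#' `l_ij = sum_{u != i,j} a_iu a_uj`, the topological overlap is
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` off the diagonal
#' and 1 on it.
#'
#' @param A symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-10)) stopf("adjacency must be symmetric")
  if (any(abs(diag(A) - 1) > 1e-10)) stopf("adjacency must have unit diagonal")
  k <- rowSums(A) - 1
  # (A^2)_ij includes u = i and u = j terms a_ii a_ij + a_ij a_jj = 2 a_ij
  L <- A %*% A - 2 * A
  minK <- outer(k, k, pmin)
  W <- (L + A) / (minK + 1 - A)
  diag(W) <- 1
  dimnames(W) <- dimnames(A)
  W
}

# Scale-free topology fit index for one connectivity vector: signed R^2
# of the log-log regression of binned degree frequency on binned degree.
scale_free_fit <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L || diff(range(k)) < 1e-10)
    return(list(rsq = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = nbins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3L) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2L]
  list(rsq = -sign(slope) * r2, slope = unname(slope))
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes per-gene
#' connectivity, and evaluates the signed scale-free fit index (the
#' R^2 of the log-log degree-distribution regression, negated when the
#' slope is positive).  The smallest power reaching `rsq_target` is
#' chosen; if none does, the power with maximal fit index, floored at
#' `beta_floor`, is used and flagged.
#'
#' @param X conditions x genes matrix.
#' @param config a [network_config()].
#' @return list of class `"soft_threshold"`: `beta`, `met_target`,
#'   `fit_table` (power, fit index, slope, mean/median/max
#'   connectivity).
#' @export
pick_soft_threshold <- function(X, config = network_config()) {
  X <- drop_constant_genes(as.matrix(X))
  if (nrow(X) < 3L) stopf("need at least 3 conditions (rows)")
  if (ncol(X) < 10L) stopf("need at least 10 genes")
  r <- stats::cor(X)
  base <- if (config$network_type == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- NA
  rows <- lapply(config$beta_grid, function(beta) {
    A <- base^beta
    k <- rowSums(A, na.rm = TRUE)
    sf <- scale_free_fit(k)
    data.frame(power = beta, fit = sf$rsq, slope = sf$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$fit) & tab$fit >= config$rsq_target)
  if (length(ok)) {
    beta <- tab$power[ok[1L]]
    met <- TRUE
  } else {
    best <- if (all(is.na(tab$fit))) length(tab$fit) else which.max(tab$fit)
    beta <- max(tab$power[best], config$beta_floor)
    met <- FALSE
  }
  structure(list(beta = as.integer(beta), met_target = met,
                 fit_table = tab, config = config),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("soft threshold: beta = %d (%s scale-free target R^2 >= %.2f, %s network)\n",
              x$beta, if (x$met_target) "met" else "fallback, did not meet",
              x$config$rsq_target, x$config$network_type))
  invisible(x)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `1 - TOM`, cut statically at `cut_height_fraction` of the maximal
#' merge height; clusters smaller than `min_module_size` are unassigned
#' (module 0) and module ids are ordered by decreasing size.
#'
#' @param W topological overlap (or any similarity in \[0, 1\]) matrix.
#' @param config a [network_config()].
#' @return object of class `"module_assignment"`: `module` (named
#'   integer vector, 0 = unassigned), `sizes`, `cut_height`, `tree`.
#' @export
detect_modules <- function(W, config = network_config()) {
  W <- as.matrix(W)
  genes <- colnames(W) %||% paste0("gene", seq_len(ncol(W)))
  d <- stats::as.dist(1 - W)
  tree <- stats::hclust(d, method = "average")
  h <- config$cut_height_fraction * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  module <- integer(length(raw))
  if (length(keep)) {
    kept_sizes <- sort(sizes[keep], decreasing = TRUE)
    for (i in seq_along(kept_sizes))
      module[raw == as.integer(names(kept_sizes)[i])] <- i
  }
  names(module) <- genes
  if (length(unique(raw)) == 1L)
    warnf("all genes fall into a single cluster at the cut height")
  structure(list(module = module,
                 sizes = table(module[module > 0L]),
                 cut_height = h, tree = tree, config = config),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module assignment: %d modules, %d/%d genes assigned\n",
              length(x$sizes), sum(x$module > 0L), length(x$module)))
  if (length(x$sizes)) {
    s <- as.integer(x$sizes)
    cat("  sizes:", paste(s, collapse = ", "), "\n")
  }
  invisible(x)
}

# First-principal-component eigengene of one module: rows of X are
# conditions, cols the module's genes (standardized here).  Returns
# unit-variance scores, gene loadings, explained variance; sign oriented
# so the eigengene correlates non-negatively with the module mean
# profile (or with reference loadings when given).
module_pc1 <- function(Xm, ref_loadings = NULL) {
  n <- nrow(Xm)
  mu <- colMeans(Xm)
  sd_ <- apply(Xm, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Z <- sweep(sweep(Xm, 2, mu), 2, sd_, "/")
  if (ncol(Z) == 1L) {
    e <- Z[, 1L]
    load <- 1
    ve <- 1
  } else {
    sv <- svd(Z, nu = 1L, nv = 1L)
    e <- sv$u[, 1L] * sv$d[1L]
    load <- sv$v[, 1L]
    ve <- sv$d[1L]^2 / sum(sv$d^2)
  }
  if (stats::sd(e) > 0) e <- e / stats::sd(e)
  flip <- if (!is.null(ref_loadings)) {
    cr <- suppressWarnings(stats::cor(load, ref_loadings))
    !is.na(cr) && cr < 0
  } else {
    cr <- suppressWarnings(stats::cor(e, rowMeans(Z)))
    !is.na(cr) && cr < 0
  }
  if (flip) { e <- -e; load <- -load }
  list(eigengene = e, loadings = stats::setNames(load, colnames(Xm)),
       var_explained = ve)
}

#' Module eigengenes over conditions
#'
#' Per module, standardizes the member genes and extracts the first
#' principal component over the rows of `X` (timesteps or samples); the
#' eigengene is scaled to unit variance and sign-oriented to correlate
#' non-negatively with the module's mean standardized profile.
#'
#' @param X conditions x genes matrix.
#' @param assignment a `"module_assignment"` (or named integer vector).
#' @return object of class `"eigengene_profile"`: `eigengenes`
#'   (conditions x modules matrix), `var_explained`, `loadings` (list of
#'   per-gene loading vectors), `modules`.
#' @export
module_eigengenes <- function(X, assignment) {
  X <- as.matrix(X)
  module <- if (inherits(assignment, "module_assignment"))
    assignment$module else assignment
  ids <- sort(unique(module[module > 0L]))
  if (!length(ids)) stopf("no assigned modules")
  miss <- setdiff(names(module)[module > 0L], colnames(X))
  if (length(miss))
    stopf("genes missing from X: %s", paste(utils::head(miss, 5), collapse = ", "))
  eig <- matrix(NA_real_, nrow(X), length(ids),
                dimnames = list(rownames(X), paste0("ME", ids)))
  ve <- stats::setNames(numeric(length(ids)), paste0("ME", ids))
  loads <- vector("list", length(ids))
  names(loads) <- paste0("ME", ids)
  for (i in seq_along(ids)) {
    g <- names(module)[module == ids[i]]
    pc <- module_pc1(X[, g, drop = FALSE])
    eig[, i] <- pc$eigengene
    ve[i] <- pc$var_explained
    loads[[i]] <- pc$loadings
  }
  structure(list(eigengenes = eig, var_explained = ve, loadings = loads,
                 modules = ids), class = "eigengene_profile")
}

#' @export
print.eigengene_profile <- function(x, ...) {
  cat(sprintf("eigengene profile: %d modules over %d conditions\n",
              ncol(x$eigengenes), nrow(x$eigengenes)))
  cat("  variance explained:",
      paste(sprintf("%.2f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Module-trait alignment in real samples
#'
#' Modules are detected on the simulated profile, but the behavioral
#' trait exists only for real samples; this recomputes each module's
#' eigengene by PCA across the real samples, orients its sign by the
#' correlation of the real-sample gene loadings with the
#' simulated-profile loadings (when supplied), and correlates the
#' eigengene with the trait.  Two-sided p-values come from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`; a module passes when
#' `p < alpha` and `|r| > r_threshold`.
#'
#' @param assignment a `"module_assignment"` from the simulated profile.
#' @param x_real an [expr_matrix()] of real samples sharing gene ids.
#' @param traits named numeric trait vector (see [read_traits()]); 0 for
#'   controls.
#' @param sim_loadings optional `"eigengene_profile"` computed on the
#'   simulated profile; used for sign orientation.
#' @param alpha,r_threshold the pass criteria (defaults 0.05 and 0.5).
#' @param adjust apply Benjamini-Hochberg across modules before the
#'   p-value criterion (off by default; the criteria are stated on raw
#'   p-values).
#' @return data.frame with columns `module`, `size`, `r`, `p`, `passes`,
#'   `region`, plus attribute `"eigengenes"` (real-sample eigengene
#'   matrix).
#' @export
module_trait_alignment <- function(assignment, x_real, traits,
                                   sim_loadings = NULL, alpha = 0.05,
                                   r_threshold = 0.5, adjust = FALSE) {
  stopifnot(inherits(x_real, "expr_matrix"))
  module <- if (inherits(assignment, "module_assignment"))
    assignment$module else assignment
  n <- length(x_real$sample_ids)
  if (n < 4L) stopf("need at least 4 real samples for trait correlation")
  miss <- setdiff(names(module)[module > 0L], x_real$gene_ids)
  if (length(miss))
    stopf("module genes missing from real data: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  tr <- traits[x_real$sample_ids]
  if (anyNA(tr)) stopf("trait values missing for some samples")
  if (stats::sd(tr) < 1e-12)
    stopf("trait has zero variance; correlation undefined")
  X <- t(x_real$values)                       # samples x genes
  ids <- sort(unique(module[module > 0L]))
  eig <- matrix(NA_real_, n, length(ids),
                dimnames = list(x_real$sample_ids, paste0("ME", ids)))
  res <- data.frame(module = ids, size = NA_integer_, r = NA_real_,
                    p = NA_real_)
  for (i in seq_along(ids)) {
    g <- names(module)[module == ids[i]]
    ref <- if (!is.null(sim_loadings))
      sim_loadings$loadings[[paste0("ME", ids[i])]][g] else NULL
    pc <- module_pc1(X[, g, drop = FALSE], ref_loadings = ref)
    eig[, i] <- pc$eigengene
    r <- stats::cor(pc$eigengene, tr)
    tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 1e-300))
    res$size[i] <- length(g)
    res$r[i] <- r
    res$p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  p_use <- if (adjust) stats::p.adjust(res$p, "BH") else res$p
  res$passes <- p_use < alpha & abs(res$r) > r_threshold
  res$region <- if (is.null(x_real$region)) NA_character_ else
    paste(unique(x_real$region), collapse = "+")
  attr(res, "eigengenes") <- eig
  res
}
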