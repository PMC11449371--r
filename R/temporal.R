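#' Align modules to their eigengene peak timepoint
#'
#' Each module is assigned the timestep at which its (sign-oriented)
#' simulated eigengene is maximal (ties resolve to the earliest
#' timestep, so a constant eigengene lands at time 0) and staged as
#' early / mid / late by the `t_early` and `t_late` boundaries on the
#' 0..100 axis.  `mode = "diff"` instead aligns to the largest absolute
#' first difference, emphasizing where a profile changes fastest rather
#' than where it is highest.
#'
#' @param eigengenes an `"eigengene_profile"` over timesteps (or a
#'   timesteps x modules matrix with timestep row names).
#' @param t_early,t_late stage boundaries (peak <= `t_early` is early,
#'   >= `t_late` is late).
#' @param mode `"peak"` (default) or `"diff"`.
#' @return data.frame with `module`, `peak`, `stage`.
#' @export
peak_align <- function(eigengenes, t_early = 10, t_late = 90,
                       mode = c("peak", "diff")) {
  mode <- match.arg(mode)
  E <- if (inherits(eigengenes, "eigengene_profile"))
    eigengenes$eigengenes else as.matrix(eigengenes)
  tsteps <- as.numeric(rownames(E) %||% (seq_len(nrow(E)) - 1))
  ids <- sub("^ME", "", colnames(E) %||% seq_len(ncol(E)))
  peak <- vapply(seq_len(ncol(E)), function(j) {
    if (mode == "peak") tsteps[which.max(E[, j])]
    else tsteps[which.max(abs(diff(E[, j]))) + 1L]
  }, numeric(1))
  stage <- ifelse(peak <= t_early, "early",
                  ifelse(peak >= t_late, "late", "mid"))
  data.frame(module = as.integer(ids), peak = peak, stage = stage)
}

#' Module-module correlation network over the simulated time axis
#'
#' Computes pairwise Pearson correlations between module eigengene time
#' profiles, keeps edges with `|r| >= edge_threshold` (signed), and
#' stages each module by its peak timepoint via [peak_align()].
#'
#' @param eigengenes an `"eigengene_profile"` over timesteps (or
#'   matrix).
#' @param edge_threshold minimum `|r|` for an edge.
#' @param t_early,t_late stage boundaries passed to [peak_align()].
#' @param align_mode passed to [peak_align()].
#' @return object of class `"temporal_network"`: `nodes` (module, peak,
#'   stage, group placeholder), `edges` (m1, m2, r, sign), `cor` (full
#'   module correlation matrix).
#' @export
module_network <- function(eigengenes, edge_threshold = 0.5,
                           t_early = 10, t_late = 90,
                           align_mode = "peak") {
  E <- if (inherits(eigengenes, "eigengene_profile"))
    eigengenes$eigengenes else as.matrix(eigengenes)
  if (ncol(E) < 2L) stopf("need at least 2 modules for a network")
  nodes <- peak_align(E, t_early = t_early, t_late = t_late,
                      mode = align_mode)
  nodes$group <- NA_character_
  R <- stats::cor(E)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  keep <- abs(R[idx]) >= edge_threshold
  edges <- data.frame(m1 = nodes$module[idx[keep, 1L]],
                      m2 = nodes$module[idx[keep, 2L]],
                      r = R[idx][keep],
                      sign = ifelse(R[idx][keep] >= 0, "positive",
                                    "negative"))
  dimnames(R) <- list(nodes$module, nodes$module)
  structure(list(nodes = nodes, edges = edges, cor = R,
                 edge_threshold = edge_threshold),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("temporal network: %d modules, %d edges (|r| >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold))
  print(table(x$nodes$stage))
  invisible(x)
}

#' Cluster modules within each stage by correlation pattern
#'
#' Within each temporal stage, the module correlation submatrix is
#' clustered (average linkage on `1 - r`) and cut into
#' `groups_per_stage` groups; labels are the stage name suffixed by an
#' index in decreasing group size (e.g. `mid1`, `mid2`).  Stages with a
#' single module form one group.
#'
#' @param network a `"temporal_network"` from [module_network()].
#' @param groups_per_stage number of groups per stage (default 2).
#' @return named character vector of group labels (names are module
#'   ids), also recorded in `network$nodes$group` of the returned
#'   attribute `"network"`.
#' @export
cluster_modules <- function(network, groups_per_stage = 2L) {
  stopifnot(inherits(network, "temporal_network"))
  nodes <- network$nodes
  groups <- stats::setNames(rep(NA_character_, nrow(nodes)),
                            nodes$module)
  for (st in unique(nodes$stage)) {
    m <- nodes$module[nodes$stage == st]
    if (length(m) == 1L) {
      groups[as.character(m)] <- paste0(st, 1L)
      next
    }
    sub <- network$cor[as.character(m), as.character(m)]
    k <- min(groups_per_stage, length(m))
    cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sub),
                                      method = "average"), k = k)
    sizes <- sort(table(cl), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes), names(sizes))
    groups[as.character(m)] <- paste0(st, relabel[as.character(cl)])
  }
  nodes$group <- groups[as.character(nodes$module)]
  network$nodes <- nodes
  attr(groups, "network") <- network
  groups
}
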