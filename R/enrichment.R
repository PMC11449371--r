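#' Hypergeometric over-representation test of a module against one term
#'
#' With universe size `N`, term size `K`, module size `n` and overlap
#' `k`, the p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  The odds ratio uses the 2x2 table
#' `(k, n - k; K - k, N - K - n + k)` with a Haldane 0.5 correction
#' when any cell is zero; the enrichment ratio is `(k/n) / (K/N)`.
#'
#' @param module_genes,term_genes character vectors (subsets of
#'   `universe`; genes outside it are ignored).
#' @param universe character vector of all testable genes (>= 2).
#' @return list with `k`, `n`, `K`, `N`, `p`, `odds_ratio`,
#'   `enrichment_ratio`.
#' @export
hypergeom_test <- function(module_genes, term_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stopf("universe must contain >= 2 genes")
  module_genes <- intersect(unique(module_genes), universe)
  term_genes <- intersect(unique(term_genes), universe)
  if (!length(module_genes)) stopf("empty module after universe restriction")
  N <- length(universe)
  K <- length(term_genes)
  n <- length(module_genes)
  k <- length(intersect(module_genes, term_genes))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                               cc <- cc + 0.5; d <- d + 0.5 }
  list(k = k, n = n, K = K, N = N, p = p,
       odds_ratio = (a * d) / (b * cc),
       enrichment_ratio = if (K == 0) 0 else (k / n) / (K / N))
}

#' Primary enrichment term of a module
#'
#' Tests the module against every eligible term of a collection and
#' returns the most significant one passing `pvalue_cutoff` (ties broken
#' toward the smaller, i.e. more specific, term), or `NULL` when none
#' passes.  Eligibility is governed by `cutoff_size`: by default terms
#' with at most `cutoff_size` genes in the universe are tested, which
#' favors specific terms; `size_mode = "min"` flips the inequality.
#'
#' @param module_genes character vector of module members.
#' @param collection named list of gene sets (see [read_gene_sets()]).
#' @param universe character vector of all testable genes.
#' @param pvalue_cutoff raw p-value cutoff (default 0.05).
#' @param cutoff_size term-size eligibility bound (default 50).
#' @param size_mode `"max"` (default: term size <= cutoff) or `"min"`.
#' @return one-row data.frame (`term`, `description`, `k`, `n`, `K`,
#'   `N`, `p`, `odds_ratio`, `enrichment_ratio`) or `NULL`.
#' @export
primary_term <- function(module_genes, collection, universe,
                         pvalue_cutoff = 0.05, cutoff_size = 50L,
                         size_mode = c("max", "min")) {
  size_mode <- match.arg(size_mode)
  tab <- enrich_terms(module_genes, collection, universe,
                      cutoff_size = cutoff_size, size_mode = size_mode)
  tab <- tab[tab$p < pvalue_cutoff, , drop = FALSE]
  if (!nrow(tab)) return(NULL)
  tab <- tab[order(tab$p, tab$K), , drop = FALSE]
  tab[1L, , drop = FALSE]
}

# Test one module against all eligible terms of a collection.
enrich_terms <- function(module_genes, collection, universe,
                         cutoff_size = 50L, size_mode = "max") {
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(id) {
    tg <- intersect(unique(collection[[id]]), universe)
    eligible <- if (size_mode == "max") length(tg) <= cutoff_size
                else length(tg) >= cutoff_size
    if (!length(tg) || !eligible) return(NULL)
    h <- hypergeom_test(module_genes, tg, universe)
    data.frame(term = id,
               description = if (is.null(desc)) NA_character_ else desc[[id]],
               k = h$k, n = h$n, K = h$K, N = h$N, p = h$p,
               odds_ratio = h$odds_ratio,
               enrichment_ratio = h$enrichment_ratio,
               row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), description = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), odds_ratio = numeric(),
                      enrichment_ratio = numeric()))
  do.call(rbind, rows)
}

#' Enrichment of every detected module against a gene-set collection
#'
#' Runs the hypergeometric test for each module against all eligible
#' terms, flags each module's primary term, and stacks the results.
#' The universe is the full set of analyzed genes (assigned or not),
#' since modules are drawn from the expressed set.
#'
#' @param assignment a `"module_assignment"` (or named integer vector).
#' @param collection named list of gene sets.
#' @param universe character vector; defaults to all genes in the
#'   assignment.
#' @inheritParams primary_term
#' @return data.frame with a `module` column, the [hypergeom_test()]
#'   fields per term, and `is_primary`.
#' @export
enrich_modules <- function(assignment, collection, universe = NULL,
                           pvalue_cutoff = 0.05, cutoff_size = 50L,
                           size_mode = c("max", "min")) {
  size_mode <- match.arg(size_mode)
  module <- if (inherits(assignment, "module_assignment"))
    assignment$module else assignment
  universe <- universe %||% names(module)
  ids <- sort(unique(module[module > 0L]))
  out <- lapply(ids, function(m) {
    g <- names(module)[module == m]
    tab <- enrich_terms(g, collection, universe,
                        cutoff_size = cutoff_size, size_mode = size_mode)
    if (!nrow(tab)) return(NULL)
    tab$module <- m
    tab <- tab[order(tab$p, tab$K), ]
    tab$is_primary <- FALSE
    if (tab$p[1L] < pvalue_cutoff) tab$is_primary[1L] <- TRUE
    tab[, c("module", setdiff(names(tab), "module"))]
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(module = integer(), term = character(),
                      description = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), odds_ratio = numeric(),
                      enrichment_ratio = numeric(),
                      is_primary = logical()))
  do.call(rbind, out)
}
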