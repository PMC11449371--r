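#' Construct a validated expression matrix
#'
#' The basic data container of the package: a gene x sample matrix of
#' log-scale expression values together with per-sample condition labels
#' (`"SN"` for controls, `"CN"` for treated samples) and an optional
#' region label.  All downstream stages (GAN training, trajectory
#' simulation, differential expression) consume this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#'   Dimnames are used as gene/sample ids when `gene_ids`/`sample_ids`
#'   are not given.
#' @param group character vector of per-sample condition labels, one of
#'   `"SN"` (control) or `"CN"` (treated).
#' @param gene_ids,sample_ids optional character vectors of unique ids.
#' @param region optional per-sample region label (e.g. a brain region);
#'   a single value is recycled.
#'
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `group` and `region`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' x <- expr_matrix(m, group = c("SN", "SN", "CN", "CN"))
#' x
#' @export
expr_matrix <- function(values, group, gene_ids = NULL, sample_ids = NULL,
                        region = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  gene_ids <- gene_ids %||% rownames(values) %||% paste0("gene", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||% paste0("sample", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stopf("gene_ids length (%d) does not match row count (%d)",
          length(gene_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stopf("sample_ids length (%d) does not match column count (%d)",
          length(sample_ids), ncol(values))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stopf("duplicated gene ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stopf("duplicated sample ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression values contain missing or non-finite entries")
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, ncol(values))
  if (length(group) != ncol(values))
    stopf("group length (%d) does not match sample count (%d)",
          length(group), ncol(values))
  bad <- setdiff(unique(group), c("SN", "CN"))
  if (length(bad))
    stopf("unknown group label(s): %s (expected SN or CN)",
          paste(bad, collapse = ", "))
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) == 1L) region <- rep(region, ncol(values))
    if (length(region) != ncol(values))
      stopf("region length does not match sample count")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, group = group, region = region),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d SN, %d CN)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "SN"), sum(x$group == "CN")))
  if (!is.null(x$region))
    cat("regions:", paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset samples of an expr_matrix by logical/integer index.
subset_samples <- function(x, idx) {
  expr_matrix(x$values[, idx, drop = FALSE], group = x$group[idx],
              gene_ids = x$gene_ids, sample_ids = x$sample_ids[idx],
              region = if (is.null(x$region)) NULL else x$region[idx])
}

#' Read an expression matrix from a delimited file
#'
#' Reads a TSV/CSV table (delimiter sniffed from the extension, or set
#' with `sep`) whose first column holds gene ids and whose remaining
#' columns are samples; `layout = "samples_in_rows"` reads the transposed
#' dialect.  Group (and optionally region) labels come from a sidecar
#' metadata table with columns `sample_id`, `group` and optionally
#' `region`.
#'
#' @param path path to the expression table.
#' @param meta path to the metadata table, or a `data.frame` with columns
#'   `sample_id` and `group` (and optional `region`).
#' @param layout `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep field delimiter; default guesses `","` for `.csv`, tab
#'   otherwise.
#' @param verbose log gene/sample counts.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, meta, layout = c("genes_in_rows", "samples_in_rows"),
                            sep = NULL, verbose = FALSE) {
  layout <- match.arg(layout)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2L) stopf("expression table %s has fewer than 2 columns", path)
  ids <- tab[[1L]]
  num <- tab[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  vals <- matrix(vals, nrow = nrow(num),
                 dimnames = list(ids, colnames(num)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric value at row '%s', column '%s' in %s",
          ids[bad[1L]], colnames(num)[bad[2L]], path)
  }
  if (layout == "samples_in_rows") vals <- t(vals)
  meta <- read_metadata(meta)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing))
    stopf("samples without group label in metadata: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  out <- expr_matrix(vals, group = meta$group,
                     region = if ("region" %in% names(meta)) meta$region else NULL)
  msgf(verbose, "read %d genes x %d samples from %s",
       nrow(out$values), ncol(out$values), path)
  out
}

read_metadata <- function(meta) {
  if (is.character(meta)) {
    sep <- if (grepl("\\.csv$", meta, ignore.case = TRUE)) "," else "\t"
    meta <- utils::read.table(meta, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, check.names = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Write an expression matrix to TSV
#'
#' @param x an [expr_matrix()] or plain matrix.
#' @param path output file; a `gene_id` first column is added.
#' @export
write_expression <- function(x, path) {
  vals <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample trait table
#'
#' The trait is a per-sample behavioral score (e.g. an addiction index),
#' non-negative, and 0 by convention for control (`SN`) samples.  The
#' table needs columns `sample_id` and `trait`.  Samples of `x` absent
#' from the table default to trait 0; every `CN` sample must be present.
#'
#' @param path TSV/CSV path or data.frame.
#' @param x optional [expr_matrix()] used to validate coverage and order
#'   the result.
#' @return named numeric vector of traits (names are sample ids).
#' @export
read_traits <- function(path, x = NULL) {
  if (is.character(path)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  } else tab <- as.data.frame(path)
  miss <- setdiff(c("sample_id", "trait"), names(tab))
  if (length(miss)) stopf("trait table missing column(s): %s",
                          paste(miss, collapse = ", "))
  tr <- as.numeric(tab$trait)
  names(tr) <- as.character(tab$sample_id)
  if (anyNA(tr)) stopf("trait table contains non-numeric trait values")
  if (any(tr < 0)) stopf("trait values must be non-negative")
  if (!is.null(x)) {
    cn <- x$sample_ids[x$group == "CN"]
    absent <- setdiff(cn, names(tr))
    if (length(absent))
      stopf("CN samples without a trait value: %s",
            paste(utils::head(absent, 5), collapse = ", "))
    out <- stats::setNames(rep(0, length(x$sample_ids)), x$sample_ids)
    out[names(tr)[names(tr) %in% x$sample_ids]] <-
      tr[names(tr) %in% x$sample_ids]
    tr <- out
  }
  tr
}

#' Log-CPM normalization of a count matrix
#'
#' Converts non-negative counts to log2 counts-per-million with a 0.5
#' pseudocount: `log2((count + 0.5) / (libsize + 1) * 1e6)`.  This is the
#' standard log-CPM transform used ahead of linear modelling of RNA-seq
#' counts; precision weights are not computed here, the downstream
#' method only needs a log-scale matrix.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param lib_size optional per-sample library sizes; defaults to the
#'   column sums of `counts`.
#' @param drop_zero drop genes with zero counts in all samples.
#' @return numeric matrix of log2-CPM values with the input dimnames.
#' @examples
#' log_cpm(matrix(0, 1, 1), lib_size = 999)  # log2(0.5/1000 * 1e6)
#' @export
log_cpm <- function(counts, lib_size = NULL, drop_zero = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  lib <- lib_size %||% colSums(counts)
  if (length(lib) != ncol(counts))
    stopf("lib_size length does not match sample count")
  if (any(lib <= 0)) stopf("zero library size in column(s): %s",
                           paste(which(lib <= 0), collapse = ", "))
  if (drop_zero) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  out <- log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' Within-group linear augmentation of training samples
#'
#' Expands each condition group by convex combinations of random
#' within-group sample pairs: each synthetic sample is
#' `alpha * x_a + (1 - alpha) * x_b` with `alpha ~ U(0, 1)` and `a`, `b`
#' distinct samples of the same group (mixup-style).  Per group,
#' `fold * group_size` synthetic samples are appended to the originals,
#' so augmented values never leave the per-gene within-group envelope
#' and group identity is preserved.
#'
#' @param x an [expr_matrix()]; each group needs at least 2 samples.
#' @param fold augmentation fold (>= 1); synthetic sample count per group
#'   is `fold * group_size`.
#' @param seed integer seed for reproducibility.
#' @return an [expr_matrix()] with originals followed by augmented
#'   samples (ids suffixed `_augN`).
#' @export
linear_augment <- function(x, fold = 10L, seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  fold <- as.integer(fold)
  if (fold < 1L) stopf("fold must be >= 1")
  sizes <- table(x$group)
  if (any(sizes < 2L))
    stopf("group(s) with fewer than 2 samples cannot be augmented: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  with_seed(seed, {
    pieces <- lapply(unique(x$group), function(g) {
      idx <- which(x$group == g)
      n_new <- fold * length(idx)
      a <- sample(idx, n_new, replace = TRUE)
      b <- vapply(a, function(i) sample(setdiff(idx, i), 1L), integer(1))
      alpha <- stats::runif(n_new)
      vals <- x$values[, a, drop = FALSE] *
        matrix(alpha, nrow(x$values), n_new, byrow = TRUE) +
        x$values[, b, drop = FALSE] *
        matrix(1 - alpha, nrow(x$values), n_new, byrow = TRUE)
      colnames(vals) <- sprintf("%s_aug%d", g, seq_len(n_new))
      list(values = vals, group = rep(g, n_new),
           region = if (is.null(x$region)) NULL else
             rep(x$region[idx[1L]], n_new))
    })
    vals <- cbind(x$values, do.call(cbind, lapply(pieces, `[[`, "values")))
    grp <- c(x$group, unlist(lapply(pieces, `[[`, "group")))
    reg <- if (is.null(x$region)) NULL else
      c(x$region, unlist(lapply(pieces, `[[`, "region")))
    expr_matrix(vals, group = grp, region = reg)
  })
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member genes.  Duplicate genes within a set are collapsed.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (names are term ids) with a
#'   `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT line %d has %d field(s); at least 3 required", i, length(f))
    ids[i] <- f[1L]
    desc[i] <- f[2L]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT line %d has an empty gene set", i)
    sets[[i]] <- genes
  }
  names(sets) <- ids
  names(desc) <- ids
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (optionally with a
#'   `"descriptions"` attribute as produced by [read_gene_sets()]).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "na", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
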