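test_that("expression tables round-trip through both layouts", {
  x <- tiny_expr(n_genes = 3, per_group = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  meta <- data.frame(sample_id = x$sample_ids, group = x$group)
  rd <- read_expression(f, meta)
  expect_equal(rd$values, x$values)
  expect_equal(dim(rd), c(3L, 4L))
  expect_equal(rd$group, x$group)

  # transposed dialect parses to the same object
  ft <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(x$values), t(x$values),
                   check.names = FALSE)
  write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  rd2 <- read_expression(ft, meta, layout = "samples_in_rows")
  expect_equal(rd2$values, x$values)
})

test_that("malformed expression input is rejected with named offenders", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "G1\t1\t2", "G1\t3\t4"), f)
  meta <- data.frame(sample_id = c("s1", "s2"), group = c("SN", "CN"))
  expect_error(read_expression(f, meta), "G1")

  writeLines(c("gene\ts1\ts2", "G1\t1\tx", "G2\t3\t4"), f)
  expect_error(read_expression(f, meta), "row 'G1'.*column 's2'")

  writeLines(c("gene\ts1\ts2", "G1\t1\t2"), f)
  expect_error(read_expression(f, meta[1, ]), "without group label")
})

test_that("log-CPM matches its closed form and scaling limits", {
  expect_equal(log_cpm(matrix(0, 1, 1), lib_size = 999)[1, 1],
               log2(500), tolerance = 1e-12)
  # doubling counts and library sizes barely moves large counts
  set.seed(1)
  counts <- matrix(rpois(200, 500), 20)
  d <- abs(log_cpm(2 * counts) - log_cpm(counts))
  expect_lt(max(d), 0.01)
  # equal columns under equal library sizes stay equal
  eq <- matrix(rep(c(5, 10, 985), 3), 3)
  out <- log_cpm(eq)
  expect_equal(out[, 1], out[, 2])
  expect_error(log_cpm(matrix(-1, 1, 1)), "non-negative")
  expect_error(log_cpm(matrix(0, 2, 2)), "library size")
})

test_that("linear augmentation keeps group sizes, envelope and determinism", {
  x <- tiny_expr(n_genes = 10, per_group = 4)
  aug <- linear_augment(x, fold = 10, seed = 9)
  expect_equal(sum(aug$group == "SN"), 4 + 40)
  expect_equal(sum(aug$group == "CN"), 4 + 40)
  # convexity: augmented values inside the per-gene within-group envelope
  for (g in c("SN", "CN")) {
    orig <- x$values[, x$group == g, drop = FALSE]
    new <- aug$values[, aug$group == g & grepl("_aug", aug$sample_ids)]
    expect_true(all(new >= apply(orig, 1, min) - 1e-12))
    expect_true(all(new <= apply(orig, 1, max) + 1e-12))
  }
  expect_identical(aug$values, linear_augment(x, fold = 10, seed = 9)$values)
  expect_false(identical(aug$values,
                         linear_augment(x, fold = 10, seed = 10)$values))

  # a group of identical samples only reproduces itself
  xx <- expr_matrix(matrix(3, 5, 4), group = c("SN", "SN", "CN", "CN"))
  expect_true(all(linear_augment(xx, fold = 1, seed = 1)$values == 3))
  one <- expr_matrix(matrix(1:10, 5), group = c("SN", "CN"))
  expect_error(linear_augment(one, fold = 2), "fewer than 2")
})

test_that("GMT collections parse, deduplicate and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc one\tG1\tG1\tG2",
               "term2\tdesc two\tG3\tG4\tG5"), f)
  sets <- read_gene_sets(f)
  expect_length(sets, 2)
  expect_equal(sets$term1, c("G1", "G2"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, f2)
  sets2 <- read_gene_sets(f2)
  expect_equal(sets2[], sets[])
  writeLines("term1\tonly-two-fields", f)
  expect_error(read_gene_sets(f), "line 1")
})

test_that("trait tables validate coverage and default controls to zero", {
  x <- tiny_expr(n_genes = 4, per_group = 2)
  tt <- data.frame(sample_id = x$sample_ids[x$group == "CN"],
                   trait = c(1.5, 2.5))
  tr <- read_traits(tt, x)
  expect_equal(unname(tr[x$group == "SN"]), c(0, 0))
  expect_equal(unname(tr[x$group == "CN"]), c(1.5, 2.5))
  expect_error(read_traits(tt[1, ], x), "without a trait")
  expect_error(read_traits(data.frame(sample_id = "a", trait = -1)),
               "non-negative")
})
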