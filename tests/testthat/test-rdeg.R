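test_that("variance moderation matches the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(1)
  s2 <- rchisq(200, df = 5) / 5 * exp(rnorm(200, sd = 0.8))
  sq <- squeeze_variance(s2, df = 5)
  lsq <- limma::squeezeVar(s2, df = 5)
  expect_equal(sq$df_prior, lsq$df.prior, tolerance = 1e-6)
  expect_equal(sq$var_prior, lsq$var.prior, tolerance = 1e-6)
  expect_equal(sq$var_post, lsq$var.post, tolerance = 1e-6)
  # homogeneous variances: infinite prior df, posterior collapses
  sqh <- squeeze_variance(rep(2, 100), df = 4)
  expect_equal(sqh$df_prior, Inf)
  expect_equal(unique(round(sqh$var_post, 10)),
               round(sqh$var_prior, 10))
})

test_that("moderated serial p-values match a limma fit on the differences", {
  skip_if_not_installed("limma")
  set.seed(2)
  n_rep <- 6; n_gene <- 120
  arr <- array(rnorm(n_rep * 3 * n_gene, sd = rep(runif(n_gene, 0.5, 2),
                                                  each = n_rep * 3)),
               dim = c(n_rep, 3, n_gene),
               dimnames = list(NULL, c(0, 50, 100),
                               paste0("g", seq_len(n_gene))))
  arr[, 2, 1:10] <- arr[, 2, 1:10] + 1       # shifted genes at t = 50
  sd_ <- serial_deg(arr, fc_threshold = 0.2, p_threshold = 0.05)
  # oracle: limma on the paired differences with an intercept design
  D <- t(arr[, 2, ] - arr[, 1, ])            # genes x repeats
  fit <- limma::eBayes(limma::lmFit(D, design = matrix(1, n_rep, 1)))
  expect_equal(unname(sd_$log2fc["50", ]), unname(fit$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(sd_$p["50", ]), unname(fit$p.value[, 1]),
               tolerance = 1e-6)
})

test_that("without moderation the serial test is the ordinary paired t-test", {
  set.seed(3)
  arr <- array(rnorm(5 * 2 * 30), dim = c(5, 2, 30),
               dimnames = list(NULL, c(0, 100), paste0("g", 1:30)))
  sd_ <- serial_deg(arr, moderated = FALSE)
  for (j in c(1, 7, 30)) {
    tt <- t.test(arr[, 2, j], arr[, 1, j], paired = TRUE)
    expect_equal(unname(sd_$p["100", j]), tt$p.value, tolerance = 1e-10)
    expect_equal(unname(sd_$log2fc["100", j]), unname(tt$estimate),
                 tolerance = 1e-12)
  }
})

test_that("null genes and identical repeats are never called", {
  arr <- array(rep(1:5, 2 * 4), dim = c(5, 2, 4),
               dimnames = list(NULL, c(0, 100), paste0("g", 1:4)))
  sd_ <- serial_deg(arr)
  expect_true(all(sd_$log2fc == 0))
  expect_true(all(!sd_$significant))
  expect_error(serial_deg(arr[1:2, , ]), "at least 3")
  arr[1, 1, 1] <- NA
  expect_error(serial_deg(arr), "non-finite")
})

test_that("endpoint-restricted serial testing reproduces the conventional test", {
  syn <- make_synthetic(seed = 4)
  st <- truth_stack(syn$truth, n_repeats = 8, timesteps = c(0, 100),
                    noise_sd = 0.2, seed = 5)
  sd_ <- serial_deg(st, paired = FALSE)
  # the same repeat-level endpoints laid out as an SN/CN expression matrix
  vals <- cbind(t(st[, 1, ]), t(st[, 2, ]))
  colnames(vals) <- paste0("r", 1:16)
  x <- expr_matrix(vals, group = rep(c("SN", "CN"), each = 8))
  cd <- conventional_deg(x)
  expect_equal(unname(sd_$log2fc["100", ]), cd$log2fc, tolerance = 1e-12)
  expect_equal(unname(sd_$p["100", ]), cd$p, tolerance = 1e-10)
  expect_equal(unname(sd_$significant["100", ]), cd$significant)
})

test_that("monotone planted genes are endpoint-significant at default effect", {
  syn <- make_synthetic(seed = 6)
  cd <- conventional_deg(syn$expr)
  up <- syn$truth$module_of_gene == which(
    syn$truth$archetype_of_module == "monotone_up")[1]
  expect_gt(mean(cd$significant[up]), 0.95)
  one <- ganex:::subset_samples(syn$expr, c(1, 13, 14))
  expect_error(conventional_deg(one), "2 samples")
})

test_that("more samples cannot lose endpoint power in expectation", {
  hits <- matrix(NA, 60, 2)
  for (i in seq_len(nrow(hits))) {
    syn_s <- make_synthetic(n_genes = 60, n_modules = 2,
                            archetypes = c("monotone_up", "flat"),
                            effect_size = 0.5, samples_per_group = 4,
                            module_sd = 0.1, seed = 1000 + i)
    syn_l <- make_synthetic(n_genes = 60, n_modules = 2,
                            archetypes = c("monotone_up", "flat"),
                            effect_size = 0.5, samples_per_group = 8,
                            module_sd = 0.1, seed = 1000 + i)
    up <- syn_s$truth$module_of_gene == 1
    hits[i, ] <- c(mean(conventional_deg(syn_s$expr)$significant[up]),
                   mean(conventional_deg(syn_l$expr)$significant[up]))
  }
  expect_gte(mean(hits[, 2]), mean(hits[, 1]))
})

test_that("rescue flags follow their definitions", {
  # hand-built serial result: g1 significant mid only, g2 endpoint + mid,
  # g3 never
  mk <- function(fc, p) {
    structure(list(
      log2fc = fc, p = p,
      significant = abs(fc) >= 0.2 & p <= 0.05,
      genes = colnames(fc), timesteps = as.numeric(rownames(fc)),
      thresholds = c(fc = 0.2, p = 0.05)), class = "rdeg_serial")
  }
  fc <- rbind(`50` = c(g1 = 0.5, g2 = 0.5, g3 = 0.0),
              `100` = c(g1 = 0.0, g2 = 0.6, g3 = 0.0))
  p <- rbind(`50` = c(0.001, 0.001, 0.9), `100` = c(0.9, 0.001, 0.9))
  serial <- mk(fc, p)
  endpoint <- data.frame(gene = c("g1", "g2", "g3"),
                         log2fc = c(0, 0.6, 0),
                         p = c(0.9, 0.001, 0.9),
                         significant = c(FALSE, TRUE, FALSE))
  rs <- rescue(serial, endpoint)
  rs <- rs[order(rs$gene), ]
  expect_equal(rs$rdeg, c(TRUE, TRUE, FALSE))
  expect_equal(rs$rescued, c(TRUE, FALSE, FALSE))
  expect_equal(rs$conventional_deg, c(FALSE, TRUE, FALSE))
  # rescued and conventional sets are disjoint by construction
  expect_true(!any(rs$rescued & rs$conventional_deg))
  expect_error(rescue(serial, endpoint[1:2, ]), "universes differ")
})
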