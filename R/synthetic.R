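#' Generate a synthetic two-condition expression data set with planted
#' module structure
#'
#' Emulates the data regime the pipeline targets: bulk log-scale
#' expression for two endpoint conditions (control `SN` at trajectory
#' time 0, treated `CN` at time 100), with genes organized into planted
#' co-expression modules that follow latent trajectory archetypes
#' (monotone up/down, intermediate peak, flat), plus unstructured
#' background genes.  A per-sample behavioral trait (addiction-index
#' style: non-negative, 0 for controls) is driven by the activity of one
#' designated module.  Intermediate timepoints are never observed in the
#' returned samples; the noiseless intermediate truth is available via
#' [truth_trajectory()] and [truth_profile()] for validating the
#' simulation stages.
#'
#' The gene model is `x[g, s] = baseline[g] + loading[g] *
#' (archetype(t_s) + eta[m, s]) + eps[g, s]` where `eta` is module-level
#' activity jitter shared by all genes of a module (co-regulation noise)
#' and `eps` is independent per-gene noise.  Intermediate-peak modules
#' are calibrated so their endpoint fold change sits below the rescued-
#' DEG fold threshold while the peak fold change sits above it, which is
#' what makes rescue testable.
#'
#' @param n_genes total gene count.
#' @param n_modules number of planted modules; archetypes are recycled
#'   from `archetypes`.
#' @param samples_per_group samples per condition (>= 3).
#' @param effect_size log2-scale separation scale of the trajectory
#'   archetypes (endpoint log2 fold change of a monotone module gene with
#'   unit loading).
#' @param noise_sd per-gene Gaussian noise SD (log2 scale).
#' @param module_sd SD of the shared module-activity jitter.
#' @param module_size genes per planted module; default splits genes as
#'   evenly as feasible leaving some background.
#' @param archetypes character vector recycled over modules; each of
#'   `"monotone_up"`, `"monotone_down"`, `"intermediate_peak"`, `"flat"`.
#' @param peak_times peak positions in (0, 100) assigned in order to the
#'   intermediate-peak modules; defaults spread over \[30, 70\].
#' @param peak_width Gaussian bump SD on the 0..100 time axis.
#' @param trait_module index of the module whose activity drives the
#'   trait.
#' @param trait_coef,trait_intercept,trait_sd linear trait model
#'   `trait = trait_coef * activity + trait_intercept + N(0, trait_sd)`,
#'   floored at 0, applied to CN samples (SN traits are 0).
#' @param counts also simulate a negative-binomial count matrix whose
#'   log-CPM approximates `values` (for exercising [log_cpm()]
#'   end-to-end).
#' @param seed integer seed.
#'
#' @return list with `expr` (an [expr_matrix()]), `traits` (named
#'   numeric, 0 for SN), `truth` (class `"synth_truth"`: module
#'   assignment, archetypes, peak times, loadings, baselines, per-sample
#'   activities, parameters) and optionally `counts`.
#' @examples
#' syn <- make_synthetic(n_genes = 60, n_modules = 3,
#'                       samples_per_group = 4, seed = 1)
#' table(syn$truth$module_of_gene)
#' @export
make_synthetic <- function(n_genes = 300L, n_modules = 5L,
                           samples_per_group = 12L,
                           effect_size = 2, noise_sd = 0.3, module_sd = 0.3,
                           module_size = NULL,
                           archetypes = c("monotone_up", "monotone_down",
                                          "intermediate_peak",
                                          "intermediate_peak", "flat"),
                           peak_times = NULL, peak_width = 12,
                           trait_module = 1L,
                           trait_coef = 2, trait_intercept = 1,
                           trait_sd = 0.3,
                           counts = FALSE, seed = 7L) {
  n_genes <- as.integer(n_genes); n_modules <- as.integer(n_modules)
  samples_per_group <- as.integer(samples_per_group)
  if (samples_per_group < 3L) stopf("samples_per_group must be >= 3")
  module_size <- as.integer(module_size %||% (n_genes %/% (n_modules + 1L)))
  if (module_size < 2L || n_genes < n_modules * module_size)
    stopf("infeasible sizes: %d genes cannot hold %d modules of %d genes",
          n_genes, n_modules, module_size)
  if (trait_module < 1L || trait_module > n_modules)
    stopf("trait_module must index a planted module")
  arch <- rep_len(match.arg(archetypes,
                            c("monotone_up", "monotone_down",
                              "intermediate_peak", "flat"),
                            several.ok = TRUE), n_modules)
  n_peak <- sum(arch == "intermediate_peak")
  if (is.null(peak_times)) {
    peak_times <- if (n_peak <= 1L) rep(50, n_peak) else
      seq(30, 70, length.out = n_peak)
  }
  if (length(peak_times) != n_peak)
    stopf("need %d peak time(s), got %d", n_peak, length(peak_times))
  pk <- rep(NA_real_, n_modules)
  pk[arch == "intermediate_peak"] <- peak_times

  with_seed(seed, {
    module_of_gene <- integer(n_genes)
    for (m in seq_len(n_modules))
      module_of_gene[seq_len(module_size) + (m - 1L) * module_size] <- m
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    names(module_of_gene) <- gene_ids

    baseline <- stats::rnorm(n_genes, mean = 6, sd = 2)
    loading <- stats::runif(n_genes, 0.7, 1.3)
    loading[module_of_gene == 0L] <- 0

    n <- 2L * samples_per_group
    grp <- rep(c("SN", "CN"), each = samples_per_group)
    sample_ids <- sprintf("%s%02d", grp, c(seq_len(samples_per_group),
                                           seq_len(samples_per_group)))
    t_of_sample <- ifelse(grp == "SN", 0, 100)

    truth <- structure(list(
      module_of_gene = module_of_gene,
      archetype_of_module = stats::setNames(arch, seq_len(n_modules)),
      peak_time = stats::setNames(pk, seq_len(n_modules)),
      peak_width = peak_width,
      trait_module = as.integer(trait_module),
      effect_size = effect_size, noise_sd = noise_sd,
      module_sd = module_sd, loading = stats::setNames(loading, gene_ids),
      baseline = stats::setNames(baseline, gene_ids)),
      class = "synth_truth")

    # module activities per real sample: archetype value at the sample's
    # endpoint time plus shared jitter
    activity <- matrix(0, n_modules, n, dimnames = list(NULL, sample_ids))
    for (m in seq_len(n_modules))
      activity[m, ] <- truth_trajectory(truth, m, t_of_sample) +
        stats::rnorm(n, sd = module_sd)

    vals <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n,
                   dimnames = list(gene_ids, sample_ids))
    vals <- vals + baseline
    planted <- module_of_gene > 0L
    vals[planted, ] <- vals[planted, ] +
      loading[planted] * activity[module_of_gene[planted], , drop = FALSE]

    truth$activity <- activity
    expr <- expr_matrix(vals, group = grp)

    traits <- stats::setNames(rep(0, n), sample_ids)
    cn <- grp == "CN"
    traits[cn] <- pmax(0, trait_coef * activity[trait_module, cn] +
                            trait_intercept + stats::rnorm(sum(cn), sd = trait_sd))

    out <- list(expr = expr, traits = traits, truth = truth)
    if (counts) {
      mu <- pmax(2^vals, 1e-8)
      cnts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                     n_genes, n, dimnames = dimnames(vals))
      out$counts <- cnts
    }
    out
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  sizes <- table(factor(x$module_of_gene[x$module_of_gene > 0],
                        levels = seq_along(x$archetype_of_module)))
  cat(sprintf("synth_truth: %d genes, %d modules (trait module %d)\n",
              length(x$module_of_gene), length(x$archetype_of_module),
              x$trait_module))
  for (m in seq_along(x$archetype_of_module)) {
    cat(sprintf("  module %d: %s, %d genes%s\n", m,
                x$archetype_of_module[m], sizes[m],
                if (!is.na(x$peak_time[m]))
                  sprintf(" (peak t=%g)", x$peak_time[m]) else ""))
  }
  invisible(x)
}

#' Noiseless archetype value of a planted module
#'
#' Returns the latent activity of a planted module at trajectory time
#' `t` on the 0..100 axis, without any noise: linear in `t` for monotone
#' archetypes (0 at t = 0, +/- `effect_size` at t = 100), a Gaussian
#' bump of height `effect_size` centered at the module's peak time for
#' intermediate-peak archetypes, and 0 everywhere for flat modules.
#'
#' @param truth a `"synth_truth"` object from [make_synthetic()].
#' @param module planted module id.
#' @param t numeric vector of times in \[0, 100\].
#' @return numeric vector of activities, one per element of `t`.
#' @export
truth_trajectory <- function(truth, module, t) {
  stopifnot(inherits(truth, "synth_truth"))
  module <- as.integer(module)
  if (module < 1L || module > length(truth$archetype_of_module))
    stopf("unknown module %d", module)
  e <- truth$effect_size
  switch(truth$archetype_of_module[[module]],
    monotone_up = e * t / 100,
    monotone_down = -e * t / 100,
    intermediate_peak = e * exp(-(t - truth$peak_time[[module]])^2 /
                                  (2 * truth$peak_width^2)),
    flat = rep(0, length(t)))
}

#' Repeat-stack of trajectory-driven profiles from the synthetic truth
#'
#' Builds a repeat x timestep x gene array of independent
#' [truth_profile()] realizations, emulating the repeat axis of a
#' [average_profile()] stack (independent re-simulations of the same
#' underlying trajectory).  Repeat-level noise is homogeneous: the
#' module-jitter SD defaults to the gene-noise SD, since checkpoint
#' repeats re-simulate the same biology rather than new animals.
#'
#' @param truth a `"synth_truth"` object.
#' @param n_repeats number of repeats (>= 3 for the serial test).
#' @param timesteps times on the 0..100 axis.
#' @param noise_sd per-gene noise SD (default: recorded in `truth`).
#' @param module_sd shared module-jitter SD per repeat (default:
#'   `noise_sd`).
#' @param seed integer seed.
#' @return 3-d array with dimnames (repeat, timestep, gene), directly
#'   consumable by [serial_deg()].
#' @export
truth_stack <- function(truth, n_repeats = 10L, timesteps = 0:100,
                        noise_sd = truth$noise_sd, module_sd = noise_sd,
                        seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  genes <- names(truth$module_of_gene)
  arr <- array(NA_real_, dim = c(n_repeats, length(timesteps), length(genes)),
               dimnames = list(NULL, timesteps, genes))
  for (r in seq_len(n_repeats))
    arr[r, , ] <- truth_profile(truth, timesteps = timesteps,
                                noise_sd = noise_sd, module_sd = module_sd,
                                seed = child_seed(seed, r))
  arr
}

#' Trajectory-driven expression profile from the synthetic truth
#'
#' Builds the idealized counterpart of the GAN-averaged profile: a
#' timestep x gene matrix in which each planted gene follows its
#' module's noiseless archetype (scaled by the gene loading) plus shared
#' module jitter and per-gene noise.  Used to validate network
#' construction and the serial differential test independently of GAN
#' training.
#'
#' @param truth a `"synth_truth"` object.
#' @param timesteps times on the 0..100 axis (default all 101).
#' @param noise_sd,module_sd noise levels; default those recorded in
#'   `truth`.  Set both to 0 for the noiseless profile.
#' @param seed integer seed.
#' @return numeric matrix, `length(timesteps)` x genes, with gene ids as
#'   column names and timesteps as row names.
#' @export
truth_profile <- function(truth, timesteps = 0:100,
                          noise_sd = truth$noise_sd,
                          module_sd = truth$module_sd, seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  genes <- names(truth$module_of_gene)
  n_t <- length(timesteps)
  with_seed(seed, {
    act <- vapply(seq_along(truth$archetype_of_module), function(m) {
      truth_trajectory(truth, m, timesteps) + stats::rnorm(n_t, sd = module_sd)
    }, numeric(n_t))  # n_t x n_modules
    out <- matrix(stats::rnorm(n_t * length(genes), sd = noise_sd),
                  n_t, length(genes), dimnames = list(timesteps, genes))
    out <- out + matrix(truth$baseline, n_t, length(genes), byrow = TRUE)
    planted <- truth$module_of_gene > 0L
    out[, planted] <- out[, planted] +
      act[, truth$module_of_gene[planted], drop = FALSE] *
      matrix(truth$loading[planted], n_t, sum(planted), byrow = TRUE)
    out
  })
}
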