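#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()],
#' with every stage's tunables as named, defaulted fields.  User
#' configurations (lists or YAML files) are merged over these defaults,
#' so only deviations need to be specified.  Protocol constants default
#' to the published procedure: 10-fold linear augmentation, 35,000
#' candidate draws and 10 nearest latents per resembled fake at the 0.95
#' Pearson gate, 99 intermediate timesteps, |log2FC| 0.2 / p 0.05
#' rescue thresholds, |r| > 0.5 / p < 0.05 trait criteria, enrichment
#' p < 0.05 with term-size cutoff 50.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    out_dir = "ganex_out",
    seed = 7L,
    resume = TRUE,
    expr = NULL, meta = NULL, traits = NULL, gmt = NULL,
    normalize = "none",
    synthetic = NULL,
    augment_fold = 10L,
    gan = list(latent_dim = 32L, hidden = c(128L, 128L), lambda_gp = 10,
               critic_steps = 5L, lr = 1e-4, total_steps = 2000L,
               batch_size = 32L, n_checkpoints = 10L,
               quality_threshold = 0.95),
    trajectory = list(n_candidates = 35000L, k = 10L, steps = 99L,
                      max_retries = 20L),
    network = list(),
    alignment = list(alpha = 0.05, r_threshold = 0.5),
    temporal = list(edge_threshold = 0.5, t_early = 10, t_late = 90),
    rdeg = list(fc_threshold = 0.2, p_threshold = 0.05),
    enrichment = list(pvalue_cutoff = 0.05, cutoff_size = 50L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config %||% list())
}

# One cached stage: if `resume` and the artifact exists, load it;
# otherwise compute, save, and mark as computed.
stage_cached <- function(path, resume, fun) {
  if (resume && file.exists(path))
    return(list(value = readRDS(path), computed = FALSE))
  value <- fun()
  saveRDS(value, path)
  list(value = value, computed = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, augmentation, WGAN-GP training, trajectory
#' simulation, network construction, module-trait alignment, temporal
#' network assembly, rescued-DEG testing and (when a GMT collection is
#' given) module enrichment, once per region label, writing artifacts
#' and a JSON manifest under `config$out_dir`.  Stages whose cached
#' artifact already exists are reloaded when `config$resume` is `TRUE`,
#' so a partially complete output directory resumes where it stopped.
#'
#' Input is either real data (`expr` + `meta` + optional `traits`
#' paths, with `normalize = "log-cpm"` for raw counts) or a synthetic
#' fixture (`synthetic` = list of [make_synthetic()] arguments).
#'
#' @param config nested list or YAML file path; see [default_config()].
#' @param verbose log stage progress.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- ingest ------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    syn <- do.call(make_synthetic,
                   c(cfg$synthetic, list(seed = cfg$synthetic$seed %||%
                                           cfg$seed)))
    x_all <- syn$expr
    traits <- syn$traits
    truth <- syn$truth
  } else {
    if (is.null(cfg$expr) || is.null(cfg$meta))
      stopf("config must provide either 'synthetic' or 'expr' + 'meta'")
    x_all <- read_expression(cfg$expr, cfg$meta, verbose = verbose)
    if (identical(cfg$normalize, "log-cpm"))
      x_all <- expr_matrix(log_cpm(x_all$values), group = x_all$group,
                           region = x_all$region)
    traits <- if (is.null(cfg$traits))
      stats::setNames(as.numeric(x_all$group == "CN"), x_all$sample_ids)
      else read_traits(cfg$traits, x_all)
    truth <- NULL
  }
  regions <- cfg$regions %||% unique(x_all$region %||% "all")

  manifest <- list(
    package = "ganex",
    version = as.character(utils::packageVersion("ganex")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = cfg$seed,
    config = cfg,
    input = list(n_genes = nrow(x_all$values),
                 n_samples = ncol(x_all$values),
                 n_sn = sum(x_all$group == "SN"),
                 n_cn = sum(x_all$group == "CN"),
                 checksum = sprintf("%.6f", sum(x_all$values)),
                 synthetic = !is.null(cfg$synthetic)),
    regions = list())

  for (region in regions) {
    x <- if (is.null(x_all$region) || identical(region, "all")) x_all
      else subset_samples(x_all, x_all$region == region)
    rdir <- file.path(cfg$out_dir, region)
    dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
    stages <- list()
    seed_r <- child_seed(cfg$seed, match(region, regions))

    msgf(verbose, "[%s] augment", region)
    st <- stage_cached(file.path(rdir, "01_augment.rds"), cfg$resume,
                       function() linear_augment(x, fold = cfg$augment_fold,
                                                 seed = child_seed(seed_r, 1)))
    x_aug <- st$value
    stages$augment <- list(done = TRUE, computed = st$computed,
                           n_train = ncol(x_aug$values))

    msgf(verbose, "[%s] train", region)
    st <- stage_cached(file.path(rdir, "02_gan.rds"), cfg$resume,
                       function() do.call(wgan, c(list(x = x_aug,
                                                       seed = child_seed(seed_r, 2),
                                                       verbose = verbose),
                                                  cfg$gan)))
    fit <- st$value
    stages$train <- list(done = TRUE, computed = st$computed,
                         checkpoints = fit$config$checkpoint_steps,
                         final_critic_loss =
                           utils::tail(fit$log$critic_loss, 1L))

    msgf(verbose, "[%s] simulate", region)
    st <- stage_cached(file.path(rdir, "03_trajectory.rds"), cfg$resume,
                       function() do.call(average_profile,
                                          c(list(fit = fit, x = x,
                                                 seed = child_seed(seed_r, 3),
                                                 verbose = verbose),
                                            cfg$trajectory)))
    stack <- st$value
    write_expression(t(stack$profile), file.path(rdir, "profile.tsv"))
    utils::write.table(stack$fakes, file.path(rdir, "resembled_fakes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages$simulate <- list(
      done = TRUE, computed = st$computed,
      n_repeats = dim(stack$stack)[1L],
      n_timesteps = dim(stack$stack)[2L],
      min_achieved_r = min(stack$fakes$achieved_r),
      resembled_fakes = stack$fakes)

    msgf(verbose, "[%s] network", region)
    st <- stage_cached(file.path(rdir, "04_network.rds"), cfg$resume,
                       function() {
      ncfg <- do.call(network_config, cfg$network)
      sft <- pick_soft_threshold(stack$profile, ncfg)
      prof <- drop_constant_genes(stack$profile, warn = FALSE)
      A <- adjacency(prof, beta = sft$beta, type = ncfg$network_type)
      modules <- detect_modules(tom(A), ncfg)
      eig <- module_eigengenes(stack$profile, modules)
      list(soft_threshold = sft, modules = modules, eigengenes = eig)
    })
    net <- st$value
    utils::write.table(
      data.frame(gene = names(net$modules$module),
                 module = net$modules$module),
      file.path(rdir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(timestep = rownames(net$eigengenes$eigengenes),
                 net$eigengenes$eigengenes, check.names = FALSE),
      file.path(rdir, "eigengenes_sim.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    stages$network <- list(done = TRUE, computed = st$computed,
                           beta = net$soft_threshold$beta,
                           met_scale_free_target =
                             net$soft_threshold$met_target,
                           n_modules = length(net$modules$sizes),
                           n_assigned = sum(net$modules$module > 0L))

    msgf(verbose, "[%s] trait alignment", region)
    st <- stage_cached(file.path(rdir, "05_alignment.rds"), cfg$resume,
                       function() module_trait_alignment(
      net$modules, x, traits, sim_loadings = net$eigengenes,
      alpha = cfg$alignment$alpha, r_threshold = cfg$alignment$r_threshold))
    align <- st$value
    utils::write.table(align, file.path(rdir, "trait_alignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages$alignment <- list(
      done = TRUE, computed = st$computed,
      n_passing = sum(align$passes),
      n_positive = sum(align$passes & align$r > 0),
      n_negative = sum(align$passes & align$r < 0),
      table = align)

    msgf(verbose, "[%s] temporal network", region)
    st <- stage_cached(file.path(rdir, "06_temporal.rds"), cfg$resume,
                       function() {
      if (ncol(net$eigengenes$eigengenes) < 2L) return(NULL)
      tn <- module_network(net$eigengenes,
                           edge_threshold = cfg$temporal$edge_threshold,
                           t_early = cfg$temporal$t_early,
                           t_late = cfg$temporal$t_late)
      groups <- cluster_modules(tn)
      attr(groups, "network")
    })
    tn <- st$value
    if (!is.null(tn)) {
      utils::write.table(tn$nodes, file.path(rdir, "temporal_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(tn$edges, file.path(rdir, "temporal_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stages$temporal <- list(done = TRUE, computed = st$computed,
                            n_edges = if (is.null(tn)) 0L else nrow(tn$edges))

    msgf(verbose, "[%s] rescued DEG", region)
    st <- stage_cached(file.path(rdir, "07_rdeg.rds"), cfg$resume,
                       function() {
      serial <- serial_deg(stack, fc_threshold = cfg$rdeg$fc_threshold,
                           p_threshold = cfg$rdeg$p_threshold)
      endpoint <- conventional_deg(x, fc_threshold = cfg$rdeg$fc_threshold,
                                   p_threshold = cfg$rdeg$p_threshold)
      rescue(serial, endpoint)
    })
    rdeg_tab <- st$value
    utils::write.table(rdeg_tab, file.path(rdir, "rdeg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stages$rdeg <- list(done = TRUE, computed = st$computed,
                        n_conventional = sum(rdeg_tab$conventional_deg),
                        n_rdeg = sum(rdeg_tab$rdeg),
                        n_rescued = sum(rdeg_tab$rescued))

    if (!is.null(cfg$gmt)) {
      msgf(verbose, "[%s] enrichment", region)
      st <- stage_cached(file.path(rdir, "08_enrich.rds"), cfg$resume,
                         function() {
        sets <- read_gene_sets(cfg$gmt)
        enrich_modules(net$modules, sets,
                       pvalue_cutoff = cfg$enrichment$pvalue_cutoff,
                       cutoff_size = cfg$enrichment$cutoff_size)
      })
      enr <- st$value
      utils::write.table(enr, file.path(rdir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stages$enrich <- list(done = TRUE, computed = st$computed,
                            n_primary = sum(enr$is_primary),
                            primary = enr[enr$is_primary, , drop = FALSE])
    }

    manifest$regions[[region]] <- list(
      n_samples = ncol(x$values), stages = stages,
      truth_trait_module = if (!is.null(truth)) truth$trait_module else NULL)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Human-readable pipeline report
#'
#' Summarizes a pipeline manifest as Markdown: per region, the stage
#' summary counts and the module table joining trait alignment (`Corr`,
#' `P.val`) with each module's primary enrichment term (`G.Pv`, `OR`,
#' `ER`) when enrichment ran.  Incomplete manifests yield a partial
#' report with a warning line rather than an error.
#'
#' @param manifest manifest list from [run_pipeline()] or path to a
#'   `manifest.json`.
#' @return character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lines <- c(sprintf("# Pipeline report (%s %s, seed %s)",
                     manifest$package %||% "ganex",
                     manifest$version %||% "?", manifest$seed %||% "?"), "")
  for (region in names(manifest$regions)) {
    rg <- manifest$regions[[region]]
    st <- rg$stages
    lines <- c(lines, sprintf("## Region %s", region), "")
    expected <- c("augment", "train", "simulate", "network", "alignment",
                  "temporal", "rdeg")
    missing <- setdiff(expected, names(st))
    if (length(missing))
      lines <- c(lines, sprintf("**Incomplete manifest**: missing stage(s) %s",
                                paste(missing, collapse = ", ")), "")
    if (!is.null(st$network))
      lines <- c(lines, sprintf(
        "- %d modules (beta = %s, scale-free target %s)",
        st$network$n_modules, st$network$beta,
        if (isTRUE(st$network$met_scale_free_target)) "met" else "not met"))
    if (!is.null(st$alignment))
      lines <- c(lines, sprintf(
        "- %d trait-passing modules (%d positive / %d negative)",
        st$alignment$n_passing, st$alignment$n_positive,
        st$alignment$n_negative))
    if (!is.null(st$rdeg))
      lines <- c(lines, sprintf(
        "- %d conventional DEG, %d rDEG, %d rescued",
        st$rdeg$n_conventional, st$rdeg$n_rdeg, st$rdeg$n_rescued))
    lines <- c(lines, "")
    if (!is.null(st$alignment$table) && length(st$alignment$table)) {
      tab <- as.data.frame(st$alignment$table)
      out <- data.frame(Module = tab$module, Corr = round(tab$r, 3),
                        P.val = signif(tab$p, 3), Passes = tab$passes)
      if (!is.null(st$enrich$primary) && length(st$enrich$primary)) {
        pr <- as.data.frame(st$enrich$primary)
        idx <- match(out$Module, pr$module)
        out$G.Pv <- signif(pr$p[idx], 3)
        out$OR <- round(pr$odds_ratio[idx], 2)
        out$ER <- round(pr$enrichment_ratio[idx], 2)
        out$Term <- pr$term[idx]
      }
      hdr <- paste(names(out), collapse = " | ")
      sep <- paste(rep("---", ncol(out)), collapse = " | ")
      body <- apply(out, 1, function(r) paste(r, collapse = " | "))
      lines <- c(lines, hdr, sep, body, "")
    } else {
      lines <- c(lines, "No passing modules to report.", "")
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
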