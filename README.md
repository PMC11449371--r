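# ganex

Generative simulation of intermediate expression trajectories between two
observed conditions, with time-resolved co-expression module analysis and
rescued differential expression.

## The problem

Endpoint-only bulk RNA-seq designs — a control group and a treated group —
cannot see genes whose expression rises and falls *between* the endpoints:
their endpoint log2 fold change is near zero, so a conventional
differential-expression (DEG) contrast discards them. `ganex` targets
researchers who have exactly such two-condition data plus a per-sample
behavioral or clinical score (for example an addiction index measured in
treated animals), and who want a principled screen for intermediate-stage
genes and modules.

## The method

1. **Generative model.** A Wasserstein GAN with gradient penalty (WGAN-GP)
   is trained on the (10-fold mixup-augmented) log-scale profiles:

   `L = E[D(x~)] − E[D(x)] + λ E[(‖∇x̂ D(x̂)‖₂ − 1)²]`,

   with the generator maximizing `E[D(x~)]`, RMSprop updates, and 5 critic
   steps per generator step. Both networks are small tanh MLPs; all
   gradients, including the second-order penalty term, are hand-derived and
   finite-difference-validated.
2. **Resembled fakes.** Each real sample is anchored in latent space: of
   35,000 candidate draws, the 10 latents whose generated profiles best
   correlate with the sample (each Pearson r ≥ 0.95) are averaged into
   `z̄`; the gate is re-checked on `G(z̄)`.
3. **Latent interpolation.** For every control × treated pair,
   `Δ = z̄_CN − z̄_SN` and `G(z̄_SN + Δ·i/100)`, `i = 1..99`, give a
   101-timestep trajectory; trajectories are averaged over all pairs and
   over 10 generator checkpoints.
4. **Co-expression modules.** On the averaged profile: soft-threshold
   adjacency (signed by default), topological overlap, average-linkage
   clustering with a static height cut. Module eigengenes (first PCs) are
   recomputed in the *real* samples and correlated with the trait; a module
   passes at `p < 0.05` and `|r| > 0.5`.
5. **Temporal networks.** Modules align to their eigengene peak timestep
   (early/mid/late), connect by signed eigengene correlations (`|r| ≥
   0.5`), and cluster into pattern groups within stages.
6. **Rescued DEG.** Treating the 10 per-checkpoint trajectories as
   replicas, each timestep is tested against t = 0 with a moderated
   (empirical-Bayes) paired t-test; a gene significant (`|log2FC| ≥ 0.2`,
   `p ≤ 0.05`) at some timestep but not in the conventional endpoint test
   is *rescued*.
7. **Enrichment.** Hypergeometric over-representation of each module
   against GMT gene sets (p < 0.05, term size ≤ 50) selects a primary term
   per module.

A synthetic-data module (`make_synthetic()`) plants co-expression modules
with known trajectory archetypes (monotone, intermediate-peak, flat) and a
trait loaded on one module, so the full pipeline is testable without any
external download.

## Worked example

```r
library(ganex)

syn <- make_synthetic(seed = 7)          # 300 genes, 12 SN + 12 CN samples
aug <- linear_augment(syn$expr, fold = 10, seed = 11)
fit <- wgan(aug, total_steps = 2000, seed = 42)
print(fit)
#> wgan fit: 300 genes, latent dim 32, hidden (128, 128)
#> 2000 generator steps (5 critic steps each), 10 checkpoints
#> final losses: critic -13.4665, generator 11.7841, penalty 0.3577

generation_quality(fit, syn$expr, n_draws = 2000, seed = 1)
#> generation quality: best-match Pearson per real sample
#>   min 0.9754 / median 0.9804 / max 0.9859 (gate 0.95: pass)
#>   per-gene mean cor 0.9997, per-gene variance cor 0.9577

stack <- average_profile(fit, syn$expr, seed = 5)
print(stack)
#> trajectory stack: 10 repeats x 101 timesteps x 300 genes
#> 12 SN x 12 CN pairs; achieved r range 0.9588 - 0.9914

prof <- averaged_profile(stack)
cfg  <- network_config()
sft  <- pick_soft_threshold(prof, cfg)
mods <- detect_modules(tom(adjacency(prof, sft$beta, cfg$network_type)), cfg)
eig  <- module_eigengenes(prof, mods)
module_trait_alignment(mods, syn$expr, syn$traits, sim_loadings = eig)
#>   module size          r            p passes region
#> 1      1  207  0.9489314 1.675096e-12   TRUE   <NA>
#> 2      2   93 -0.9523812 7.887231e-13   TRUE   <NA>
```

The training gate reports, per real sample, the best Pearson correlation
against 2,000 generated profiles — all above the 0.95 protocol threshold.
The trajectory stack records, per sample and checkpoint, the achieved
correlation of its resembled fake (minimum 0.959 here). On the averaged
trajectories the heavily smoothed curves cluster into two large modules
(rising and falling); the module containing the planted trait-driving genes
correlates with the synthetic addiction index at r = 0.95 in the real
samples and passes the `|r| > 0.5`, `p < 0.05` criteria.

The same stages run from one configuration via `run_pipeline()` (or the
thin CLI in `inst/cli/ganex.R`), which writes per-stage TSV artifacts and a
JSON manifest, and `serial_deg()` / `conventional_deg()` / `rescue()`
produce the rescued-gene table.

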