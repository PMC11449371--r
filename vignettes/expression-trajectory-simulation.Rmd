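---
title: "Simulating intermediate expression trajectories with a WGAN-GP and analyzing them as co-expression networks"
author: "ganex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intermediate expression trajectories with a WGAN-GP and analyzing them as co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk RNA-seq studies of a progressive condition typically sample only the
endpoints: a control group and a treated/affected group. Genes whose
expression rises and then falls *between* those endpoints are invisible to an
endpoint contrast — their endpoint fold change is near zero — yet they may be
exactly the intermediate regulators one wants to find. `ganex` implements a
generative strategy for this setting: learn a generative model of the
observed endpoint transcriptomes, anchor every real sample in the model's
latent space, interpolate between control and treated anchors to synthesize
the unobserved intermediate time course, and then run systems-level analyses
(co-expression modules, trait correlation, serial differential testing) on
the simulated trajectories.

Nothing in the simulation adds information that is not in the endpoint data;
the generator can only interpolate along the data manifold it has learned.
What the method buys is a *structured* interpolation — one that respects the
joint distribution of genes rather than interpolating each gene
independently — plus a statistical framework (replicated trajectories) in
which intermediate-stage effects can be tested.

## The generative model

The generator `G` maps a latent vector `z ~ N(0, I_d)` to a full expression
profile; the critic `D` scores profiles. Both are fully connected networks
with tanh hidden layers. Training minimizes the Wasserstein objective with a
gradient penalty,

```
L_critic = E[D(G(z))] - E[D(x)] + lambda * E[(||grad_xhat D(xhat)|| - 1)^2]
L_gen    = -E[D(G(z))]
```

with `xhat` drawn uniformly on segments between real and generated batch
rows (`xhat = eps * x_real + (1 - eps) * x_fake`, `eps ~ U(0,1)` per row).
The critic takes `critic_steps` (default 5) updates per generator update;
both use RMSprop.

Because no automatic-differentiation stack is assumed, the gradients are
hand-derived. The penalty term needs the derivative of the critic's *input
gradient* with respect to the critic's *parameters* (a second-order
quantity); it is computed by forward-over-reverse differentiation: the
adjoint `R = dP/dg` of the input gradient is pushed through a tangent
(dual-number) forward stream, and a reverse sweep through both the primal
and tangent streams yields exact parameter gradients. tanh is used precisely
because this construction needs a twice-differentiable activation. The
implementation is validated against finite differences in the test suite.

Tunables that matter (all exposed in `wgan()` and the pipeline config):

* `latent_dim` (default 32) — the dimension of the latent prior. It bounds
  the complexity of the manifold the generator can represent; a few tens of
  dimensions suffice for a few hundred genes with block structure.
* `hidden` (default 128, 128) — layer widths shared by generator and critic.
* `lambda_gp` (default 10) — the penalty weight; the conventional value.
* `lr` (default 1e-4) and `total_steps` (default 2000) — at desk scale
  (hundreds of genes, a few thousand generator steps) a learning rate of
  1e-4 reaches the data scale within the step budget; published full-scale
  trainings run an order of magnitude longer with smaller rates.
* `standardize` (default TRUE) — genes are standardized before training and
  generated output is returned in original units. This keeps network inputs
  in a numerically comfortable range whatever the expression scale, and is
  inverted exactly on output.
* `checkpoint_steps` — generator snapshots, by default 10 evenly spaced
  steps over the second half of training. The checkpoints are deliberately
  *not* just the final model: they act as quasi-independent draws from the
  training trajectory and become the repeat axis of the simulation.

Training data are first expanded by `linear_augment()`: per condition group,
`fold` (default 10) times the group size of synthetic samples, each a convex
combination `alpha * x_a + (1 - alpha) * x_b` of a random within-group pair
with `alpha ~ U(0, 1)`. This mixup-style scheme never extrapolates (every
augmented value stays inside the per-gene within-group envelope) and
preserves group identity.

## Resembled fakes and latent interpolation

A *resembled fake* anchors a real sample in latent space: draw 35,000
candidate latents, rank the generated profiles by Pearson correlation with
the target sample, require the 10 best to reach r >= 0.95, and average their
latents into `z_bar`. The achieved correlation is then *recomputed* on
`G(z_bar)` — averaging latents does not preserve the selection correlations
— and must itself clear the gate; otherwise the draw is retried with a
shifted seed (cap: 20 retries). The averaging makes the anchor stable: a
single best latent can sit in a thin ridge of the manifold, while the mean
of ten near-optimal latents is robust to the draw.

For every control x treated sample pair, with `delta = z_CN - z_SN`, the
trajectory is `G(z_SN + delta * i/100)` for `i = 1..99`, flanked by the two
endpoint profiles — 101 timesteps on a 0..100 axis, where 0 is the control
state. Trajectories are averaged over all pairs within a checkpoint, and the
stack over the 10 checkpoints is the `trajectory_stack`; its mean is the
averaged profile that the network stage consumes. Means commute, so the
order of averaging does not affect the profile; it does define the replica
unit of the serial test (see below), and both readings — checkpoints as
replicas (default) or pairs as replicas — are available via `repeat_axis`.

Latent interpolation is *not* feature-space interpolation: for a nonlinear
trained generator the per-gene curves are generically non-linear in `i`
(the test suite asserts the departure, and exact equality for a linear
generator).

## Co-expression networks on the simulated time course

The network stage is a from-scratch implementation of weighted co-expression
analysis:

* **Adjacency**: `a_ij = ((1 + r_ij)/2)^beta` (signed, the package default)
  or `|r_ij|^beta` (unsigned). The signed default matters here: on
  trajectories, a monotone-decreasing module is the mirror image of a
  monotone-increasing one, and unsigned similarity would merge the two into
  a single module by construction. Unsigned remains available (and is the
  classic tutorial convention) via `network_config(network_type =
  "unsigned")`.
* **Soft threshold**: the smallest power on the grid whose signed scale-free
  fit index (R^2 of the log-log degree-distribution regression, negated for
  positive slopes) reaches 0.8. Smooth low-dimensional trajectory data
  frequently never reaches that target — the degree distribution of a
  block-structured network is not scale-free — so a fallback takes the
  argmax of the fit index floored at the field-standard power (6 unsigned /
  12 signed) and flags `met_target = FALSE`. This mirrors what happens on
  real data sets where the conventional criterion cannot be met.
* **Topological overlap**: `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 -
  a_ij)` with `l_ij = sum_u a_iu a_uj` over `u != i, j`; validated against a
  triple-loop oracle.
* **Modules**: average-linkage clustering of `1 - TOM`, cut statically at
  `cut_height_fraction` (default 0.99) of the maximal merge height;
  clusters below `min_module_size` (default 10 at this package's default
  problem scale; 30 is the genome-scale convention) are unassigned. A
  static cut with a size filter stands in for the dynamic tree-cut
  heuristics; it is transparent and reproducible, at the cost of some
  fragility when between-module merge heights approach the cut (see
  Limitations).
* **Eigengenes**: per module, the first principal component of the
  standardized member genes across conditions, unit variance, sign-oriented
  to correlate non-negatively with the module mean profile.

**Module–trait alignment** bridges simulated and real data: modules are
detected on the simulated profile, but each module's eigengene is
*recomputed* by PCA across the real samples (sign tied to the simulated
loadings), then correlated with the per-sample behavioral trait (controls
carry trait 0). Two-sided p-values use the exact t transform
`t = r sqrt(n-2)/sqrt(1-r^2)`. A module passes at `p < 0.05` and
`|r| > 0.5`; no multiplicity correction is applied, matching the stated
criteria (Benjamini–Hochberg is available behind `adjust = TRUE`).

## Temporal module networks

Each module is aligned to the timestep where its simulated eigengene peaks
(ties to the earliest timestep, so a constant eigengene lands at 0 — a
documented artifact) and staged early/mid/late with boundaries `t_early =
10`, `t_late = 90`; these boundaries are a package choice, exposed in
config. An alternative alignment by the largest absolute first difference
(`mode = "diff"`) emphasizes where profiles change fastest and is useful
because most monotone modules otherwise pile up at the endpoints. Module
pairs with `|r| >= 0.5` between eigengene time profiles form signed edges;
within each stage the correlation submatrix is clustered (average linkage
on `1 - r`, cut to 2 groups) to label pattern groups such as mid1/mid2.

## Rescued differential expression (rDEG)

The serial test treats the repeats of the trajectory stack as biological
replicas. For every timestep `t >= 1`, each gene's log2 fold change is the
mean over repeats of `x_t - x_0`, tested with a moderated paired t-test:
gene-wise variances are shrunk toward a common prior, `s2_post = (d0 s0^2 +
d s2)/(d0 + d)`, with the prior `(d0, s0^2)` estimated by method of moments
on `log s2` (trigamma inversion); the moderated t gains `d0` degrees of
freedom. The implementation is written from these formulas and
cross-checked against an established empirical-Bayes implementation in the
tests. Pairing across repeats is the default because repeats share a
checkpoint; an unpaired variant exists. Significance at a timestep requires
`|log2FC| >= 0.2` and `p <= 0.05` (raw, per timestep — the union over
timesteps is reported, not corrected).

A gene significant at one or more timesteps is an rDEG; an rDEG that the
conventional endpoint comparison (same thresholds, moderated two-sample
test on the real samples) does *not* call is *rescued* — the typical rescue
is a gene with an intermediate peak and flat endpoints. Restricted to the
two endpoints, the serial criterion coincides exactly with the conventional
criterion applied to repeat-level endpoints; this consistency is asserted
in the tests.

## Enrichment

Modules are annotated by a hypergeometric over-representation test against
flat GMT gene sets, with the analyzed gene set as universe (modules are
drawn from the expressed genes, so a genome-wide universe would inflate
enrichment). `cutoff_size` (default 50) bounds the *maximum* term size:
selecting the "primary" term per module should favor specific terms over
broad ones. The opposite reading (minimum size) is available via
`size_mode = "min"`. Odds ratios use a Haldane 0.5 correction when a table
cell is zero. No term-graph structure is modelled; collections are flat
sets.

## The synthetic generator

`make_synthetic()` is first-class, tested code, not a fixture dump. It
emulates the regime the method targets: two endpoint conditions (12 + 12
samples by default), 300 genes, five planted modules following trajectory
archetypes — monotone up, monotone down, two intermediate peaks (t = 30 and
t = 70, Gaussian bumps of width 12 calibrated so endpoint fold changes sit
below the 0.2 rescue threshold while peak fold changes sit above it), and
flat — plus unstructured background genes. Genes load on their module's
activity (`x = baseline + loading * (archetype(t) + module jitter) + gene
noise`); the behavioral trait of each treated sample is a positive affine
function of the trait module's activity plus noise, and 0 for controls.
Default noise levels (gene noise SD 0.3, module jitter SD 0.3 on a log2
scale with baseline SD 2 and effect size 2) were chosen once as plausible
for strongly-responding bulk tissue contrasts.

What the generator does *not* emulate: count-level sampling (a
negative-binomial mode exists for exercising the log-CPM path, but the
default is Gaussian on the log scale), library-size and batch artifacts,
correlated background structure, or realistic gene-gene correlation decay.
Passing tests on this generator therefore demonstrate that the pipeline's
machinery recovers planted structure under its own assumptions — not that
the biology of any particular real data set would be recovered.

`truth_trajectory()`, `truth_profile()` and `truth_stack()` expose the
noiseless intermediate truth and trajectory-driven realizations so that the
network and rDEG stages can be validated in isolation from GAN training
fidelity (GAN-dependent checks — the 0.95 resembled-fake gate, protocol
constants, trait recovery through the full pipeline — run on the actual
trained model).

## Numerical choices and degenerate inputs

* Problem sizes used by the validation suite: 300 genes, 24 samples, 2000
  generator steps, 35,000-candidate resembled fakes at 10 checkpoints, 101
  timesteps. One full train + simulate pass completes in a few minutes on a
  single CPU.
* Seeds: every stochastic function takes a `seed`; the pipeline derives
  per-stage child seeds deterministically, and equal seeds give bitwise
  equal results (single-threaded BLAS assumed).
* Constant genes are dropped (with a warning) before network construction;
  zero-variance genes are a hard error in `adjacency()`.
* A zero-variance trait is an error, not a NaN correlation.
* Ties in peak alignment resolve to the earliest timestep.
* `trigamma` inversion for the variance prior uses Newton iteration with
  the standard asymptotic starting point; homogeneous variances yield an
  infinite prior df and a collapsed posterior, and `moderated = FALSE`
  recovers the ordinary t-test (the `d0 -> 0` limit).
* Retry seeds for resembled fakes increment deterministically from the
  stage seed, so retries are reproducible.

## Known limitations

* The generator is trained on endpoints only; trajectories are
  interpolations on the learned manifold, not observations. Intermediate
  "time" is latent-path arc position, mapped linearly onto 0..100; it has
  no calibrated relation to experimental time.
* On heavily averaged trajectories most gene curves are smooth and mutually
  correlated, so module detection at this stage typically yields few, large
  modules and the scale-free criterion is not met (the fallback power path
  is the norm, not the exception, on simulated profiles).
* The static tree cut is brittle when between-module merge heights approach
  the cut height; at very low noise with a low fallback power, distinct
  modules can merge. The fit-based power selection compensates at moderate
  noise; for difficult data, raise `beta_floor` or lower
  `cut_height_fraction`.
* The per-timestep rescue criterion is intentionally uncorrected across 99
  timesteps; rescued calls should be read as screening hypotheses, and the
  per-timestep type-I control (asserted on null data) does not bound the
  union rate.
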