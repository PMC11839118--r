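---
title: "Microniche case-control analysis of spatial molecular data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microniche case-control analysis of spatial molecular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-sample spatial molecular experiments — multiplexed imaging panels,
spatial transcriptomics — ask a deceptively simple question: *which tissue
structures differ between cases and controls?*  Answering it requires (i) a
representation of local tissue organisation that is comparable across
samples, (ii) a unit of analysis fine enough to capture structures that do
not respect predefined cell-type or region boundaries, and (iii) a test
that is calibrated despite small sample sizes, donor structure, and the
enormous multiplicity of spatial locations.

`vima` implements an end-to-end pipeline for this problem:

1. **Pixel preprocessing.** Each sample is rasterized into pixels (10 µm by
   default), tissue is segmented from background, pixels are
   log-normalized, reduced to `K` *meta-markers* by PCA on locally averaged
   "meta-pixels", batch-corrected across samples, and standardized.
2. **Patch fingerprints.** The tissue is cut into overlapping 40×40-pixel
   patches; an ensemble of `E` conditional variational autoencoders (cVAEs)
   is trained to reconstruct them, and each patch's *fingerprint* is the
   posterior mean of its latent encoding.
3. **Microniches.** For each encoder, a k-nearest-neighbour graph of
   fingerprints is built and a random walk of adaptively chosen length `s`
   defines, for every patch, a soft, overlapping *microniche*.  The
   microniche abundance tensor (MAT) `Q[n, p, e]` is the expected fraction
   of sample *n*'s patches that arrive at patch *p* after `s` steps in
   graph *e*.
4. **Association testing.**  Microniche abundances are standardized and
   correlated with the phenotype; the per-encoder correlations `C[e, p]`
   are meta-analyzed into a *microniche coefficient*
   `rho_p = sum_e C^3 / sum_e C^2` (an average weighted by each encoder's
   squared correlation), with an empirical false discovery rate from
   donor-preserving permutations.  The *global* statistic
   `R = mean_p (sum_e C^4 / sum_e C^2)` is tested against the same
   permutation null.

## The model, briefly

**Normalization.**  For a pixel with channel values `p_1..p_M` and dataset
median total intensity `q`, the normalized value is
`log(q * p_m / sum(p))`.  Zero entries are stabilized: intensity data
substitutes a pseudocount (`eps = 1`) in the numerator; transcript counts
map zeros to `log1p(0) = 0`.  Rescaling the whole dataset by a constant
shifts these values additively by `log c` — the shift is removed by the PCA
centering, so meta-markers are scale-free.

**The cVAE.**  Each autoencoder is a compact residual convolutional
network: a stem convolution, three residual stages (default widths 64,
128, 256) with stride-2 downsampling (40 → 20 → 10 → 5), global average
pooling, and a linear head emitting a posterior mean and log-variance of
dimension `C` (100 by default).  The decoder mirrors the scale schedule
with nearest-neighbour upsampling and one convolution per scale (the
exact layer plan is recorded in each model's `arch_plan`).  The loss is the per-element reconstruction
MSE plus `beta` (default `1e-5`) times the KL divergence from the standard
normal prior, optimized with Adam (learning rate `1e-3`, decayed ×0.9 per
epoch), KL warm-up over 5 epochs, an 80/20 train/validation split, and 20
epochs with optional 5-epoch extensions while the validation loss improves
by more than 0.5% per epoch (capped at 60).  Conditioning: a learned
4-dimensional per-sample embedding (one-hot sample ID plus any covariates,
linearly mapped; encoder and decoder each learn their own) is broadcast
spatially and concatenated to the representation at every stage.  Giving
both encoder and decoder access to sample identity lets the variational
penalty push sample-specific information out of the latent code.  Because
no deep-learning framework is a dependency, the layers and backpropagation
are implemented in the package (C++ im2col convolutions, BLAS matrix
products); gradients are verified against finite differences in the test
suite.

**Fingerprints are posterior means.**  We encode deterministically with
`mu(p)` rather than sampling `z`: it is lower-variance and reproducible.
Patches with tissue fraction at or below `alpha = 0.5` are excluded from
the analysis set (but still train the autoencoders).

**The random walk.**  The walk's transition operator is the row-normalized
`A_e + I`; the `+ I` self-loop keeps mass at the anchor, and
row-normalization is required for the arrival probabilities to be a
proper distribution (mass conservation is asserted to `1e-8` in the
tests).  The number of steps is chosen per encoder by tracking the median,
across microniches, of the Fisher kurtosis of each microniche's
across-sample abundance and stopping when its relative decrease falls
below 3% — with the proviso that microniches must actually have drawn
mass from more than one sample before a plateau counts as convergence
(otherwise a frozen, disconnected graph would "converge" instantly); if
that never happens the walk stops at `s_max = 10` with a warning.

**Testing.**  Binary phenotypes are encoded 0/1; all phenotypes are
standardized.  Permutations shuffle phenotype values at the *donor* level,
so samples from one donor always share a value.  P-values use the add-one
estimator `(1 + #{null >= obs}) / (1 + n_perm)`, with rejection at
`p <= alpha`; the floor is `1/(n_perm + 1)`.  The empirical FDR at a
threshold is the permutation-expected number of null coefficients beyond
it divided by the observed number beyond it, computed separately for the
positive and negative tails on the grid of observed values, and isotonized
by a running minimum toward extreme thresholds so the curve is monotone.
The local and global tests share one set of permutation draws.
Covariates, when supplied, are projected out of both the MAT columns and
the phenotype by least squares before correlation.

**Batch correction.**  Pixel meta-markers are corrected by an iterative
soft-clustering linear correction: each round softly clusters the
corrected values (entropic k-means on cosine-normalized vectors,
`sigma = 0.4`, up to 50 clusters, 20 rounds) and then recomputes the
corrected values *from the original meta-markers* by subtracting
ridge-shrunk per-cluster per-sample mean deviations.  Recomputing from the
original values each round — rather than compounding shifts — bounds the
total correction by the batch deviations actually present: per-pixel
offsets are removed while per-sample differences in cluster *abundance*,
which are exactly what association testing consumes, are preserved.  (A
naive compounding variant provably erases confounded case-control signal;
the package's tests pin both behaviours: offsets removed to within 0.1,
abundance signal retained.)  The corrected meta-markers are standardized
dataset-wide per channel with the population (1/n) variance convention —
this is what makes the "dataset-mean predictor has MSE 1" baseline exact.

## The synthetic-data generator

`generate_dataset()` emulates a multi-sample intensity experiment: a
disc-shaped tissue mask with a wavy boundary inside a 96×96-pixel frame,
per-channel backgrounds that are Gaussian random fields (smoothing scale
20 px) plus white noise around a common baseline, dim extra-tissue
background (so foreground segmentation is a real step), 5 channels, 8
samples/donors by default, and a horizontal "signal band" mimicking a
cortical layer.  Case/control structure is spiked into one channel around
foci drawn as a Poisson process in the band (rate 0.01 per pixel):

* type A — cases receive a Gaussian blur of diameter 7 px per focus,
  controls nothing;
* type B — blur(7) in cases versus blur(51) in controls, total spiked
  mass matched so only the geometry differs;
* type C — a disc of diameter 7 px versus a 1×33 px strip, mass matched.

A blur of "diameter d" is a Gaussian with `sigma = d/4`.  The spike
amplitude defaults to 10× the background baseline, calibrated once so
that, after log-normalization, PCA and standardization, focus peaks land
roughly 5 standardized meta-marker units above the background texture's
own extreme envelope — the scale at which a focal cellular aggregate
stands out from tissue.  Label noise `h` re-assigns a random fraction of
samples' observed labels; truth (per-sample label and the signal-region
mask) is retained for scoring.

What the generator does *not* emulate: real segmentation artifacts,
technical batch effects with structure beyond per-sample shifts,
cell-scale texture, multi-donor sampling designs, or modality-specific
noise (e.g. MERFISH spot misassignment).  Passing tests on this generator
therefore demonstrates calibration and the mechanics of signal recovery,
not performance on any real cohort.

## Problem sizes used by the validation suite

All validation runs on one CPU.  The type-I-error experiment uses the
generator's default 8 samples, an ensemble of `E = 2` encoders with
`C = 20` latent dimensions, stage widths (6, 12, 24), 10 epochs, 100 null
label simulates and 200 permutations per test — the simulation-scale
analogue of the full method (the full-scale defaults are `E = 10`,
`C = 100`, widths (64, 128, 256), 20+ epochs).  The power study uses 12
samples: with only 8 samples a donor-level permutation null has just
C(8,4) = 70 distinct relabelings, which caps achievable power at
`alpha = 0.05` regardless of effect size, whereas the reference
simulation design this emulates used 27 samples.  Power replicates run
the ensemble pipeline with `E = 2` encoders (the same configuration as
the type-I experiment; the ensemble meta-analysis contributes real power
even at `E = 2`), stage widths (6, 12, 24), an 88×88-pixel frame, and
minibatches of 64 (a batch of 256 would give only ~2 gradient steps per
epoch at a few hundred patches).  The single-representation variant
(`cvae_single`) and the flattened-PCA, two-layer-convnet and patch-mean
embeddings remain available through `power_experiment()` for ablation
sweeps.

## Design choices where the design was genuinely open

* **Stride 10 px** between patch anchors (≈10,000 patches per cm² at
  10 µm pixels); patches are fully contained in the raster — no edge
  padding, avoiding zero-padding artifacts in the autoencoder.
* **Otsu on the log scale** for intensity foregrounds: raw-scale Otsu on
  heavy-tailed summaries can split the bright tail (dense aggregates)
  from everything else and classify ordinary tissue as background;
  thresholding `log1p(summary)` with the same 256-bin between-class
  variance maximization is robust to this and is oracle-tested.
* **Per-encoder walk length**, since graphs differ across encoders; all
  chosen values are recorded in the fitted object.
* **Graph weights** follow the standard fuzzy-connectivity construction
  used throughout single-cell analysis (per-point kernel calibrated to
  `log2(k)` total membership, fuzzy-union symmetrization); the oracle and
  property tests treat the exact kernel as an implementation detail.
* **Two-tailed FDR handling**: positive and negative tails are
  thresholded separately, each with its own empirical FDR curve, and the
  significant set is their union.
* **Microniche mass truncation** at `1e-6` (with row renormalization)
  keeps the MAT effectively sparse; the dense-oracle test bounds the
  error.
* **Ensemble seeds** derive from one base seed (`seed * 131 + e`), so a
  single integer reproduces the entire fit.

## Known limitations

* The emergent benefit of sample-ID conditioning — better sample mixing
  of fingerprints than an unconditioned autoencoder — requires
  production-scale training; at the reduced scale of this package's test
  suite it does not reproduce, and the suite instead verifies the conditioning
  *mechanism* (identity channels demonstrably enter encoder and decoder).
  On real data, follow the `beta`-escalation guidance: if patches
  integrate poorly across samples, raise `beta` one order of magnitude at
  a time.
* Training on CPU is the dominant cost; the implementation is exact but
  not a speed match for GPU frameworks.  Widths, latent dimension, batch
  size and epochs are all configurable for scale.
* The batch correction is a compact implementation of the
  soft-clustering linear-correction family, not a drop-in reimplementation
  of any published tool; its contracts (offset removal, abundance
  preservation, standardization) are what the tests pin down.
* With very few samples, permutation granularity limits both power and
  the resolution of empirical FDRs; the package reports the add-one
  floor rather than extrapolating.

## A worked example

```{r}
library(vima)

# simulate a small case-control cohort with focal signal
ds <- generate_dataset(sim_config(n_samples = 12, seed = 1))

# preprocess: segment, normalize, meta-markers, batch-correct, patches
pre <- vima_preprocess(ds$rasters, modality = "intensity")

# fit: train the ensemble, build microniches, run the tests
fit <- vima(pre$patches, ds$metadata, E = 2,
            config = cvae_config(latent_dim = 20, epochs = 10,
                                 widths = c(6, 12, 24)),
            n_perm = 500, fdr_level = 0.1, seed = 1)
print(fit)
summary(fit)
head(patch_results(fit))
plot(fit)
```
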