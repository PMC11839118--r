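# vima

Case-control association analysis for multi-sample spatial molecular
data — multiplexed imaging (CODEX, immunofluorescence) and spatial
transcriptomics (e.g. MERFISH) — for analysts who need to ask *which
tissue structures differ between cases and controls?* with calibrated
statistics rather than visual inspection.

## What it does

Given per-sample rasters of marker intensities or transcript counts and a
sample-level metadata table (`sample_id`, `donor_id`, `phenotype`,
optional covariates), the pipeline:

1. segments tissue from background (10-transcript rule for count data;
   log-scale Otsu for intensity data), log-normalizes pixels
   (`log(q p_m / Σp)` with dataset median total `q`), reduces markers to
   `K` **meta-markers** by PCA on 5×5 meta-pixels, and batch-corrects and
   standardizes them across samples;
2. cuts tissue into overlapping 40×40-pixel patches and trains an
   ensemble of `E` **conditional variational autoencoders** (compact
   residual convolutional networks, implemented in the package with C++
   convolution kernels) whose posterior means are the patch
   **fingerprints**;
3. defines one soft, overlapping **microniche** per patch and encoder via
   a random walk on the fingerprint k-NN graph (transition operator:
   row-normalized `A + I`; walk length chosen adaptively from the
   kurtosis of across-sample microniche abundances), assembling the
   samples × patches × encoders **microniche abundance tensor** `Q`;
4. tests association: per-encoder Pearson correlations `C[e, p]` between
   standardized microniche abundance and the phenotype are meta-analyzed
   into microniche coefficients

   ρ<sub>p</sub> = Σ<sub>e</sub> C<sub>e,p</sub>³ / Σ<sub>e</sub> C<sub>e,p</sub>²,

   with empirical FDRs from donor-preserving permutations, and a global
   statistic

   R = (1/P) Σ<sub>p</sub> (Σ<sub>e</sub> C<sub>e,p</sub>⁴ / Σ<sub>e</sub> C<sub>e,p</sub>²),

   whose permutation P-value summarizes the whole matrix.

A synthetic-data module (`sim_config()`, `generate_dataset()`,
`type1_experiment()`, `power_experiment()`, `spatial_accuracy()`)
generates multi-sample rasters with tissue masks, donor structure and
focal/diffuse/striated spiked signals, and runs the calibration and power
experiments used to validate the method.

## A worked example

```r
library(vima)

ds  <- generate_dataset(sim_config(n_samples = 12, seed = 1))
pre <- vima_preprocess(ds$rasters, modality = "intensity")
fit <- vima(pre$patches, ds$metadata, E = 2,
            config = cvae_config(latent_dim = 20, epochs = 10,
                                 widths = c(6, 12, 24)),
            n_perm = 500, fdr_level = 0.1, seed = 1)
print(fit)
```

```
Microniche case-control analysis
  432 analysis patches (of 432), 12 samples, 2 encoders
  global R = 0.615, P = 0.002 (500 permutations)
  227 positively / 205 negatively associated patches at FDR 10%
```

(A few minutes on one CPU.)  The global `R` is the correlation mass in
the microniche-by-encoder matrix; `P = 0.002` is the permutation floor
`1/(n_perm + 1)` here — no donor-relabeled dataset produced as much
correlation mass, i.e. tissue organisation differs between the case and
control samples.  The significant patches are the
ones driving it: `patch_results(fit)` returns each analysis patch with
its sample, anchor coordinates, microniche coefficient `rho` (a signed,
correlation-scale effect size), tail and significance call, and
`plot(fit)` lays out the consensus fingerprint graph with patches colored
by `rho`.  `coef(fit)` returns the coefficient vector.

For file-based workflows a thin command-line driver ships in
`inst/cli/vima.R` with `simulate` / `preprocess` / `train` / `test`
subcommands operating on TIFF + CSV inputs.

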