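#' Simulation configuration
#'
#' Describes a synthetic multi-sample intensity dataset: per-channel
#' smooth background textures on a tissue mask, a designated signal
#' region (a horizontal band, mimicking a cortical layer), and spiked
#' signal structures whose geometry differs between cases and controls.
#'
#' Signal types (all added to one designated channel, with total spiked
#' mass matched between case and control geometries so that only the
#' geometry differs):
#' * `A_focal_vs_none`: cases get a Gaussian blur of diameter 7 px around
#'   each focus; controls get nothing.
#' * `B_focal_vs_diffuse`: cases get blur(7); controls blur(51).
#' * `C_focal_vs_striated`: cases get a disc of diameter 7 px; controls a
#'   1 x 33 px rectangle.
#' * `null`: no signal; labels are random.
#'
#' @param n_samples number of samples (default 8).
#' @param n_donors number of donors (default `n_samples`).
#' @param raster_extent_px spatial extent, `c(X, Y)` (default 96 x 96).
#' @param n_channels number of marker channels (default 5).
#' @param signal_type one of `"A_focal_vs_none"`, `"B_focal_vs_diffuse"`,
#'   `"C_focal_vs_striated"`, `"null"`.
#' @param focus_density Poisson rate of foci per signal-region pixel
#'   (default 0.01, the sparse end of a dense suprathreshold-focus
#'   process).
#' @param amplitude peak added intensity of a case focus, in units of the
#'   background baseline (default 10).  The default is calibrated so
#'   that, after log-normalization, PCA and standardization, focus peaks
#'   reach roughly 5 standardized meta-marker units above the background
#'   texture's extreme envelope -- the intensity scale at which focal
#'   cellular aggregates stand out from tissue background.
#' @param label_noise_h fraction of samples whose case/control label is
#'   re-assigned at random (0 to 0.5; default 0).
#' @param signal_channel channel receiving the spikes (default 2).
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8, n_donors = n_samples,
                       raster_extent_px = c(96, 96), n_channels = 5,
                       signal_type = c("A_focal_vs_none",
                                       "B_focal_vs_diffuse",
                                       "C_focal_vs_striated", "null"),
                       focus_density = 0.01, amplitude = 10,
                       label_noise_h = 0, signal_channel = 2, seed = 1) {
  signal_type <- match.arg(signal_type)
  stopifnot(label_noise_h >= 0, label_noise_h <= 0.5, n_donors <= n_samples,
            n_channels >= 2)
  structure(list(n_samples = n_samples, n_donors = n_donors,
                 raster_extent_px = raster_extent_px,
                 n_channels = n_channels, signal_type = signal_type,
                 focus_density = focus_density, amplitude = amplitude,
                 label_noise_h = label_noise_h,
                 signal_channel = signal_channel, seed = seed),
            class = "sim_config")
}

## separable Gaussian smoothing of a matrix (reflecting borders)
.gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(pmin(pmax(seq(1 - r, n + r), 1), n))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  sm <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
}

## Gaussian random field: smoothed white noise, standardized
.grf <- function(X, Y, scale = 20) {
  f <- .gauss_smooth(matrix(rnorm(X * Y), X, Y), scale / 4)
  (f - mean(f)) / sd(f)
}

## additive spike kernel centred at (cx, cy), returned as a full matrix
.spike <- function(X, Y, cx, cy, shape, peak) {
  m <- matrix(0, X, Y)
  if (shape$kind == "blur") {
    sigma <- shape$diameter / 4
    r <- ceiling(shape$diameter)
    xs <- max(1, cx - r):min(X, cx + r)
    ys <- max(1, cy - r):min(Y, cy + r)
    m[xs, ys] <- peak * exp(-(outer((xs - cx)^2, (ys - cy)^2, `+`)) /
                              (2 * sigma^2))
  } else if (shape$kind == "disc") {
    r <- shape$diameter / 2
    xs <- max(1, floor(cx - r)):min(X, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(Y, ceiling(cy + r))
    inside <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2
    m[xs, ys][inside] <- peak
  } else {  # rect: 1 px tall, `len` px wide strip
    half <- floor(shape$len / 2)
    xs <- max(1, cx - half):min(X, cx + half)
    if (cy >= 1 && cy <= Y) m[xs, cy] <- peak
  }
  m
}

#' Generate a synthetic multi-sample spatial dataset
#'
#' Backgrounds are per-channel Gaussian random fields (smoothing scale 20
#' px) plus white noise around a baseline, on a disc-shaped tissue mask
#' surrounded by dim background.  Foci are drawn as a Poisson process in
#' the signal band; spikes are added to the designated channel with
#' case/control geometry per the signal type (total mass matched).  True
#' labels are balanced across donors; observed labels re-assign a random
#' fraction `h` of samples.
#'
#' @param config a [sim_config()].
#' @return list with `rasters` (list of [sample_raster()]), `metadata`
#'   (a [sample_metadata()] with observed labels), `truth` (a
#'   `sim_truth`: per-sample true labels and per-sample signal-region
#'   masks).
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  X <- config$raster_extent_px[1]
  Y <- config$raster_extent_px[2]
  if (X < 40 || Y < 40) stop("extent too small for patch extraction")
  M <- config$n_channels
  ns <- config$n_samples
  donors <- rep(seq_len(config$n_donors), length.out = ns)
  # balanced true labels at the donor level
  dl <- rep(c(1, 0), length.out = config$n_donors)
  dl <- dl[sample.int(config$n_donors)]
  true_label <- dl[donors]
  # tissue mask: disc with wavy boundary
  cx <- X / 2; cy <- Y / 2
  rad <- 0.58 * min(X, Y)
  # signal band: horizontal stripe through the middle of the tissue
  band <- c(floor(0.35 * Y), ceiling(0.65 * Y))

  shape_case <- switch(config$signal_type,
                       A_focal_vs_none = list(kind = "blur", diameter = 7),
                       B_focal_vs_diffuse = list(kind = "blur", diameter = 7),
                       C_focal_vs_striated = list(kind = "disc",
                                                  diameter = 7),
                       `null` = NULL)
  shape_ctrl <- switch(config$signal_type,
                       A_focal_vs_none = NULL,
                       B_focal_vs_diffuse = list(kind = "blur",
                                                 diameter = 51),
                       C_focal_vs_striated = list(kind = "rect", len = 33),
                       `null` = NULL)
  # unit-peak mass of each geometry, for mass matching
  unit_mass <- function(shape) {
    if (is.null(shape)) return(NA_real_)
    sum(.spike(201, 201, 101, 101, shape, 1))
  }
  mass_case <- unit_mass(shape_case)

  rasters <- vector("list", ns)
  region_masks <- vector("list", ns)
  baseline <- 10
  for (n in seq_len(ns)) {
    wob <- .grf(X, Y, scale = 25)
    dist2 <- outer((seq_len(X) - cx)^2, (seq_len(Y) - cy)^2, `+`)
    tissue <- sqrt(dist2) <= rad * (1 + 0.08 * wob)
    vals <- array(0, c(X, Y, M))
    for (m in seq_len(M)) {
      tex <- baseline + 2.5 * .grf(X, Y, 20) + rnorm(X * Y)
      vals[, , m] <- pmax(tex, 0.1) * tissue + pmax(rnorm(X * Y, 1, 0.3), 0)
    }
    region <- matrix(FALSE, X, Y)
    region[, band[1]:band[2]] <- TRUE
    region <- region & tissue
    shape <- if (true_label[n] == 1) shape_case else shape_ctrl
    if (!is.null(shape)) {
      lam <- config$focus_density * sum(region)
      nf <- rpois(1, lam)
      if (nf > 0) {
        cells <- which(region)
        pick <- cells[sample.int(length(cells), min(nf, length(cells)))]
        peak <- config$amplitude * baseline
        if (true_label[n] == 0)  # match total mass to the case geometry
          peak <- peak * mass_case / unit_mass(shape_ctrl)
        add <- matrix(0, X, Y)
        for (cell in pick) {
          px <- ((cell - 1) %% X) + 1
          py <- ((cell - 1) %/% X) + 1
          add <- add + .spike(X, Y, px, py, shape, peak)
        }
        vals[, , config$signal_channel] <-
          vals[, , config$signal_channel] + add * tissue
      }
    }
    rasters[[n]] <- sample_raster(vals, sample_id = sprintf("s%02d", n),
                                  channel_names = paste0("ch", seq_len(M)))
    region_masks[[n]] <- region
  }
  # observed labels: re-assign a fraction h at random
  obs <- true_label
  h <- config$label_noise_h
  if (h > 0) {
    flip <- sample.int(ns, round(h * ns))
    obs[flip] <- rbinom(length(flip), 1, 0.5)
  }
  metadata <- sample_metadata(data.frame(
    sample_id = vapply(rasters, `[[`, "", "sample_id"),
    donor_id = sprintf("d%02d", donors),
    phenotype = obs))
  truth <- structure(list(true_label = true_label,
                          region_masks = region_masks,
                          sample_id = metadata$sample_id,
                          signal_type = config$signal_type),
                     class = "sim_truth")
  list(rasters = rasters, metadata = metadata, truth = truth,
       config = config)
}

#' Patch-level truth classes
#'
#' Labels each patch of a patch set as `case_region`, `control_region`
#' or `null`: a patch is a region patch when at least half of its pixels
#' lie inside the sample's signal region, and its class follows the
#' sample's true label.
#'
#' @param patchset a [patch_set()].
#' @param truth a `sim_truth` from [generate_dataset()].
#' @param side_px patch side (default taken from the patch array).
#' @param min_overlap minimum in-region pixel fraction (default 0.5).
#' @return factor of levels `case_region`, `control_region`, `null`.
#' @export
patch_truth <- function(patchset, truth, min_overlap = 0.5) {
  side <- dim(patchset$patches)[2]
  out <- character(length(patchset))
  if (identical(truth$signal_type, "null"))
    return(factor(rep("null", length(patchset)),
                  levels = c("case_region", "control_region", "null")))
  for (i in seq_len(length(patchset))) {
    n <- match(patchset$sample_ids[i], truth$sample_id)
    a <- patchset$anchors[i, ]
    frac <- mean(truth$region_masks[[n]][a[1] + seq_len(side),
                                         a[2] + seq_len(side)])
    out[i] <- if (frac >= min_overlap) {
      if (truth$true_label[n] == 1) "case_region" else "control_region"
    } else "null"
  }
  factor(out, levels = c("case_region", "control_region", "null"))
}

#' Type-I error experiment
#'
#' Draws random binary donor-level labels for an (unmodified) dataset
#' whose fingerprints and MAT were computed once, runs the global
#' permutation test for each simulate, and reports the rejection
#' fraction at level `alpha`.  Label draws are a fair coin per donor,
#' redrawn if all samples land in one class.
#'
#' @param mat a standardized `vima_mat`.
#' @param metadata a [sample_metadata()] (only `donor_id` is used).
#' @param n_simulates number of null label draws (default 100).
#' @param n_perm permutations per global test (default 200).
#' @param alpha rejection level (default 0.05).
#' @return list with `rejection_fraction`, `ci95` (binomial), `p_values`.
#' @export
type1_experiment <- function(mat, metadata, n_simulates = 100, n_perm = 200,
                             alpha = 0.05) {
  if (n_simulates <= 0) stop("n_simulates must be positive")
  ord <- match(mat$samples, metadata$sample_id)
  don <- metadata$donor_id[ord]
  lev <- unique(don)
  pv <- vapply(seq_len(n_simulates), function(i) {
    repeat {
      dl <- rbinom(length(lev), 1, 0.5)
      y <- dl[match(don, lev)]
      if (sd(y) > 0) break
    }
    md <- list(sample_id = mat$samples, donor_id = don, phenotype = y)
    global_test(mat, md, n_perm = n_perm)$p_value
  }, 0)
  rej <- mean(pv <= alpha)
  se <- sqrt(rej * (1 - rej) / n_simulates)
  list(rejection_fraction = rej, ci95 = rej + c(-1.96, 1.96) * se,
       p_values = pv, alpha = alpha)
}

#' Spatial-accuracy figure of merit
#'
#' The average of two AUROCs (mid-rank tie handling): distinguishing
#' truly case-associated patches from the rest using the score, and
#' truly control-associated patches from the rest using the negated
#' score.  Perfectly signed scores give 1; uninformative (constant)
#' scores give 0.5.  If one truth class is empty, the other AUROC is
#' returned with a warning.
#'
#' @param scores per-patch scores (e.g. microniche coefficients).
#' @param truth factor from [patch_truth()] (levels `case_region`,
#'   `control_region`, `null`).
#' @return scalar in `[0, 1]`.
#' @export
spatial_accuracy <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  a_case <- .auroc(scores, truth == "case_region")
  a_ctrl <- .auroc(-scores, truth == "control_region")
  if (is.na(a_case) && is.na(a_ctrl))
    stop("both truth classes are empty")
  if (is.na(a_case) || is.na(a_ctrl)) {
    warning("one truth class is empty; returning the single AUROC")
    return(if (is.na(a_case)) a_ctrl else a_case)
  }
  (a_case + a_ctrl) / 2
}

#' Relative perplexity across samples
#'
#' For each patch, the exponential of the Shannon entropy of the sample
#' composition of its k nearest neighbours, divided by the exponential
#' entropy of the global sample composition.  Values near 1 indicate the
#' patch's neighbourhood mixes samples as well as the dataset overall.
#'
#' @param embedding P x C matrix.
#' @param sample_ids per-patch sample labels.
#' @param k neighbours (default 15).
#' @return length-P vector of relative perplexities.
#' @export
relative_perplexity <- function(embedding, sample_ids, k = 15) {
  stopifnot(length(unique(sample_ids)) >= 2)
  nn <- .knn(as.matrix(embedding), k)
  lev <- sort(unique(sample_ids))
  sidx <- match(sample_ids, lev)
  perp <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    exp(-sum(p * log(p)))
  }
  global <- perp(tabulate(sidx, nbins = length(lev)))
  vapply(seq_len(nrow(nn$idx)), function(i)
    perp(tabulate(sidx[nn$idx[i, ]], nbins = length(lev))) / global, 0)
}

## embed analysis patches by one of the ablation representations
.embed_patches <- function(patchset, method, cvae, metadata, seed,
                           alpha = 0.5, n_pcs = 20, E = 1) {
  keep <- which(patchset$tissue_fraction > alpha)
  sub <- patchset$patches[keep, , , , drop = FALSE]
  emb <- switch(method,
    patch_mean = apply(sub, c(1, 4), mean),
    flattened_pca = {
      X <- matrix(sub, dim(sub)[1], prod(dim(sub)[-1]))
      pc <- prcomp(X, center = TRUE, scale. = FALSE,
                   rank. = min(n_pcs, nrow(X) - 1, ncol(X)))
      pc$x
    },
    cvae_single = {
      m <- train_cvae(patchset, cvae, metadata, seed = seed)
      unclass(encode(m, patchset, alpha = alpha))
    },
    convnet2 = {
      cfg <- cvae
      cfg$variant <- "convnet2_ae"
      m <- train_cvae(patchset, cfg, metadata, seed = seed)
      unclass(encode(m, patchset, alpha = alpha))
    },
    vima = {
      ens <- train_ensemble(patchset, cvae, metadata, E = E, seed = seed)
      fp <- fingerprint_matrices(ens, patchset, alpha = alpha)
      fp$fingerprints
    },
    stop("unknown embedding method: ", method))
  if (!is.list(emb)) emb <- list(emb)
  list(fingerprints = emb, keep = keep,
       sample_ids = patchset$sample_ids[keep])
}

#' Power and ablation experiment
#'
#' Runs the spiked-signal power study: for each replicate, generates a
#' synthetic dataset, preprocesses it, embeds the tissue patches with
#' each requested representation, and tests case-control association
#' with the microniche global test and/or the cluster-based comparator,
#' at each label-noise level `h` (labels are re-randomized per `h`
#' without retraining, since training never sees labels).
#'
#' @param signal_types character vector of [sim_config()] signal types.
#' @param h_grid label-noise fractions (default `c(0, 0.2, 0.4)`).
#' @param n_reps replicates per condition (default 10).
#' @param methods embedding variants: subset of `"cvae_single"`,
#'   `"vima"`, `"convnet2"`, `"flattened_pca"`, `"patch_mean"`.
#' @param tests `"microniche"` and/or `"cluster"`.
#' @param cvae a [cvae_config()] used for neural embeddings (simulation
#'   scale defaults: `latent_dim = 20`, `epochs = 10`).
#' @param sim_args list of overrides passed to [sim_config()].
#' @param n_perm permutations per test (default 200).
#' @param alpha rejection level (default 0.05).
#' @param alpha_tissue tissue threshold for the analysis set (default 0.5).
#' @param k graph neighbours (default 15).
#' @param E ensemble size for the `"vima"` method (default 2).
#' @param seed base seed.
#' @return data frame with columns `method`, `test`, `signal`, `h`,
#'   `rep`, `p_value`, `reject`, `n_significant`, `accuracy`.
#' @export
power_experiment <- function(signal_types = "A_focal_vs_none",
                             h_grid = c(0, 0.2, 0.4), n_reps = 10,
                             methods = c("cvae_single", "patch_mean"),
                             tests = c("microniche", "cluster"),
                             cvae = cvae_config(latent_dim = 20,
                                                epochs = 10,
                                                widths = c(8, 16, 32)),
                             sim_args = list(), n_perm = 200, alpha = 0.05,
                             alpha_tissue = 0.5, k = 15, E = 2, seed = 1) {
  rows <- list()
  for (sig in signal_types) {
    for (r in seq_len(n_reps)) {
      cfg <- do.call(sim_config, c(list(signal_type = sig,
                                        seed = seed * 10000 + r),
                                   sim_args))
      ds <- generate_dataset(cfg)
      pre <- vima_preprocess(ds$rasters, "intensity")
      truth_patch <- patch_truth(pre$patches, ds$truth)
      don <- ds$metadata$donor_id
      embeds <- lapply(methods, function(m)
        .embed_patches(pre$patches, m, cvae, ds$metadata,
                       seed = seed * 10000 + r, alpha = alpha_tissue,
                       E = E))
      names(embeds) <- methods
      for (m in methods) {
        fp <- embeds[[m]]
        mats <- NULL
        if ("microniche" %in% tests) {
          graphs <- lapply(fp$fingerprints, build_graph, k = k)
          s <- vapply(graphs, choose_steps, 0, sample_ids = fp$sample_ids)
          mats <- standardize_mat(compute_mat(graphs, s, fp$sample_ids))
        }
        for (h in h_grid) {
          set.seed(seed * 100000 + r * 100 + round(100 * h))
          y <- ds$truth$true_label
          if (h > 0) {
            flip <- sample.int(length(y), round(h * length(y)))
            y[flip] <- rbinom(length(flip), 1, 0.5)
            if (sd(y) == 0) y[sample.int(length(y), 1)] <- 1 - y[1]
          }
          md <- list(sample_id = ds$metadata$sample_id, donor_id = don,
                     phenotype = y)
          for (tst in tests) {
            if (tst == "microniche") {
              res <- vima_association(mats, md, n_perm = n_perm,
                                      fdr_level = 0.10)
              acc <- spatial_accuracy(res$local$rho,
                                      truth_patch[fp$keep])
              rows[[length(rows) + 1]] <- data.frame(
                method = m, test = tst, signal = sig, h = h, rep = r,
                p_value = res$global$p_value,
                reject = res$global$p_value <= alpha,
                n_significant = length(res$local$significant_pos) +
                  length(res$local$significant_neg),
                accuracy = acc)
            } else {
              cb <- cluster_baseline_test(fp$fingerprints[[1]],
                                          fp$sample_ids, md,
                                          n_perm = n_perm, k = k)
              rows[[length(rows) + 1]] <- data.frame(
                method = m, test = tst, signal = sig, h = h, rep = r,
                p_value = cb$global_bonferroni_p,
                reject = cb$global_bonferroni_p <= alpha,
                n_significant = length(cb$fdr_calls),
                accuracy = spatial_accuracy(cb$patch_score,
                                            truth_patch[fp$keep]))
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
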