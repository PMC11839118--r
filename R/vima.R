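#' Joint local and global association tests sharing permutations
#'
#' Runs the donor-preserving permutation loop once and derives both the
#' local (per-microniche, empirical FDR) and global (aggregate R) tests
#' from the same null draws.
#'
#' @param mat a standardized `vima_mat`.
#' @param metadata a [sample_metadata()] (or list with `sample_id`,
#'   `donor_id`, `phenotype`).
#' @param n_perm number of permutations (default 1000).
#' @param fdr_level FDR level for significant sets (default 0.10).
#' @return list with `local` (a `local_result`) and `global` (a
#'   `global_result`).
#' @export
vima_association <- function(mat, metadata, n_perm = 1000,
                             fdr_level = 0.10) {
  if (is.null(mat$standardized)) mat <- standardize_mat(mat)
  ord <- match(mat$samples, metadata$sample_id)
  y <- metadata$phenotype[ord]
  meta_ord <- list(sample_id = mat$samples,
                   donor_id = metadata$donor_id[ord], phenotype = y)
  P <- dim(mat$Q)[2]
  null_rho <- matrix(0, P, n_perm)
  null_R <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Cb <- correlate(mat, permute_phenotype(meta_ord))
    null_rho[, b] <- meta_local(Cb)
    null_R[b] <- global_stat(Cb)
  }
  loc <- local_test(mat, meta_ord, fdr_level = fdr_level,
                    null_rho = null_rho)
  C <- correlate(mat, y)
  R <- global_stat(C)
  glob <- structure(list(R = R,
                         p_value = (1 + sum(null_R >= R)) / (1 + n_perm),
                         n_permutations = n_perm, null_R = null_R),
                    class = "global_result")
  list(local = loc, global = glob, C = C)
}

#' Fit a microniche case-control analysis
#'
#' The main entry point: starting from preprocessed tissue patches and
#' sample metadata, trains the autoencoder ensemble, builds per-encoder
#' fingerprint graphs, runs the adaptive random walk to form the
#' microniche abundance tensor, and performs the calibrated global and
#' local association tests.
#'
#' @param patches a [patch_set()] (see [vima_preprocess()]).
#' @param metadata a [sample_metadata()].
#' @param E ensemble size (default 10).
#' @param config a [cvae_config()].
#' @param alpha tissue-density threshold for the analysis set
#'   (default 0.5).
#' @param k graph neighbours (default 15).
#' @param n_perm permutations for the tests (default 1000).
#' @param fdr_level FDR level (default 0.10).
#' @param covariates optional character vector of covariate names to
#'   project out of the MAT (and condition the autoencoders on).
#' @param seed RNG seed governing training, graph walks and permutations.
#' @return an object of class `vima` with components `ensemble`,
#'   `fingerprints`, `graphs`, `steps`, `mat`, `local`, `global`,
#'   `keep`, `patches`, `metadata`, `call`.
#' @export
vima <- function(patches, metadata, E = 10, config = cvae_config(),
                 alpha = 0.5, k = 15, n_perm = 1000, fdr_level = 0.10,
                 covariates = NULL, seed = config$seed) {
  stopifnot(inherits(patches, "patch_set"),
            inherits(metadata, "sample_metadata"))
  missing_meta <- setdiff(unique(patches$sample_ids), metadata$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  ensemble <- train_ensemble(patches, config, metadata, E = E, seed = seed)
  fp <- fingerprint_matrices(ensemble, patches, alpha = alpha)
  set.seed(seed + 1L)
  graphs <- lapply(fp$fingerprints, build_graph, k = k)
  steps <- vapply(graphs, choose_steps, 0, sample_ids = fp$sample_ids)
  mat <- compute_mat(graphs, steps, fp$sample_ids)
  if (!is.null(covariates)) {
    cv <- metadata$covariates[match(mat$samples, metadata$sample_id),
                              covariates, drop = FALSE]
    mat <- project_covariates(mat, cv)
  }
  mat <- standardize_mat(mat)
  assoc <- vima_association(mat, metadata, n_perm = n_perm,
                            fdr_level = fdr_level)
  structure(list(ensemble = ensemble, fingerprints = fp$fingerprints,
                 graphs = graphs, steps = steps, mat = mat,
                 local = assoc$local, global = assoc$global, C = assoc$C,
                 keep = fp$keep, sample_ids = fp$sample_ids,
                 patches = patches, metadata = metadata,
                 fdr_level = fdr_level, seed = seed,
                 call = match.call()),
            class = "vima")
}

#' @export
print.vima <- function(x, ...) {
  cat("Microniche case-control analysis\n")
  cat(sprintf("  %d analysis patches (of %d), %d samples, %d encoders\n",
              length(x$keep), length(x$patches),
              length(unique(x$sample_ids)), length(x$fingerprints)))
  cat(sprintf("  global R = %.4g, P = %.3g (%d permutations)\n",
              x$global$R, x$global$p_value, x$global$n_permutations))
  cat(sprintf("  %d positively / %d negatively associated patches at FDR %.0f%%\n",
              length(x$local$significant_pos),
              length(x$local$significant_neg), 100 * x$fdr_level))
  invisible(x)
}

#' @export
summary.vima <- function(object, ...) {
  res <- list(
    n_patches = length(object$patches),
    n_analysis = length(object$keep),
    n_samples = length(unique(object$sample_ids)),
    E = length(object$fingerprints),
    steps = object$steps,
    R = object$global$R,
    p_value = object$global$p_value,
    n_perm = object$global$n_permutations,
    fdr_level = object$fdr_level,
    n_sig_pos = length(object$local$significant_pos),
    n_sig_neg = length(object$local$significant_neg),
    rho_summary = summary(object$local$rho))
  class(res) <- "summary.vima"
  res
}

#' @export
print.summary.vima <- function(x, ...) {
  cat("Microniche case-control analysis\n")
  cat(sprintf("  patches: %d total, %d in analysis set; samples: %d\n",
              x$n_patches, x$n_analysis, x$n_samples))
  cat(sprintf("  encoders: %d; random-walk steps: %s\n", x$E,
              paste(x$steps, collapse = ", ")))
  cat(sprintf("  global statistic R = %.4g, P = %.3g (%d permutations)\n",
              x$R, x$p_value, x$n_perm))
  cat(sprintf("  significant at FDR %.0f%%: %d positive, %d negative\n",
              100 * x$fdr_level, x$n_sig_pos, x$n_sig_neg))
  cat("  microniche coefficients:\n")
  print(x$rho_summary)
  invisible(x)
}

#' Microniche coefficients of a fitted analysis
#' @param object a `vima` fit.
#' @param ... unused.
#' @return named vector of per-patch meta-analyzed correlations.
#' @export
coef.vima <- function(object, ...) {
  setNames(object$local$rho, object$keep)
}

#' Plot a fitted microniche analysis
#'
#' Lays out the consensus nearest-neighbour graph with a force-directed
#' layout and colors patches by their microniche coefficient.
#'
#' @param x a `vima` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vima <- function(x, ...) {
  cons <- build_consensus_graph(x$graphs)
  ig <- igraph::graph_from_adjacency_matrix(cons$A, mode = "undirected",
                                            weighted = TRUE)
  xy <- igraph::layout_with_fr(ig)
  rho <- x$local$rho
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  col <- pal[1 + round(50 * (1 + rho / max(abs(rho), 1e-12)))]
  graphics::plot(xy, col = col, pch = 16, cex = 0.6, xlab = "", ylab = "",
                 axes = FALSE, main = "consensus patch graph", ...)
  invisible(x)
}

#' Patch-level results table
#'
#' @param x a `vima` fit.
#' @return data frame with sample id, anchor coordinates, microniche
#'   coefficient, tail, and significance call at the fitted FDR level.
#' @export
patch_results <- function(x) {
  stopifnot(inherits(x, "vima"))
  keep <- x$keep
  tail <- ifelse(x$local$rho > 0, "positive",
                 ifelse(x$local$rho < 0, "negative", "zero"))
  sig <- logical(length(keep))
  sig[x$local$significant_pos] <- TRUE
  sig[x$local$significant_neg] <- TRUE
  data.frame(patch = keep,
             sample_id = x$sample_ids,
             anchor_x = x$patches$anchors[keep, 1],
             anchor_y = x$patches$anchors[keep, 2],
             rho = x$local$rho, tail = tail, significant = sig)
}
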