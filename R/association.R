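#' Standardize the MAT along microniches
#'
#' Each (patch, encoder) column is standardized across samples to mean 0
#' and unit variance (population convention).  Columns with zero variance
#' are flagged and excluded from testing.
#'
#' @param mat a `vima_mat` (see [compute_mat()]).
#' @return a `vima_mat` with standardized `Q` and a logical `testable`
#'   P x E matrix marking non-degenerate columns.
#' @export
standardize_mat <- function(mat) {
  d <- dim(mat$Q)
  if (d[1] < 3) stop("need at least 3 samples to standardize and test")
  testable <- matrix(TRUE, d[2], d[3])
  for (e in seq_len(d[3])) {
    M <- mat$Q[, , e]
    mu <- colMeans(M)
    s <- sqrt(colMeans(M^2) - mu^2)
    zero <- s <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
    s[zero] <- 1
    mat$Q[, , e] <- sweep(sweep(M, 2, mu), 2, s, "/")
    mat$Q[, zero, e] <- 0
    testable[zero, e] <- FALSE
  }
  if (!any(testable)) stop("all microniche columns have zero variance")
  mat$testable <- testable
  mat$standardized <- TRUE
  mat
}

#' Correlate microniche abundance with a phenotype
#'
#' @param mat a standardized `vima_mat` (see [standardize_mat()]).
#' @param y numeric phenotype, one value per sample (binary encoded 0/1
#'   or continuous); standardized internally.
#' @return E x P matrix of Pearson correlations (class
#'   `correlation_matrix`); untestable columns carry 0.
#' @export
correlate <- function(mat, y) {
  if (is.null(mat$standardized)) mat <- standardize_mat(mat)
  d <- dim(mat$Q)
  stopifnot(length(y) == d[1])
  if (sd(y) == 0) stop("phenotype is constant")
  ys <- .std_pop(y)
  C <- matrix(0, d[3], d[2])
  for (e in seq_len(d[3]))
    C[e, ] <- as.vector(crossprod(ys, mat$Q[, , e])) / d[1]
  C[t(!mat$testable)] <- 0
  structure(C, class = c("correlation_matrix", "matrix", "array"))
}

#' Meta-analyze per-encoder correlations into microniche coefficients
#'
#' For each patch, the coefficient is the ratio of third to second
#' moments of its per-encoder correlations,
#' `rho_p = sum_e C[e,p]^3 / sum_e C[e,p]^2` -- a correlation average
#' weighted by each encoder's squared correlation.  Patches where all
#' correlations are zero get `rho = 0`.
#'
#' @param C an E x P correlation matrix.
#' @return length-P vector of microniche coefficients.
#' @export
meta_local <- function(C) {
  s2 <- colSums(C^2)
  s3 <- colSums(C^3)
  ifelse(s2 > 0, s3 / s2, 0)
}

#' Global association statistic
#'
#' `R = (1/P) * sum_p sum_e C[e,p]^4 / sum_e C[e,p]^2`, the mean over
#' patches of the squared-correlation-weighted average of squared
#' correlations.  Lies in `[0, 1]`; equals 0 iff `C` is identically zero.
#'
#' @param C an E x P correlation matrix.
#' @return scalar `R`.
#' @export
global_stat <- function(C) {
  s2 <- colSums(C^2)
  s4 <- colSums(C^4)
  mean(ifelse(s2 > 0, s4 / s2, 0))
}

#' Donor-preserving phenotype permutation
#'
#' Permutes phenotype values at the donor level: donors swap their
#' values, and all samples of a donor always share that donor's permuted
#' value.  With singleton donors this is an ordinary permutation.
#'
#' @param metadata a [sample_metadata()] (or any list with `donor_id` and
#'   `phenotype` aligned per sample).
#' @return permuted phenotype vector, one value per sample.
#' @export
permute_phenotype <- function(metadata) {
  don <- metadata$donor_id
  lev <- unique(don)
  val <- metadata$phenotype[match(lev, don)]
  perm <- val[sample.int(length(lev))]
  perm[match(don, lev)]
}

## raw empirical-FDR curve for one tail.
## rho_obs: observed coefficients; rho_null: P x n_perm matrix;
## thresholds: increasing candidate values (positive tail on rho, or on
## -rho for the negative tail).
.fdr_curve <- function(stat_obs, stat_null, thresholds) {
  n_obs <- vapply(thresholds, function(t) sum(stat_obs >= t), 0)
  n_null <- vapply(thresholds, function(t) sum(stat_null >= t), 0) /
    ncol(stat_null)
  raw <- ifelse(n_obs > 0, n_null / n_obs, 0)
  # isotonize: FDR non-increasing in the threshold (running min from the top)
  iso <- rev(cummin(rev(raw)))
  data.frame(threshold = thresholds, n_observed = n_obs,
             expected_null = n_null, fdr_raw = raw,
             fdr = pmin(iso, 1))
}

#' Local microniche association test with empirical FDR
#'
#' Computes observed microniche coefficients, recomputes them under
#' donor-preserving phenotype permutations, and estimates, for each
#' candidate threshold, the empirical false discovery rate
#' `FDR(rho*) = E[# null coefficients beyond rho*] / # observed beyond
#' rho*`, separately for the positive and negative tails.  The raw curve
#' is isotonized by a running minimum toward extreme thresholds.
#'
#' @param mat a standardized `vima_mat`.
#' @param metadata a [sample_metadata()] (samples in `mat$samples` order).
#' @param n_perm number of permutations (default 1000).
#' @param fdr_level FDR level for the significant sets (default 0.10).
#' @param null_rho optional precomputed P x n_perm null coefficient
#'   matrix (shared with the global test).
#' @return object of class `local_result`: `rho`, `fdr_pos`, `fdr_neg`
#'   (threshold tables), `significant_pos`, `significant_neg` (patch
#'   indices), `fdr_level`, `n_perm`.
#' @export
local_test <- function(mat, metadata, n_perm = 1000, fdr_level = 0.10,
                       null_rho = NULL) {
  stopifnot(identical(sort(metadata$sample_id), sort(mat$samples)))
  ord <- match(mat$samples, metadata$sample_id)
  y <- metadata$phenotype[ord]
  C <- correlate(mat, y)
  rho <- meta_local(C)
  if (is.null(null_rho)) {
    meta_ord <- list(donor_id = metadata$donor_id[ord], phenotype = y)
    null_rho <- vapply(seq_len(n_perm), function(b)
      meta_local(correlate(mat, permute_phenotype(meta_ord))),
      numeric(length(rho)))
  }
  n_perm <- ncol(null_rho)
  thr_pos <- sort(unique(rho[rho > 0]))
  thr_neg <- sort(unique(-rho[rho < 0]))
  fdr_pos <- if (length(thr_pos))
    .fdr_curve(rho, null_rho, thr_pos) else NULL
  fdr_neg <- if (length(thr_neg))
    .fdr_curve(-rho, -null_rho, thr_neg) else NULL
  sig <- function(curve, stat) {
    if (is.null(curve)) return(integer(0))
    ok <- curve$fdr <= fdr_level & curve$n_observed > 0
    if (!any(ok)) return(integer(0))
    which(stat >= min(curve$threshold[ok]))
  }
  structure(list(rho = rho, fdr_pos = fdr_pos, fdr_neg = fdr_neg,
                 significant_pos = sig(fdr_pos, rho),
                 significant_neg = sig(fdr_neg, -rho),
                 fdr_level = fdr_level, n_perm = n_perm,
                 null_rho = null_rho),
            class = "local_result")
}

#' @export
print.local_result <- function(x, ...) {
  cat(sprintf(
    "local microniche test: %d patches; %d positive / %d negative at FDR %.0f%% (%d permutations)\n",
    length(x$rho), length(x$significant_pos), length(x$significant_neg),
    100 * x$fdr_level, x$n_perm))
  invisible(x)
}

#' Global association test
#'
#' Compares the observed global statistic `R` (see [global_stat()]) to
#' its donor-preserving permutation null; the P-value uses the add-one
#' estimator `(1 + #null >= R) / (1 + n_perm)`.
#'
#' @param mat a standardized `vima_mat`.
#' @param metadata a [sample_metadata()].
#' @param n_perm number of permutations (default 1000).
#' @param null_C optional list of null correlation matrices to reuse.
#' @return object of class `global_result`: `R`, `p_value`, `null_R`,
#'   `n_permutations`.
#' @export
global_test <- function(mat, metadata, n_perm = 1000, null_C = NULL) {
  stopifnot(identical(sort(metadata$sample_id), sort(mat$samples)))
  ord <- match(mat$samples, metadata$sample_id)
  y <- metadata$phenotype[ord]
  R <- global_stat(correlate(mat, y))
  meta_ord <- list(donor_id = metadata$donor_id[ord], phenotype = y)
  null_R <- if (is.null(null_C)) {
    vapply(seq_len(n_perm), function(b)
      global_stat(correlate(mat, permute_phenotype(meta_ord))), 0)
  } else {
    vapply(null_C, global_stat, 0)
  }
  p <- (1 + sum(null_R >= R)) / (1 + length(null_R))
  structure(list(R = R, p_value = p, n_permutations = length(null_R),
                 null_R = null_R),
            class = "global_result")
}

#' @export
print.global_result <- function(x, ...) {
  cat(sprintf("global test: R = %.4g, P = %.3g (%d permutations)\n", x$R,
              x$p_value, x$n_permutations))
  invisible(x)
}

#' PCA of the flattened MAT
#'
#' Flattens the N x P x E tensor into an N x (P*E) matrix and applies
#' standard PCA, returning per-sample scores.
#'
#' @param mat a `vima_mat`.
#' @param n_pcs number of components to keep (default 10).
#' @return list with `scores` (N x n_pcs), `explained_variance`.
#' @export
mat_pca <- function(mat, n_pcs = 10) {
  d <- dim(mat$Q)
  if (d[1] < 3) stop("need at least 3 samples")
  X <- matrix(mat$Q, d[1], d[2] * d[3])
  n_pcs <- min(n_pcs, d[1] - 1, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       explained_variance = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2))
}

#' Cluster-based comparator association test
#'
#' The standard discrete alternative to microniches: cluster the patch
#' embedding (Leiden, resolution 1), form the per-sample cluster
#' abundance matrix, correlate each cluster's abundance with the
#' phenotype, compute a donor-preserving permutation P-value per cluster,
#' and Bonferroni-correct the minimum across clusters.  A sum-of-squares
#' global variant and per-cluster empirical FDR calls are also returned.
#'
#' @param embedding P x C patch embedding.
#' @param sample_ids per-patch sample labels.
#' @param metadata a [sample_metadata()].
#' @param n_perm permutations (default 1000).
#' @param k neighbours for the clustering graph (default 15).
#' @param resolution Leiden resolution (default 1).
#' @param fdr_level level for per-cluster FDR calls (default 0.10).
#' @return list with `clusters`, `per_cluster_p`, `global_bonferroni_p`,
#'   `global_sumsq_p`, `cluster_cor`, `fdr_calls`, `patch_score`
#'   (each patch's cluster correlation, a cluster-level patch score).
#' @export
cluster_baseline_test <- function(embedding, sample_ids, metadata,
                                  n_perm = 1000, k = 15, resolution = 1,
                                  fdr_level = 0.10) {
  g <- build_graph(embedding, k = k)
  ig <- igraph::graph_from_adjacency_matrix(g$A, mode = "undirected",
                                            weighted = TRUE)
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               resolution = resolution)
  clusters <- igraph::membership(cl)
  lev <- sort(unique(clusters))
  samples <- sort(unique(sample_ids))
  ab <- t(vapply(samples, function(s) {
    tab <- tabulate(factor(clusters[sample_ids == s], levels = lev),
                    nbins = length(lev))
    tab / sum(tab)
  }, numeric(length(lev))))
  ord <- match(samples, metadata$sample_id)
  y <- metadata$phenotype[ord]
  meta_ord <- list(donor_id = metadata$donor_id[ord], phenotype = y)
  corr_of <- function(yy) {
    ys <- .std_pop(yy)
    apply(ab, 2, function(a) {
      s <- sd(a)
      if (s == 0) 0 else mean(ys * .std_pop(a))
    })
  }
  obs <- corr_of(y)
  null_cor <- vapply(seq_len(n_perm), function(b)
    corr_of(permute_phenotype(meta_ord)), numeric(length(lev)))
  per_p <- vapply(seq_along(lev), function(j)
    (1 + sum(abs(null_cor[j, ]) >= abs(obs[j]))) / (1 + n_perm), 0)
  kc <- length(lev)
  global_bonf <- min(1, kc * min(per_p))
  ss_obs <- sum(obs^2)
  ss_null <- colSums(null_cor^2)
  global_ss <- (1 + sum(ss_null >= ss_obs)) / (1 + n_perm)
  fdr_calls <- which(p.adjust(per_p, "BH") <= fdr_level)
  list(clusters = as.integer(clusters), per_cluster_p = per_p,
       global_bonferroni_p = global_bonf, global_sumsq_p = global_ss,
       cluster_cor = obs, fdr_calls = fdr_calls,
       patch_score = obs[match(clusters, lev)])
}

#' Log-odds ratio of a 2x2 contingency table
#'
#' @param a,b,c,d the four positive cell counts (`log OR = log(ad/bc)`);
#'   the standard error uses the asymptotic variance
#'   `1/a + 1/b + 1/c + 1/d`.
#' @return list with `log_or`, `se`, `ci95` (Wald 95% interval).
#' @export
contingency_log_odds <- function(a, b, c, d) {
  if (min(a, b, c, d) <= 0)
    stop("all four cells must be positive; add an explicit continuity ",
         "correction for zero cells")
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(log_or = log_or, se = se, ci95 = log_or + c(-1.96, 1.96) * se)
}
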