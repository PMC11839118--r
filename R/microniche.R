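#' Build a k-nearest-neighbour patch graph
#'
#' Computes exact Euclidean k-NN on the fingerprint matrix and converts
#' the directed neighbour sets into symmetric fuzzy connectivities in the
#' style standard in single-cell neighbour graphs: per-point kernels
#' `exp(-(d - rho_i)/sigma_i)` with `rho_i` the distance to the nearest
#' neighbour and `sigma_i` calibrated so each point's memberships sum to
#' `log2(k)`, combined by the fuzzy union `w + w' - w w'`.
#'
#' @param fingerprints P x C numeric matrix.
#' @param k number of neighbours (default 15).
#' @return object of class `patch_graph` with a sparse symmetric
#'   adjacency `A` (zero diagonal) and `k`.
#' @export
build_graph <- function(fingerprints, k = 15) {
  P <- nrow(fingerprints)
  if (P <= k) stop("need more than k = ", k, " patches, got ", P)
  nn <- .knn(fingerprints, k)
  # per-point kernel calibration (binary search on sigma)
  target <- log2(k)
  rho <- nn$dist[, 1]
  W <- matrix(0, P, k)
  for (i in seq_len(P)) {
    d <- pmax(nn$dist[i, ] - rho[i], 0)
    if (all(d == 0)) {
      W[i, ] <- 1
      next
    }
    lo <- 1e-6 * max(d); hi <- max(d) * 10
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    W[i, ] <- exp(-d / mid)
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(P), each = k),
                            j = as.vector(t(nn$idx)),
                            x = as.vector(t(W)), dims = c(P, P))
  At <- Matrix::t(A)
  A <- A + At - A * At  # fuzzy union
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  structure(list(A = A, k = k), class = "patch_graph")
}

## exact kNN by chunked distance computation; returns idx, dist (P x k),
## neighbours sorted by increasing distance, self excluded
.knn <- function(x, k, chunk = 2048L) {
  P <- nrow(x)
  xs <- rowSums(x^2)
  idx <- matrix(0L, P, k)
  dst <- matrix(0, P, k)
  for (from in seq(1L, P, by = chunk)) {
    rows <- from:min(from + chunk - 1L, P)
    d2 <- outer(xs[rows], xs, `+`) - 2 * x[rows, , drop = FALSE] %*% t(x)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (r in seq_along(rows)) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[rows[r], ] <- o
      dst[rows[r], ] <- sqrt(pmax(d2[r, o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("patch_graph: %d patches, k = %d, %d edges\n", nrow(x$A),
              x$k, length(x$A@x) / 2))
  invisible(x)
}

#' Consensus graph across an ensemble
#'
#' Edge weights are the mean of the per-encoder connectivities; used for
#' visualization layouts.
#'
#' @param graphs list of `patch_graph` objects on the same patches.
#' @return a `patch_graph`.
#' @export
build_consensus_graph <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  A <- Reduce(`+`, lapply(graphs, `[[`, "A")) / length(graphs)
  structure(list(A = A, k = graphs[[1]]$k), class = "patch_graph")
}

## row-stochastic transition operator of the walk on A + I
.transition <- function(graph) {
  A <- graph$A + Matrix::Diagonal(nrow(graph$A))
  rs <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / rs) %*% A
}

## sample indicator matrix, rows normalized to 1/|S_n|
.sample_indicator <- function(sample_ids) {
  lev <- sort(unique(sample_ids))
  j <- match(sample_ids, lev)
  B <- Matrix::sparseMatrix(i = j, j = seq_along(sample_ids), x = 1,
                            dims = c(length(lev), length(sample_ids)))
  sz <- Matrix::rowSums(B)
  list(B = Matrix::Diagonal(x = 1 / sz) %*% B, samples = lev, sizes = sz)
}

#' Choose the number of random-walk steps
#'
#' Walks forward one step at a time and tracks, across microniches, the
#' median Fisher (excess) kurtosis of each microniche's across-sample
#' abundance distribution.  Stops at the first step where the relative
#' decrease of this median falls below `kurtosis_drop_tol`; microniches
#' with zero variance across samples are skipped.
#'
#' @param graph a `patch_graph`.
#' @param sample_ids per-patch sample labels (at least 2 samples).
#' @param kurtosis_drop_tol relative decrease threshold (default 0.03).
#' @param s_max maximum steps (default 10); reached without convergence
#'   issues a warning.
#' @return the chosen number of steps `s`.
#' @export
choose_steps <- function(graph, sample_ids, kurtosis_drop_tol = 0.03,
                         s_max = 10) {
  si <- .sample_indicator(sample_ids)
  if (length(si$samples) < 2) stop("need at least 2 samples")
  Tr <- .transition(graph)
  M <- si$B
  med_prev <- NULL
  for (s in seq_len(s_max)) {
    M <- M %*% Tr
    Md <- as.matrix(M)
    ku <- apply(Md, 2, .kurtosis)
    med <- median(ku, na.rm = TRUE)
    if (is.na(med)) {  # every column has zero across-sample variance
      if (median(colSums(Md > 1e-12)) > 1) return(s)  # fully mixed
      med <- Inf
    }
    # microniches must actually draw mass from several samples before a
    # kurtosis plateau counts as convergence (a frozen, single-sample
    # distribution also has constant kurtosis but has not mixed at all)
    mixed <- median(colSums(Md > 1e-12)) > 1
    if (!is.null(med_prev) && mixed) {
      drop_rel <- (med_prev - med) / max(abs(med_prev), .Machine$double.eps)
      if (!is.nan(drop_rel) && drop_rel < kurtosis_drop_tol) return(s)
    }
    med_prev <- med
  }
  warning("random walk did not converge by s_max = ", s_max)
  s_max
}

#' Compute the microniche abundance tensor (MAT)
#'
#' `Q[n, p, e]` is the expected fraction of patches from sample `n`
#' arriving at patch `p` after `s` steps of the random walk on graph `e`
#' (transition operator: row-normalized `A_e + I`), computed by `s`
#' sparse products with the sample indicator matrix.  Entries below
#' `truncate` are zeroed and rows renormalized to keep the tensor sparse
#' in spirit.
#'
#' @param graphs list of `patch_graph` objects sharing patch order.
#' @param s steps; a scalar or one value per graph.
#' @param sample_ids per-patch sample labels.
#' @param truncate mass truncation threshold (default `1e-6`).
#' @return object of class `vima_mat`: list with `Q` (N x P x E array),
#'   `samples`, `s`, `projected = FALSE`.
#' @export
compute_mat <- function(graphs, s, sample_ids, truncate = 1e-6) {
  E <- length(graphs)
  s <- rep(s, length.out = E)
  si <- .sample_indicator(sample_ids)
  N <- length(si$samples)
  P <- length(sample_ids)
  Q <- array(0, c(N, P, E),
             dimnames = list(si$samples, NULL, NULL))
  for (e in seq_len(E)) {
    Tr <- .transition(graphs[[e]])
    M <- si$B
    for (step in seq_len(s[e])) M <- M %*% Tr
    M <- as.matrix(M)
    M[M < truncate] <- 0
    M <- M / rowSums(M)
    Q[, , e] <- M
  }
  structure(list(Q = Q, samples = si$samples, s = s, projected = FALSE),
            class = "vima_mat")
}

#' @export
print.vima_mat <- function(x, ...) {
  d <- dim(x$Q)
  cat(sprintf("vima_mat: %d samples x %d microniches x %d encoders (s = %s%s)\n",
              d[1], d[2], d[3], paste(x$s, collapse = ","),
              if (x$projected) ", covariates projected" else ""))
  invisible(x)
}

#' Project covariates out of the MAT
#'
#' Replaces each microniche column with the residual of a least-squares
#' regression on an intercept plus the covariates, across samples.
#' Collinear covariate columns are dropped with a warning.
#'
#' @param mat a `vima_mat`.
#' @param covariates numeric matrix with one row per sample (row order
#'   matching `mat$samples`).
#' @return the residualized `vima_mat` (`projected = TRUE`).
#' @export
project_covariates <- function(mat, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == dim(mat$Q)[1])
  X <- cbind(1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping collinear covariate column(s): ",
            paste(drop - 1, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  d <- dim(mat$Q)
  for (e in seq_len(d[3]))
    mat$Q[, , e] <- qr.resid(qrX, mat$Q[, , e])
  mat$projected <- TRUE
  mat
}
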