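#' Log-normalize foreground pixels across a dataset
#'
#' Pools all non-empty foreground pixels of a raster list, computes the
#' dataset-wide median total intensity `q`, and normalizes each pixel `p`
#' channel-wise as `log(q * p_m / sum(p))`.  A pixel is "non-empty" when it
#' is foreground and has positive total intensity.  Zero channel entries
#' are stabilized: for intensity data the zero is replaced by `eps` in the
#' numerator (giving `log(q * eps / sum(p))`); for transcript counts a
#' zero maps to `log1p(0) = 0`.
#'
#' @param rasters list of segmented [sample_raster()] objects.
#' @param modality `"transcript"` or `"intensity"`.
#' @param eps pseudocount for zero intensities (default 1).
#' @return list with `pixels` (n x M matrix of normalized values),
#'   `coords` (data frame `sample_id`, `x`, `y`, 1-based pixel indices),
#'   `q`, `dims` (named list of spatial extents) and `foreground` masks.
#' @export
lognormalize_pixels <- function(rasters, modality = c("transcript", "intensity"),
                                eps = 1) {
  modality <- match.arg(modality)
  stopifnot(length(rasters) >= 1)
  per <- lapply(rasters, function(r) {
    d <- dim(r$values)
    fg <- r$foreground %||% matrix(TRUE, d[1], d[2])
    v <- matrix(r$values, d[1] * d[2], d[3])
    tot <- rowSums(v)
    keep <- as.vector(fg) & tot > 0
    list(values = v[keep, , drop = FALSE], tot = tot[keep],
         which = which(keep), dim = d, sample_id = r$sample_id,
         foreground = fg)
  })
  q <- median(unlist(lapply(per, `[[`, "tot")))
  pixels <- do.call(rbind, lapply(per, function(s) {
    ratio <- q * s$values / s$tot  # recycles tot down columns
    if (modality == "intensity") {
      ratio[s$values == 0] <- (q * eps / s$tot)[which(s$values == 0,
                                                      arr.ind = TRUE)[, 1]]
      log(ratio)
    } else {
      out <- log(ratio)
      out[s$values == 0] <- 0
      out
    }
  }))
  coords <- do.call(rbind, lapply(per, function(s) {
    data.frame(sample_id = s$sample_id,
               x = ((s$which - 1) %% s$dim[1]) + 1,
               y = ((s$which - 1) %/% s$dim[1]) + 1)
  }))
  dims <- lapply(per, function(s) s$dim[1:2])
  names(dims) <- vapply(per, `[[`, "", "sample_id")
  fgs <- lapply(per, `[[`, "foreground")
  names(fgs) <- names(dims)
  list(pixels = pixels, coords = coords, q = q, dims = dims,
       foreground = fgs, modality = modality)
}

## 5x5 box average over non-empty pixels of one sample's normalized field.
## field: X*Y x M matrix with NA rows at empty pixels.
.metapixel_field <- function(field, X, Y) {
  M <- ncol(field)
  filled <- !is.na(field[, 1])
  acc <- matrix(0, X * Y, M)
  cnt <- numeric(X * Y)
  f0 <- field
  f0[!filled, ] <- 0
  for (dx in -2:2) {
    xs_src <- max(1, 1 - dx):min(X, X - dx)
    for (dy in -2:2) {
      ys_src <- max(1, 1 - dy):min(Y, Y - dy)
      src <- outer(xs_src, (ys_src - 1) * X, `+`)
      dst <- outer(xs_src + dx, (ys_src + dy - 1) * X, `+`)
      acc[dst, ] <- acc[dst, ] + f0[src, ]
      cnt[dst] <- cnt[dst] + filled[src]
    }
  }
  acc[filled, , drop = FALSE] / pmax(cnt[filled], 1)
}

#' Compute meta-markers by PCA on 5x5 meta-pixels
#'
#' Averages the normalized values of non-empty pixels within the 5x5
#' square centered on each non-empty pixel ("meta-pixels"), fits PCA on
#' the meta-pixels, and projects every original normalized pixel onto the
#' top `K` loadings (centering by the meta-pixel means).
#'
#' @param normalized result of [lognormalize_pixels()].
#' @param K number of meta-markers; default 10, or 5 when the dataset has
#'   fewer than 10 markers.
#' @return list with `scores` (n x K), `loadings` (M x K), `center`,
#'   `sdev`, plus the coords/dims/foreground carried through.
#' @export
compute_metamarkers <- function(normalized, K = NULL) {
  M <- ncol(normalized$pixels)
  K <- K %||% (if (M < 10) 5L else 10L)
  if (K > M) stop("K (", K, ") exceeds number of markers (", M, ")")
  meta <- vector("list", length(normalized$dims))
  for (i in seq_along(normalized$dims)) {
    sid <- names(normalized$dims)[i]
    d <- normalized$dims[[i]]
    rows <- normalized$coords$sample_id == sid
    field <- matrix(NA_real_, d[1] * d[2], M)
    lin <- normalized$coords$x[rows] + (normalized$coords$y[rows] - 1) * d[1]
    field[lin, ] <- normalized$pixels[rows, , drop = FALSE]
    meta[[i]] <- .metapixel_field(field, d[1], d[2])
  }
  meta <- do.call(rbind, meta)
  pc <- prcomp(meta, center = TRUE, scale. = FALSE)
  loadings <- pc$rotation[, seq_len(K), drop = FALSE]
  scores <- sweep(normalized$pixels, 2, pc$center) %*% loadings
  out <- normalized
  out$pixels <- NULL
  out$scores <- scores
  out$loadings <- loadings
  out$center <- pc$center
  out$sdev <- pc$sdev[seq_len(K)]
  out$K <- K
  out
}

#' Batch-correct pixel meta-markers across samples
#'
#' Iterative soft-clustering linear correction: each round softly assigns
#' pixels to clusters (entropic k-means on cosine-normalized corrected
#' values), then recomputes the corrected values from the *original*
#' meta-markers by removing, within each soft cluster, the ridge-shrunk
#' per-batch mean deviation from the cluster centroid.  Deriving the
#' correction from the original values each round (rather than
#' compounding shifts) bounds the total correction by the batch
#' deviations actually present, so per-sample differences in cluster
#' *abundance* -- the signal downstream association testing uses -- are
#' preserved while per-pixel batch offsets are removed.  With a single
#' sample the input passes through unchanged (with a warning).  The
#' output is standardized dataset-wide per channel (population
#' convention: mean 0, variance 1).
#'
#' @param scores n x K matrix of pixel meta-markers.
#' @param sample_ids length-n batch labels.
#' @param n_clusters number of soft clusters (default
#'   `min(50, n / 60)`).
#' @param n_iter clustering/correction rounds (default 20).
#' @param sigma softness of the cluster assignments on the cosine scale
#'   (default 0.4).
#' @param ridge ridge term added to the per-cluster batch weight when
#'   estimating the batch deviation (default 1).
#' @param standardize standardize columns afterwards (default TRUE).
#' @return matrix of corrected (and standardized) meta-markers.
#' @export
correct_batch <- function(scores, sample_ids, n_clusters = NULL,
                          n_iter = 20, sigma = 0.4, ridge = 1,
                          standardize = TRUE) {
  n <- nrow(scores)
  batches <- unique(sample_ids)
  Z0 <- scale(scores)  # original (standardized) values; never overwritten
  Zc <- Z0
  if (length(batches) >= 2) {
    k <- max(2L, min(n_clusters %||% 50, floor(n / 60)))
    unitize <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
    # deterministic init: spread centroids along the first meta-marker
    init <- order(Z0[, 1])[unique(round(seq(1, n, length.out = k)))]
    mu <- unitize(Z0)[init, , drop = FALSE]
    for (it in seq_len(n_iter)) {
      Un <- unitize(Zc)
      mu <- unitize(mu)
      # squared cosine distance 2(1 - cos); softmax with temperature sigma
      d2 <- 2 - 2 * Un %*% t(mu)
      d2 <- d2 - apply(d2, 1, min)
      R <- exp(-d2 / sigma)
      R <- R / rowSums(R)
      size <- colSums(R)
      keep_k <- size > 1e-6
      R <- R[, keep_k, drop = FALSE]
      size <- size[keep_k]
      mu_orig <- crossprod(R, Z0) / size     # cluster centroids of Z0
      shift <- matrix(0, n, ncol(Z0))
      for (b in batches) {
        ib <- sample_ids == b
        Rb <- R[ib, , drop = FALSE]
        sb <- colSums(Rb)
        delta <- (crossprod(Rb, Z0[ib, , drop = FALSE]) -
                    sb * mu_orig) / (sb + ridge)
        shift[ib, ] <- Rb %*% delta
      }
      Zc <- Z0 - shift
      mu <- crossprod(R, Un) / size  # centroids for the next round
    }
  } else {
    warning("single sample: batch correction is a pass-through")
  }
  if (standardize) Zc <- apply(Zc, 2, .std_pop)
  unname(Zc)
}

#' Assemble per-sample meta-marker fields
#'
#' Scatters corrected pixel meta-markers back onto each sample's spatial
#' grid (background and empty pixels carry 0).
#'
#' @param corrected n x K matrix of corrected meta-markers.
#' @param metainfo the list carrying `coords`, `dims`, `foreground`
#'   (as returned by [compute_metamarkers()]).
#' @return named list of `metamarker_field` objects with elements
#'   `values` (X x Y x K), `foreground`, `sample_id`.
#' @export
build_fields <- function(corrected, metainfo) {
  K <- ncol(corrected)
  out <- lapply(names(metainfo$dims), function(sid) {
    d <- metainfo$dims[[sid]]
    rows <- metainfo$coords$sample_id == sid
    arr <- array(0, dim = c(d[1], d[2], K))
    lin <- metainfo$coords$x[rows] + (metainfo$coords$y[rows] - 1) * d[1]
    flat <- matrix(arr, d[1] * d[2], K)
    flat[lin, ] <- corrected[rows, , drop = FALSE]
    arr[] <- flat
    structure(list(sample_id = sid, values = arr,
                   foreground = metainfo$foreground[[sid]],
                   loadings = metainfo$loadings,
                   pixel_median_intensity = metainfo$q),
              class = "metamarker_field")
  })
  names(out) <- names(metainfo$dims)
  out
}

#' One-call preprocessing pipeline
#'
#' Segments tissue, log-normalizes, computes meta-markers, batch-corrects
#' and standardizes, and extracts overlapping square patches.
#'
#' @param rasters list of [sample_raster()] objects (raw; segmentation is
#'   applied here unless a raster already carries a foreground mask).
#' @param modality `"transcript"` or `"intensity"`.
#' @param K number of meta-markers (default: 10, or 5 if fewer than 10
#'   markers).
#' @param side_px,stride_px,min_tissue patch geometry, see
#'   [extract_patches()].
#' @param negative_control negative-control channels for intensity
#'   segmentation.
#' @param ... further arguments to [correct_batch()].
#' @return list with `patches` (a [patch_set()]), `fields`, `q`, `K`,
#'   `loadings`.
#' @export
vima_preprocess <- function(rasters, modality = c("transcript", "intensity"),
                            K = NULL, side_px = 40, stride_px = 10,
                            min_tissue = 0.2, negative_control = NULL, ...) {
  modality <- match.arg(modality)
  rasters <- lapply(rasters, function(r) {
    if (is.null(r$foreground))
      segment_foreground(r, modality, negative_control = negative_control)
    else r
  })
  norm <- lognormalize_pixels(rasters, modality)
  mm <- compute_metamarkers(norm, K = K)
  corrected <- correct_batch(mm$scores, mm$coords$sample_id, ...)
  fields <- build_fields(corrected, mm)
  patches <- do.call(c, lapply(fields, extract_patches, side_px = side_px,
                               stride_px = stride_px,
                               min_tissue = min_tissue))
  list(patches = patches, fields = fields, q = mm$q, K = mm$K,
       loadings = mm$loadings)
}
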