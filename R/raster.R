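#' Construct a sample raster
#'
#' A `sample_raster` holds one sample's pixel grid of raw marker counts or
#' intensities, shaped `X x Y x M` (x runs along the first axis), together
#' with its pixel size and an optional foreground (tissue) mask.
#'
#' @param values numeric array of dimension `X x Y x M`, non-negative.
#' @param sample_id scalar identifier.
#' @param channel_names character vector of length `M`.
#' @param resolution_um pixel side length in micrometers (default 10).
#' @param foreground optional logical `X x Y` mask; if supplied, background
#'   pixels are zeroed across all channels.
#' @return an object of class `sample_raster`.
#' @export
sample_raster <- function(values, sample_id, channel_names = NULL,
                          resolution_um = 10, foreground = NULL) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  if (any(values < 0)) stop("raster values must be non-negative")
  d <- dim(values)
  channel_names <- channel_names %||% paste0("ch", seq_len(d[3]))
  stopifnot(length(channel_names) == d[3])
  if (!is.null(foreground)) {
    stopifnot(identical(dim(foreground), d[1:2]))
    values <- values * as.numeric(rep(foreground, d[3]))
  }
  structure(list(sample_id = sample_id, resolution_um = resolution_um,
                 values = values, foreground = foreground,
                 channel_names = channel_names),
            class = "sample_raster")
}

#' @export
print.sample_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("sample_raster '%s': %d x %d px, %d channels, %g um/px\n",
              x$sample_id, d[1], d[2], d[3], x$resolution_um))
  if (!is.null(x$foreground))
    cat(sprintf("  foreground: %.1f%% of pixels\n", 100 * mean(x$foreground)))
  invisible(x)
}

#' Rasterize a transcript table into a pixel grid
#'
#' Bins detected transcripts into square pixels of side `resolution_um`.
#' Pixel indices are 0-based half-open bins `[i*r, (i+1)*r)`; transcript
#' counts are conserved exactly.
#'
#' @param transcripts data frame with columns `x`, `y` (micrometers) and
#'   `gene`.
#' @param resolution_um pixel size in micrometers.
#' @param gene_order character vector fixing the channel order; every gene
#'   present in `transcripts` must appear here.
#' @param sample_id identifier attached to the result.
#' @param extent_px optional `c(X, Y)` grid size; defaults to the smallest
#'   grid containing all transcripts.
#' @return a [sample_raster()] of counts.
#' @export
rasterize_transcripts <- function(transcripts, resolution_um = 10,
                                  gene_order = NULL, sample_id = "sample",
                                  extent_px = NULL) {
  if (nrow(transcripts) == 0L) stop("transcript table is empty (zero extent)")
  stopifnot(all(is.finite(transcripts$x)), all(is.finite(transcripts$y)),
            resolution_um > 0)
  gene_order <- gene_order %||% sort(unique(as.character(transcripts$gene)))
  g <- match(as.character(transcripts$gene), gene_order)
  if (anyNA(g)) {
    bad <- unique(as.character(transcripts$gene)[is.na(g)])
    stop("unknown gene id(s): ", paste(bad, collapse = ", "))
  }
  ix <- floor(transcripts$x / resolution_um)
  iy <- floor(transcripts$y / resolution_um)
  if (any(ix < 0) || any(iy < 0)) stop("negative pixel coordinates")
  ext <- extent_px %||% c(max(ix) + 1, max(iy) + 1)
  M <- length(gene_order)
  counts <- array(0, dim = c(ext[1], ext[2], M))
  idx <- cbind(ix + 1, iy + 1, g)
  tab <- table(factor(ix + 1 + ext[1] * (iy) + ext[1] * ext[2] * (g - 1),
                      levels = seq_len(ext[1] * ext[2] * M)))
  counts[] <- as.numeric(tab)
  sample_raster(counts, sample_id = sample_id, channel_names = gene_order,
                resolution_um = resolution_um)
}

#' Otsu threshold of a numeric vector
#'
#' Finds the threshold maximizing between-class variance on a fixed-width
#' 256-bin histogram of the input.
#'
#' @param x numeric values (e.g. a per-pixel summary image).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold (a value strictly between the two classes);
#'   foreground is conventionally `x > threshold`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate histogram: summary image is constant")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) 0, 0)
  agg <- rowsum(x, bin)
  sums[as.integer(rownames(agg))] <- agg
  w <- cumsum(counts)
  m <- cumsum(sums)  # exact within-bin sums, not bin-centre approximations
  n <- w[n_bins]
  mT <- m[n_bins]
  # between-class variance for a cut after bin t
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mT * w0[valid] - n * m[-n_bins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  t <- which.max(bcv)
  edges[t + 1]
}

#' Segment tissue foreground
#'
#' Transcript-based modalities use a fixed threshold of 10 transcripts per
#' pixel on the per-pixel total; intensity-based modalities use Otsu
#' thresholding of a per-pixel summary (sum of marker intensities, divided
#' by the summed negative-control intensities when such channels exist).
#' Background pixels are zeroed for all markers.
#'
#' @param raster a [sample_raster()].
#' @param modality `"transcript"` or `"intensity"`.
#' @param min_transcripts foreground cutoff for transcript data (default 10;
#'   pixels with total >= this are tissue).
#' @param negative_control integer or character indices of negative-control
#'   channels (intensity mode denominator); these channels stay in the
#'   raster but a channel subset for analysis can be handled upstream.
#' @return a `sample_raster` with `foreground` set and background zeroed.
#' @export
segment_foreground <- function(raster, modality = c("transcript", "intensity"),
                               min_transcripts = 10, negative_control = NULL) {
  modality <- match.arg(modality)
  v <- raster$values
  if (modality == "transcript") {
    tot <- apply(v, c(1, 2), sum)
    mask <- tot >= min_transcripts
  } else {
    if (is.character(negative_control))
      negative_control <- match(negative_control, raster$channel_names)
    if (length(negative_control)) {
      marker <- setdiff(seq_len(dim(v)[3]), negative_control)
      num <- apply(v[, , marker, drop = FALSE], c(1, 2), sum)
      den <- apply(v[, , negative_control, drop = FALSE], c(1, 2), sum)
      summary_img <- num / pmax(den, .Machine$double.eps)
    } else {
      summary_img <- apply(v, c(1, 2), sum)
    }
    # threshold on the log scale: intensity summaries are heavy-tailed and
    # linear-scale Otsu can split the bright tail instead of tissue/background
    thr <- otsu_threshold(log1p(as.numeric(summary_img)))
    mask <- log1p(summary_img) > thr
  }
  sample_raster(v, sample_id = raster$sample_id,
                channel_names = raster$channel_names,
                resolution_um = raster$resolution_um, foreground = mask)
}
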