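#' Construct a patch set
#'
#' @param patches numeric array `P x side x side x K`.
#' @param sample_ids length-P sample identifiers.
#' @param anchors P x 2 matrix of 0-based (x, y) pixel coordinates of each
#'   patch origin.
#' @param tissue_fraction length-P fractions in `[0, 1]`.
#' @return object of class `patch_set`.
#' @export
patch_set <- function(patches, sample_ids, anchors, tissue_fraction) {
  stopifnot(length(dim(patches)) == 4,
            dim(patches)[1] == length(sample_ids),
            nrow(anchors) == length(sample_ids),
            length(tissue_fraction) == length(sample_ids))
  structure(list(patches = patches, sample_ids = as.character(sample_ids),
                 anchors = anchors, tissue_fraction = tissue_fraction),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("patch_set: %d patches of %d x %d px, %d meta-markers, %d samples\n",
              d[1], d[2], d[3], d[4], length(unique(x$sample_ids))))
  invisible(x)
}

#' @export
length.patch_set <- function(x) dim(x$patches)[1]

#' Combine patch sets
#' @param ... `patch_set` objects sharing side length and channel count.
#' @return a single `patch_set`.
#' @export
c.patch_set <- function(...) {
  sets <- list(...)
  sets <- Filter(function(s) length(s) > 0, sets)
  patch_set(do.call(.abind1, lapply(sets, `[[`, "patches")),
            unlist(lapply(sets, `[[`, "sample_ids")),
            do.call(rbind, lapply(sets, `[[`, "anchors")),
            unlist(lapply(sets, `[[`, "tissue_fraction")))
}

## bind 4-d arrays along the first axis
.abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, dim = c(n, d[2], d[3], d[4]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Extract overlapping square patches from a meta-marker field
#'
#' Patches are placed on a stride grid, fully contained in the raster (no
#' edge padding), and patches with less than `min_tissue` tissue fraction
#' are discarded.
#'
#' @param field a `metamarker_field` (see [build_fields()]).
#' @param side_px patch side in pixels (default 40).
#' @param stride_px stride between patch anchors (default 10).
#' @param min_tissue minimum fraction of tissue pixels (default 0.2).
#' @return a [patch_set()].
#' @export
extract_patches <- function(field, side_px = 40, stride_px = 10,
                            min_tissue = 0.2) {
  d <- dim(field$values)
  if (side_px > d[1] || side_px > d[2])
    stop("patch side exceeds raster extent")
  fg <- field$foreground %||% matrix(TRUE, d[1], d[2])
  ax <- seq(0L, d[1] - side_px, by = stride_px)
  ay <- seq(0L, d[2] - side_px, by = stride_px)
  anchors <- as.matrix(expand.grid(x = ax, y = ay))
  tf <- apply(anchors, 1, function(a)
    mean(fg[a[1] + seq_len(side_px), a[2] + seq_len(side_px)]))
  keep <- tf >= min_tissue
  if (!any(keep))
    stop("no patch passes the minimum tissue fraction in sample ",
         field$sample_id)
  anchors <- anchors[keep, , drop = FALSE]
  tf <- tf[keep]
  P <- nrow(anchors)
  K <- d[3]
  patches <- array(0, dim = c(P, side_px, side_px, K))
  for (i in seq_len(P)) {
    patches[i, , , ] <- field$values[anchors[i, 1] + seq_len(side_px),
                                     anchors[i, 2] + seq_len(side_px), ,
                                     drop = FALSE]
  }
  patch_set(patches, rep(field$sample_id, P), anchors, tf)
}

#' Sample metadata table
#'
#' Validates a sample-level metadata table: every sample appears exactly
#' once, donor ids partition samples, and the phenotype is numeric (binary
#' phenotypes encoded 0/1) or convertible to it.
#'
#' @param data data frame with columns `sample_id`, `donor_id`,
#'   `phenotype` and optional covariate columns.
#' @param covariates character vector naming covariate columns (optional).
#' @return object of class `sample_metadata`: list with `sample_id`,
#'   `donor_id`, `phenotype`, `covariates` (matrix or NULL).
#' @export
sample_metadata <- function(data, covariates = NULL) {
  for (col in c("sample_id", "donor_id", "phenotype"))
    if (!col %in% names(data)) stop("metadata is missing column '", col, "'")
  if (anyDuplicated(data$sample_id))
    stop("duplicate sample_id in metadata")
  ph <- data$phenotype
  if (is.logical(ph)) ph <- as.numeric(ph)
  if (is.factor(ph) || is.character(ph)) {
    lev <- sort(unique(as.character(ph)))
    if (length(lev) != 2)
      stop("non-numeric phenotype must be binary")
    ph <- as.numeric(as.character(ph) == lev[2])
  }
  cov <- NULL
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov))
      stop("metadata is missing covariate column(s): ",
           paste(missing_cov, collapse = ", "))
    cov <- as.matrix(data[covariates])
    storage.mode(cov) <- "double"
  }
  structure(list(sample_id = as.character(data$sample_id),
                 donor_id = as.character(data$donor_id),
                 phenotype = as.numeric(ph), covariates = cov),
            class = "sample_metadata")
}
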