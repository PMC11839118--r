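#' Read a transcript table
#'
#' Accepts CSV, TSV or Parquet with required columns `sample_id`, `x`,
#' `y`, `gene` (coordinates in micrometers).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_transcripts <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
               csv = read.csv(path),
               tsv = , txt = read.csv(path, sep = "\t"),
               parquet = {
                 if (!requireNamespace("arrow", quietly = TRUE))
                   stop("reading parquet requires the 'arrow' package")
                 as.data.frame(arrow::read_parquet(path))
               },
               stop("unsupported transcript format: .", ext))
  for (col in c("sample_id", "x", "y", "gene"))
    if (!col %in% names(df))
      stop("transcript table is missing column '", col, "'")
  df
}

#' Read a multichannel TIFF as a sample raster
#'
#' @param path TIFF path; planes are interpreted as channels.
#' @param channel_names optional channel names (length = number of
#'   planes).
#' @param sample_id identifier; defaults to the file name.
#' @param resolution_um pixel size in micrometers.
#' @return a [sample_raster()].
#' @export
read_intensity_tiff <- function(path, channel_names = NULL,
                                sample_id = NULL, resolution_um = 10) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(img)) img <- list(img)
  M <- length(img)
  vals <- array(0, c(nrow(img[[1]]), ncol(img[[1]]), M))
  for (m in seq_len(M)) vals[, , m] <- img[[m]]
  sample_raster(vals,
                sample_id = sample_id %||%
                  tools::file_path_sans_ext(basename(path)),
                channel_names = channel_names, resolution_um = resolution_um)
}

#' Write a sample raster as a multichannel TIFF
#'
#' @param raster a [sample_raster()].
#' @param path output path.
#' @export
write_intensity_tiff <- function(raster, path) {
  v <- raster$values
  mx <- max(v)
  planes <- lapply(seq_len(dim(v)[3]), function(m) v[, , m] / max(mx, 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a sample metadata CSV
#'
#' @param path CSV with columns `sample_id`, `donor_id`, `phenotype` and
#'   optional covariates.
#' @param covariates covariate column names (optional).
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path, covariates = NULL) {
  sample_metadata(read.csv(path), covariates = covariates)
}

#' Write the JSON report of a fitted analysis
#'
#' @param fit a [vima()] fit.
#' @param path output path.
#' @param config_hash optional configuration hash recorded in the report.
#' @export
write_report <- function(fit, path, config_hash = NULL) {
  rep <- list(global_R = fit$global$R, global_p = fit$global$p_value,
              n_permutations = fit$global$n_permutations,
              n_significant_pos = length(fit$local$significant_pos),
              n_significant_neg = length(fit$local$significant_neg),
              fdr_level = fit$fdr_level, steps = fit$steps,
              seed = fit$seed, config_hash = config_hash)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
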