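#' Write an EpochSet to the on-disk container
#'
#' The container is one little-endian 32-bit-float binary array file
#' (`<prefix>.bin`, trials x channels x samples in column-major order,
#' microvolts) plus a JSON sidecar (`<prefix>.json`) holding the sampling
#' rate, epoch offset, channel names, region map, array dimensions and the
#' per-trial metadata table.
#'
#' @param epochs An [epoch_set()].
#' @param prefix Output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_epochset <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "EpochSet"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 4, endian = "little")
  sidecar <- list(
    fs = epochs$fs,
    t0_offset_ms = epochs$t0_offset_ms,
    dims = dim(epochs$data),
    channel_names = epochs$channel_names,
    region_of = as.list(epochs$montage$region_of),
    trials_meta = epochs$trials_meta
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(prefix)
}

#' Read an EpochSet from the on-disk container
#'
#' @param prefix Path prefix used with [write_epochset()].
#' @return An [epoch_set()]. Sample values are single precision.
#' @export
read_epochset <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  dims <- as.integer(sidecar$dims)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(dims), size = 4,
                  endian = "little")
  meta <- as.data.frame(sidecar$trials_meta, stringsAsFactors = FALSE)
  region_of <- unlist(sidecar$region_of)
  epoch_set(array(vals, dims), fs = sidecar$fs,
            t0_offset_ms = sidecar$t0_offset_ms,
            channel_names = sidecar$channel_names,
            montage = channel_montage(sidecar$channel_names, region_of),
            trials_meta = meta)
}

#' Write a FeatureMatrix as TSV plus JSON sidecar
#'
#' The TSV carries the trial metadata columns followed by one column per
#' feature; the sidecar records the feature space, names and regions.
#'
#' @param fm A `FeatureMatrix`.
#' @param prefix Output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  tab <- cbind(fm$trials_meta, as.data.frame(fm$values))
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(space_tag = fm$space_tag, feature_names = fm$feature_names,
         feature_regions = fm$feature_regions),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a FeatureMatrix written by [write_feature_matrix()]
#'
#' @param prefix Path prefix (without extension).
#' @return A `FeatureMatrix`.
#' @export
read_feature_matrix <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  tab <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- setdiff(names(tab), sidecar$feature_names)
  feature_matrix(as.matrix(tab[, sidecar$feature_names, drop = FALSE]),
                 sidecar$feature_names, sidecar$space_tag,
                 tab[, meta_cols, drop = FALSE], sidecar$feature_regions)
}
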