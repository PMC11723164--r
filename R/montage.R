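#' Scalp region names used throughout the pipeline
#'
#' The six scalp subregions, in the fixed order used for feature naming:
#' prefrontal, frontal, temporal, central, parietal, occipital.
#'
#' @return Character vector of length 6.
#' @export
scalp_regions <- function() {
  c("prefrontal", "frontal", "temporal", "central", "parietal", "occipital")
}

# Short region prefixes used in feature names (Pre_beta_3 etc.)
region_abbrev <- c(
  prefrontal = "Pre", frontal = "F", temporal = "T",
  central = "C", parietal = "Par", occipital = "O"
)

#' Construct a channel montage
#'
#' A montage is the channel label list plus the channel-to-region map that
#' drives the spatial averaging step of the feature reduction.
#'
#' @param channel_names Character vector of channel labels.
#' @param region_of Named character vector mapping every channel label to one
#'   of the six regions in [scalp_regions()].
#' @return A `ChannelMontage` object.
#' @export
channel_montage <- function(channel_names, region_of) {
  stopifnot(is.character(channel_names), length(channel_names) > 0)
  if (!all(channel_names %in% names(region_of))) {
    missing <- setdiff(channel_names, names(region_of))
    stop("channels without a region: ", paste(missing, collapse = ", "))
  }
  region_of <- region_of[channel_names]
  bad <- setdiff(unique(region_of), scalp_regions())
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  if (!all(scalp_regions() %in% region_of)) {
    stop("all six scalp regions must be non-empty")
  }
  structure(
    list(channel_names = channel_names, region_of = region_of),
    class = "ChannelMontage"
  )
}

#' @export
print.ChannelMontage <- function(x, ...) {
  cat("ChannelMontage:", length(x$channel_names), "channels\n")
  print(table(factor(x$region_of, levels = scalp_regions())))
  invisible(x)
}

# Canonical 60-channel 10-10 layout partitioned into six regions.
montage_60 <- list(
  prefrontal = c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8"),
  frontal    = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
                 "FC3", "FCz", "FC4"),
  temporal   = c("FT9", "FT7", "T7", "TP7", "TP9",
                 "FT10", "FT8", "T8", "TP8", "TP10"),
  central    = c("FC5", "FC1", "FC2", "FC6", "C3", "C1", "Cz", "C2", "C4",
                 "CP1", "CP2"),
  parietal   = c("CP5", "CP3", "CPz", "CP4", "CP6", "P7", "P3", "Pz", "P4",
                 "P8", "POz"),
  occipital  = c("PO7", "PO3", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
)

#' Default six-region montage
#'
#' For `n_channels = 60` returns the canonical 10-10-style layout used by the
#' analysis (e.g. `Fp1` is prefrontal, `O1` occipital), with the mastoid-
#' adjacent channels `TP9`/`TP10` in the temporal region. For other counts
#' (test fixtures) channels are split as evenly as possible across the six
#' regions with generic labels such as `Pre1`, `F1`, `T1`.
#'
#' @param n_channels Number of channels (at least 6).
#' @return A `ChannelMontage`.
#' @export
default_montage <- function(n_channels = 60) {
  stopifnot(length(n_channels) == 1, n_channels >= 6)
  if (n_channels == 60) {
    region_of <- unlist(lapply(names(montage_60), function(r) {
      stats::setNames(rep(r, length(montage_60[[r]])), montage_60[[r]])
    }))
    return(channel_montage(unlist(montage_60, use.names = FALSE), region_of))
  }
  sizes <- rep(n_channels %/% 6, 6)
  extra <- n_channels %% 6
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  regions <- scalp_regions()
  labels <- unlist(lapply(seq_along(regions), function(i) {
    paste0(region_abbrev[[regions[i]]], seq_len(sizes[i]))
  }))
  region_of <- stats::setNames(rep(regions, sizes), labels)
  channel_montage(labels, region_of)
}

# channel indices of one region
region_channels <- function(montage, region) {
  which(montage$region_of == region)
}
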