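#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz, as half-open intervals
#' `[low, high)`: a frequency bin belongs to the band containing its center.
#'
#' @return Named list of `c(low, high)` pairs, in fixed band order.
#' @export
band_scheme <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# indices of the one-sided bins whose center lies in [low, high)
band_bins <- function(freqs, band) {
  which(freqs >= band[1] & freqs < band[2])
}

#' Construct a feature matrix
#'
#' @param values Numeric matrix, trials x features (non-negative power).
#' @param feature_names Character labels, `Region_band[_window]`.
#' @param space_tag One of `"F216"`, `"F24"`, `"PBTST"`.
#' @param trials_meta Per-trial metadata carried over from the epochs.
#' @param feature_regions Region of each feature (full region names).
#' @return A `FeatureMatrix`.
#' @export
feature_matrix <- function(values, feature_names, space_tag, trials_meta,
                           feature_regions) {
  stopifnot(is.matrix(values), ncol(values) == length(feature_names),
            length(feature_regions) == length(feature_names),
            space_tag %in% c("F216", "F24", "PBTST"),
            nrow(trials_meta) == nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 space_tag = space_tag, trials_meta = trials_meta,
                 feature_regions = feature_regions),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d trials x %d features\n", x$space_tag,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# region-major, band-middle, window-minor naming of the F216 space
f216_names <- function(n_win = 9) {
  bands <- names(band_scheme())
  out <- character(0)
  regions <- character(0)
  for (r in scalp_regions()) {
    for (b in bands) {
      out <- c(out, paste(region_abbrev[[r]], b, seq_len(n_win), sep = "_"))
      regions <- c(regions, rep(r, n_win))
    }
  }
  list(names = out, regions = regions)
}

#' Reduce a spectrogram to the region x band x window feature space (F216)
#'
#' For each trial: the PSD is averaged over the bins of each frequency band
#' (bin centers, half-open band edges), then over the channels of each of
#' the six scalp regions, separately per time window. With 6 regions, 4
#' bands and 9 windows this is the 216-dimensional feature space, in
#' region-major, band-middle, window-minor order (`Pre_delta_1`, ...,
#' `O_beta_9`).
#'
#' @param tfr A [spectrogram()] result.
#' @return A `FeatureMatrix` with `space_tag = "F216"`.
#' @export
reduce_to_f216 <- function(tfr) {
  stopifnot(inherits(tfr, "TFR"))
  bands <- band_scheme()
  if (max(vapply(bands, `[`, numeric(1), 2)) > max(tfr$freqs) + 1e-9) {
    stop("band outside the frequency grid")
  }
  d <- dim(tfr$psd)
  n_win <- d[4]
  nm <- f216_names(n_win)
  values <- matrix(0, d[1], length(nm$names))
  col <- 1L
  band_idx <- lapply(bands, band_bins, freqs = tfr$freqs)
  for (r in scalp_regions()) {
    ch <- region_channels(tfr$montage, r)
    ch <- match(names(tfr$montage$region_of)[ch], tfr$channel_names)
    for (b in names(bands)) {
      sub <- tfr$psd[, ch, band_idx[[b]], , drop = FALSE]
      bm <- apply(sub, c(1, 4), mean)  # trials x windows
      values[, col:(col + n_win - 1L)] <- bm
      col <- col + n_win
    }
  }
  feature_matrix(values, nm$names, "F216", tfr$trials_meta, nm$regions)
}

#' Compute F216 features directly from epochs
#'
#' Mathematically identical to `reduce_to_f216(spectrogram(epochs, config))`
#' but evaluates the tapered spectra only at the frequency bins inside the
#' analysis bands and accumulates the band/region averages window by
#' window, avoiding materializing the full spectrogram. Preferred for
#' dataset-scale runs.
#'
#' @param epochs An [epoch_set()].
#' @param config A [multitaper_config()].
#' @return A `FeatureMatrix` with `space_tag = "F216"`.
#' @export
f216_from_epochs <- function(epochs, config = multitaper_config()) {
  stopifnot(inherits(epochs, "EpochSet"))
  d <- dim(epochs$data)
  fs <- epochs$fs
  bands <- band_scheme()
  freqs <- psd_freqs(config$nfft, fs)
  band_idx <- lapply(bands, band_bins, freqs = freqs)
  bins <- sort(unique(unlist(band_idx)))
  local_idx <- lapply(band_idx, match, table = bins)
  n_win <- n_windows(d[3], config$nperseg, config$noverlap)
  step <- config$nperseg - config$noverlap
  bank <- compute_tapers(config$nperseg, config$nw, config$k)
  bases <- taper_bases(bank, config$nfft, bins)
  reg_ch <- lapply(scalp_regions(), function(r) {
    match(names(epochs$montage$region_of)[
      region_channels(epochs$montage, r)], epochs$channel_names)
  })
  names(reg_ch) <- scalp_regions()

  nm <- f216_names(n_win)
  values <- matrix(0, d[1], length(nm$names))
  n_bands <- length(bands)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * step + 1):((w - 1) * step + config$nperseg)
    X <- matrix(epochs$data[, , idx], d[1] * d[2], config$nperseg)
    P <- gemm_power(X, bases, config$nfft, fs, bins)
    # band means: trials*channels x n_bands
    bm <- vapply(names(bands), function(b) {
      rowMeans(P[, local_idx[[b]], drop = FALSE])
    }, numeric(nrow(P)))
    dim(bm) <- c(d[1], d[2], n_bands)
    for (ri in seq_along(reg_ch)) {
      rm <- apply(bm[, reg_ch[[ri]], , drop = FALSE], c(1, 3), mean)
      for (bi in seq_len(n_bands)) {
        col <- (ri - 1) * n_bands * n_win + (bi - 1) * n_win + w
        values[, col] <- rm[, bi]
      }
    }
  }
  feature_matrix(values, nm$names, "F216", epochs$trials_meta, nm$regions)
}

#' Average the F216 space over time windows (F24)
#'
#' Unweighted mean over the window indices per (region, band), giving the
#' 24-dimensional region x band space.
#'
#' @param f216 A `FeatureMatrix` with `space_tag = "F216"`.
#' @return A `FeatureMatrix` with `space_tag = "F24"`.
#' @export
reduce_to_f24 <- function(f216) {
  stopifnot(inherits(f216, "FeatureMatrix"))
  if (f216$space_tag != "F216") stop("input must be the F216 space")
  bands <- names(band_scheme())
  groups <- sub("_[0-9]+$", "", f216$feature_names)
  keys <- unique(groups)
  values <- vapply(keys, function(k) {
    rowMeans(f216$values[, groups == k, drop = FALSE])
  }, numeric(nrow(f216$values)))
  values <- matrix(values, nrow = nrow(f216$values),
                   dimnames = list(NULL, keys))
  regions <- f216$feature_regions[match(keys, groups)]
  feature_matrix(values, keys, "F24", f216$trials_meta, regions)
}

#' Select the prefrontal beta time-series features (PBTST)
#'
#' Projects the F216 space onto the nine prefrontal beta-band window
#' features `Pre_beta_1 .. Pre_beta_9`, the fixed feature set of the
#' prefrontal-beta time-series test. No screening is applied to this set.
#'
#' @param f216 A `FeatureMatrix` with `space_tag = "F216"`.
#' @return A `FeatureMatrix` with `space_tag = "PBTST"`, 9 features.
#' @export
select_pbtst <- function(f216) {
  stopifnot(inherits(f216, "FeatureMatrix"))
  if (f216$space_tag != "F216") stop("input must be the F216 space")
  n_win <- max(as.integer(sub("^.*_", "", f216$feature_names)))
  want <- paste("Pre_beta", seq_len(n_win), sep = "_")
  miss <- setdiff(want, f216$feature_names)
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  idx <- match(want, f216$feature_names)
  feature_matrix(f216$values[, idx, drop = FALSE], want, "PBTST",
                 f216$trials_meta, f216$feature_regions[idx])
}

# Vectorized per-column Welch two-sample t-tests, neutral minus risky.
# Constant columns (zero pooled standard error) get t = 0, p = 1.
welch_tests <- function(x, labels) {
  g1 <- x[labels == "neutral", , drop = FALSE]
  g2 <- x[labels == "risky", , drop = FALSE]
  n1 <- nrow(g1)
  n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least two samples")
  m1 <- colMeans(g1)
  m2 <- colMeans(g2)
  v1 <- colSums(sweep(g1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(g2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stats <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p_values <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stats), df), 1)
  if (any(se2 == 0)) {
    message(sprintf("welch tests: %d constant feature(s), p set to 1",
                    sum(se2 == 0)))
  }
  list(t = t_stats, p = p_values)
}

# BH q-values of the per-column Welch tests; used for nested screening
# inside cross-validation folds.
welch_bh_q <- function(x, labels) {
  stats::p.adjust(welch_tests(x, labels)$p, method = "BH")
}

#' Mass-univariate group screening with FDR control
#'
#' Per-feature Welch two-sample t-test (neutral minus risky) with
#' Benjamini-Hochberg correction; features with `q < alpha` are selected.
#' Reports the selected-set counts: `total`, `pre_f` (selected features in
#' the prefrontal or frontal region) and `ratio = pre_f / total * 100`.
#'
#' @param fm A `FeatureMatrix` whose metadata carries the `group` labels.
#' @param alpha Significance threshold on the q-values (default `1e-3`).
#' @param unit `"trials"` (default) pools trials across subjects as the
#'   test samples; `"subjects"` tests per-subject feature means.
#' @return A `ScreeningResult`: t statistics, p- and q-values, selection
#'   mask and counts.
#' @export
screen_features <- function(fm, alpha = 1e-3, unit = c("trials", "subjects")) {
  stopifnot(inherits(fm, "FeatureMatrix"), alpha > 0, alpha < 1)
  unit <- match.arg(unit)
  x <- fm$values
  labels <- as.character(fm$trials_meta$group)
  if (unit == "subjects") {
    sid <- as.character(fm$trials_meta$subject_id)
    x <- do.call(rbind, lapply(split(seq_len(nrow(x)), sid), function(ii) {
      colMeans(x[ii, , drop = FALSE])
    }))
    labels <- vapply(split(labels, sid), `[`, character(1), 1)
  }
  wt <- welch_tests(x, labels)
  t_stats <- wt$t
  p_values <- wt$p
  q_values <- stats::p.adjust(p_values, method = "BH")
  selected <- q_values < alpha
  total <- sum(selected)
  pre_f <- sum(selected &
                 fm$feature_regions %in% c("prefrontal", "frontal"))
  structure(
    list(t_stats = t_stats, p_values = p_values, q_values = q_values,
         selected = selected, alpha = alpha,
         feature_names = fm$feature_names,
         feature_regions = fm$feature_regions, unit = unit,
         counts = list(total = total, pre_f = pre_f,
                       ratio = if (total > 0) pre_f / total * 100 else 0)),
    class = "ScreeningResult"
  )
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat(sprintf(
    "ScreeningResult: %d/%d selected at q < %g (Pre&F %d, ratio %.2f%%)\n",
    x$counts$total, length(x$selected), x$alpha, x$counts$pre_f,
    round(x$counts$ratio, 2)))
  invisible(x)
}

#' Region-concentration table over screening results
#'
#' One row per condition: the number of selected features (`Total`), the
#' selected features lying in the prefrontal or frontal region (`PreF`)
#' and `Ratio = PreF / Total * 100` rounded to two decimals.
#'
#' @param results Named list of [screen_features()] results.
#' @return Data frame with columns `condition`, `Total`, `PreF`, `Ratio`.
#' @export
ratio_report <- function(results) {
  stopifnot(length(results) > 0)
  rows <- lapply(names(results), function(cond) {
    ct <- results[[cond]]$counts
    data.frame(condition = cond, Total = ct$total, PreF = ct$pre_f,
               Ratio = round(ct$ratio, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
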