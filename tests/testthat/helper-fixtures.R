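# Shared fixture builders; everything is generated in code.

# Minimal EpochSet around a raw trials x channels x samples array,
# using the generic 12-channel montage (2 channels per region).
fixture_epochs <- function(data, fs = 250, t0_offset_ms = -80,
                           meta = NULL) {
  nch <- dim(data)[2]
  mont <- default_montage(nch)
  if (is.null(meta)) {
    n <- dim(data)[1]
    meta <- data.frame(
      subject_id = rep(c("N01", "R01"), length.out = n),
      group = rep(c("neutral", "risky"), length.out = n),
      condition = "SH",
      response_time = 800, correct = TRUE,
      stringsAsFactors = FALSE
    )
  }
  epoch_set(data, fs = fs, t0_offset_ms = t0_offset_ms,
            channel_names = mont$channel_names, montage = mont,
            trials_meta = meta)
}

# A small synthetic dataset config used by several tests.
fixture_config <- function(n_neutral_subjects = 4, n_risky_subjects = 4,
                           trials_per_subject_mean = 12,
                           n_channels = 12, seed = 11, ...) {
  synthetic_config(
    n_neutral_subjects = n_neutral_subjects,
    n_risky_subjects = n_risky_subjects,
    conditions = "SH", trials_per_subject_mean = trials_per_subject_mean,
    trials_per_subject_sd = 0, n_channels = n_channels, seed = seed, ...
  )
}

# Hand-built TFR with constant PSD, for feature-reduction arithmetic.
fixture_constant_tfr <- function(value = 1, n_trials = 3, n_channels = 12,
                                 n_bins = 257, n_win = 9, fs = 250) {
  mont <- default_montage(n_channels)
  meta <- data.frame(
    subject_id = rep(c("N01", "R01"), length.out = n_trials),
    group = rep(c("neutral", "risky"), length.out = n_trials),
    condition = "SH", stringsAsFactors = FALSE
  )
  structure(
    list(psd = array(value, c(n_trials, n_channels, n_bins, n_win)),
         freqs = psd_freqs((n_bins - 1) * 2, fs),
         window_times = seq(0.046, by = 0.128, length.out = n_win),
         fs = fs, config = multitaper_config(),
         channel_names = mont$channel_names, montage = mont,
         trials_meta = meta),
    class = "TFR"
  )
}

# FeatureMatrix in the F216 layout with prescribed values.
fixture_f216 <- function(values, meta = NULL) {
  nm <- taskbeta:::f216_names(9)
  if (is.null(meta)) {
    meta <- data.frame(
      subject_id = rep(c("N01", "R01"), length.out = nrow(values)),
      group = rep(c("neutral", "risky"), length.out = nrow(values)),
      condition = "SH", stringsAsFactors = FALSE
    )
  }
  feature_matrix(values, nm$names, "F216", meta, nm$regions)
}

# Mann-Whitney pair-counting AUC (concordant + half ties), the
# independent oracle for the trapezoidal ROC AUC.
mw_auc <- function(is_positive, scores) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
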