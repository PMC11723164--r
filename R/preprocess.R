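#' Re-reference to the average of two mastoid-adjacent channels
#'
#' Subtracts the sample-wise mean of the two reference channels (typically
#' `TP9` and `TP10`) from every channel, approximating an average-mastoid
#' reference. The reference channels are retained.
#'
#' @param epochs An [epoch_set()].
#' @param left_label,right_label Labels of the two reference channels.
#' @return A re-referenced `EpochSet`.
#' @export
rereference_mastoid <- function(epochs, left_label = "TP9",
                                right_label = "TP10") {
  for (lab in c(left_label, right_label)) {
    if (!lab %in% epochs$channel_names) {
      stop("reference channel not present: ", lab)
    }
  }
  il <- match(left_label, epochs$channel_names)
  ir <- match(right_label, epochs$channel_names)
  ref <- (epochs$data[, il, , drop = FALSE] +
            epochs$data[, ir, , drop = FALSE]) / 2
  out <- epochs
  out$data <- epochs$data - ref[, rep(1, dim(epochs$data)[2]), , drop = FALSE]
  out
}

#' Zero-phase Butterworth bandpass
#'
#' Second-order Butterworth high-pass and low-pass stages, each applied
#' forward-backward (zero phase). With order-2 stages the forward-backward
#' pass puts the *half-amplitude* (-6 dB) point at the stage cutoff, and the
#' per-stage roll-off is 12 dB/octave, matching common ERP filtering
#' practice of quoting half-amplitude cutoffs.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Half-amplitude cutoffs in Hz, `0 < low < high < fs/2`.
#' @return A filtered `EpochSet`.
#' @export
bandpass <- function(epochs, low = 1, high = 30) {
  fs <- epochs$fs
  if (!(low > 0 && low < high && high < fs / 2)) stop("invalid band")
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(2, high / (fs / 2), type = "low")
  out <- epochs
  d <- dim(epochs$data)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      x <- signal::filtfilt(hp, x)
      x <- signal::filtfilt(lp, x)
      out$data[tr, ch, ] <- x
    }
  }
  out
}

#' Trial-selection thresholds
#'
#' @param min_rt,max_rt Response-time window in ms (inclusive); defaults
#'   200 and 1500 (interference task; use 2000 for the memory task).
#' @param require_correct Keep only correct-response trials.
#' @param p2p_threshold Per-channel peak-to-peak rejection threshold in
#'   microvolts; a single violating channel rejects the trial.
#' @return A `TrialFilterSpec`.
#' @export
trial_filter_spec <- function(min_rt = 200, max_rt = 1500,
                              require_correct = TRUE, p2p_threshold = 150) {
  stopifnot(min_rt < max_rt, p2p_threshold > 0)
  structure(list(min_rt = min_rt, max_rt = max_rt,
                 require_correct = require_correct,
                 p2p_threshold = p2p_threshold),
            class = "TrialFilterSpec")
}

#' Select trials by response behaviour and amplitude
#'
#' Keeps trials that (i) are correct responses when required, (ii) have
#' `min_rt <= RT <= max_rt`, and (iii) have peak-to-peak amplitude at or
#' below the threshold in *every* channel. Trials without response metadata
#' (e.g. resting-state segments) pass the behavioural gates and are only
#' subject to the amplitude gate. Trial order is preserved; the operation
#' is idempotent.
#'
#' @param epochs An [epoch_set()].
#' @param spec A [trial_filter_spec()].
#' @return A filtered `EpochSet` (possibly with zero trials).
#' @export
filter_trials <- function(epochs, spec = trial_filter_spec()) {
  stopifnot(inherits(spec, "TrialFilterSpec"))
  meta <- epochs$trials_meta
  rt <- if ("response_time" %in% names(meta)) meta$response_time else
    rep(NA_real_, nrow(meta))
  ok <- if ("correct" %in% names(meta)) meta$correct else rep(NA, nrow(meta))
  rt_pass <- is.na(rt) | (rt >= spec$min_rt & rt <= spec$max_rt)
  correct_pass <- if (spec$require_correct) is.na(ok) | ok else TRUE
  p2p <- apply(epochs$data, 1, function(tr) {
    max(apply(tr, 1, function(x) diff(range(x))))
  })
  keep <- which(rt_pass & correct_pass & p2p <= spec$p2p_threshold)
  n_drop <- n_trials(epochs) - length(keep)
  if (n_drop > 0) {
    message(sprintf("filter_trials: dropped %d of %d trials", n_drop,
                    n_trials(epochs)))
  }
  subset_trials(epochs, trials = keep)
}

#' Segment a continuous resting-state recording into fixed epochs
#'
#' Cuts non-overlapping consecutive epochs of `interval_s` seconds by
#' inserting virtual stimulus zero points; the trailing remainder is
#' discarded. The resulting trials carry condition `"Rest"`.
#'
#' @param continuous Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate, Hz; `interval_s * fs` must be an integer.
#' @param interval_s Epoch length in seconds (default 1.2).
#' @param channel_names,montage Channel labels and montage of the recording.
#' @param subject_id,group Metadata applied to every segment.
#' @return An [epoch_set()] of the segments, `t0_offset_ms = 0`.
#' @export
segment_resting <- function(continuous, fs, interval_s = 1.2,
                            channel_names, montage,
                            subject_id = "S01", group = "neutral") {
  stopifnot(is.matrix(continuous))
  n_per <- interval_s * fs
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("interval_s * fs must be an integer sample count")
  }
  n_per <- as.integer(round(n_per))
  n_seg <- floor(ncol(continuous) / n_per)
  if (n_seg < 1) stop("recording shorter than one interval")
  nch <- nrow(continuous)
  data <- array(0, c(n_seg, nch, n_per))
  for (s in seq_len(n_seg)) {
    data[s, , ] <- continuous[, ((s - 1) * n_per + 1):(s * n_per)]
  }
  epoch_set(data, fs = fs, t0_offset_ms = 0,
            channel_names = channel_names, montage = montage,
            trials_meta = data.frame(
              subject_id = rep(subject_id, n_seg),
              group = rep(group, n_seg),
              condition = rep("Rest", n_seg),
              response_time = rep(NA_real_, n_seg),
              correct = rep(NA, n_seg)
            ))
}

#' Decimate a continuous recording with anti-alias filtering
#'
#' Plain plumbing for inputs sampled above the analysis rate (e.g.
#' 1000 -> 250 Hz): per-channel anti-aliased decimation by an integer
#' factor via [signal::decimate()] (FIR mode, zero phase).
#'
#' @param continuous Numeric matrix, channels x samples.
#' @param factor Integer decimation factor.
#' @return Matrix, channels x `floor(samples / factor)` (as returned by the
#'   decimator, channels x ceiling for partial tails).
#' @export
decimate_recording <- function(continuous, factor) {
  stopifnot(is.matrix(continuous), factor >= 2, factor == round(factor))
  out <- t(apply(continuous, 1, function(x) {
    signal::decimate(x, factor, ftype = "fir")
  }))
  out
}
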