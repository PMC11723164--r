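#' Configuration for the synthetic two-group EEG generator
#'
#' The generator emulates the structure of the study data: two subject
#' groups (neutral / risky), 60 channels in six scalp regions, 250 Hz epochs
#' spanning -80..1200 ms (320 samples), per-condition trial counts at the
#' scale of the source study's availability table, and a group-level
#' reduction of prefrontal beta-band source power in the risky group whose
#' within-epoch envelope follows the observed temporal shape (onset
#' activation, minimum near 0.6 s, late rebound).
#'
#' @param n_neutral_subjects,n_risky_subjects Subject counts (defaults 21
#'   and 18, the study's group sizes).
#' @param conditions Conditions to generate, subset of
#'   `c("ML","MH","SL","SH","Rest")`.
#' @param trials_per_subject_mean,trials_per_subject_sd Optional scalar
#'   overrides of the per-condition trial-count distribution; if `NULL`
#'   (default) each condition uses its study-scale mean/sd
#'   (ML 77.04/6.68, MH 72.65/7.65, SL 63.61/6.49, SH 53.20/8.69,
#'   Rest 160/15). Counts are drawn from a normal truncated at 10.
#' @param fs Sampling rate, Hz.
#' @param epoch_window_ms Epoch limits in ms relative to stimulus onset,
#'   half-open `[start, end)`.
#' @param n_channels Channel count; `montage` defaults to
#'   [default_montage()] of this size.
#' @param montage Optional [channel_montage()].
#' @param beta_effect Fraction in `[0, 1)`: relative reduction of the
#'   prefrontal beta-band source *amplitude* in the risky group (source
#'   power is reduced by `1 - (1 - beta_effect)^2`). `0` yields
#'   exchangeable groups.
#' @param temporal_profile Numeric vector of 9 power gains, one per
#'   multitaper time window, shaping the prefrontal beta envelope.
#' @param subject_sd Between-subject standard deviation of log source
#'   power.
#' @param noise_sd Innovation scale of the broadband AR(1) noise, microvolts.
#' @param beta_amp Prefrontal beta source amplitude scale, microvolts.
#' @param osc_amp Amplitude of the generic per-region band oscillations.
#' @param ar_phi AR(1) coefficient of the broadband noise (spectral decay).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   full configuration.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_neutral_subjects = 21, n_risky_subjects = 18,
                             conditions = c("ML", "MH", "SL", "SH", "Rest"),
                             trials_per_subject_mean = NULL,
                             trials_per_subject_sd = NULL,
                             fs = 250, epoch_window_ms = c(-80, 1200),
                             n_channels = 60, montage = NULL,
                             beta_effect = 0.3,
                             temporal_profile = c(1, 1, 0.75, 0.5, 0.35,
                                                  0.45, 0.6, 0.7, 0.75),
                             subject_sd = 0.2, noise_sd = 1,
                             beta_amp = 2, osc_amp = 0.8, ar_phi = 0.95,
                             seed = 1) {
  stopifnot(n_neutral_subjects >= 1, n_risky_subjects >= 1,
            fs > 0, n_channels >= 6,
            beta_effect >= 0, beta_effect < 1,
            subject_sd >= 0, noise_sd > 0,
            length(temporal_profile) >= 2, all(temporal_profile >= 0))
  conditions <- match.arg(conditions, c("ML", "MH", "SL", "SH", "Rest"),
                          several.ok = TRUE)
  n_samples <- round(diff(epoch_window_ms) * fs / 1000)
  if (n_samples <= 0) stop("empty epoch window")
  trial_defaults <- list(
    ML = c(77.04, 6.68), MH = c(72.65, 7.65),
    SL = c(63.61, 6.49), SH = c(53.20, 8.69), Rest = c(160, 15)
  )
  counts <- lapply(trial_defaults[conditions], function(ms) {
    if (!is.null(trials_per_subject_mean)) {
      ms[1] <- trials_per_subject_mean
    }
    if (!is.null(trials_per_subject_sd)) ms[2] <- trials_per_subject_sd
    ms
  })
  if (is.null(montage)) montage <- default_montage(n_channels)
  if (length(montage$channel_names) != n_channels) {
    stop("montage size does not match n_channels")
  }
  structure(
    list(n_neutral_subjects = n_neutral_subjects,
         n_risky_subjects = n_risky_subjects,
         conditions = conditions, trial_counts = counts,
         fs = fs, epoch_window_ms = epoch_window_ms, n_samples = n_samples,
         n_channels = n_channels, montage = montage,
         beta_effect = beta_effect, temporal_profile = temporal_profile,
         subject_sd = subject_sd, noise_sd = noise_sd,
         beta_amp = beta_amp, osc_amp = osc_amp, ar_phi = ar_phi,
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

# Band-limited unit-variance Gaussian noise, samples x cols.
# FFT masking keeps bins whose aliased frequency lies in [lo, hi);
# the theoretical post-mask variance (kept-bin fraction) is divided out so
# columns stay independent with expected variance 1.
bandlimited_noise <- function(n_samples, n_cols, fs, band) {
  x <- matrix(stats::rnorm(n_samples * n_cols), n_samples, n_cols)
  f_alias <- pmin(0:(n_samples - 1), n_samples - (0:(n_samples - 1))) *
    fs / n_samples
  mask <- f_alias >= band[1] & f_alias < band[2]
  if (!any(mask)) stop("band outside the representable grid")
  xf <- stats::mvfft(x) * mask
  y <- Re(stats::mvfft(xf, inverse = TRUE)) / n_samples
  y / sqrt(mean(mask))
}

# AR(1) broadband noise, samples x cols, innovation sd `sd`.
ar1_noise <- function(n_samples, n_cols, phi, sd) {
  e <- matrix(stats::rnorm(n_samples * n_cols, sd = sd), n_samples, n_cols)
  x <- e
  x[1, ] <- e[1, ] / sqrt(1 - phi^2)  # stationary start
  for (t in 2:n_samples) x[t, ] <- phi * x[t - 1, ] + e[t, ]
  x
}

# Amplitude envelope over the epoch implied by the per-window power gains.
profile_envelope <- function(profile, n_samples, fs, nperseg = 64,
                             noverlap = 32) {
  step <- nperseg - noverlap
  n_win <- length(profile)
  centers <- ((seq_len(n_win) - 1) * step + (nperseg - 1) / 2) / fs
  times <- (seq_len(n_samples) - 1) / fs
  gain <- stats::approx(centers, profile, xout = times, rule = 2)$y
  sqrt(pmax(gain, 0))
}

#' Generate a synthetic two-group epoched EEG dataset
#'
#' Each epoch is the sum of (i) per-channel AR(1) broadband noise with a
#' decaying spectrum, (ii) per-region band-limited Gaussian oscillations in
#' the four canonical bands (delta/theta/alpha/beta), shared by the channels
#' of a region within a trial, and (iii) a prefrontal beta-band source whose
#' within-epoch envelope follows `temporal_profile`, whose amplitude carries
#' a per-subject lognormal gain, and which is scaled by
#' `1 - beta_effect` for risky subjects. Deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return An [epoch_set()] with per-trial subject, group, condition,
#'   response time and correctness metadata.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  mont <- config$montage
  nch <- config$n_channels
  ns <- config$n_samples
  fs <- config$fs
  bands <- band_scheme()

  subj_ids <- c(sprintf("N%02d", seq_len(config$n_neutral_subjects)),
                sprintf("R%02d", seq_len(config$n_risky_subjects)))
  subj_grp <- c(rep("neutral", config$n_neutral_subjects),
                rep("risky", config$n_risky_subjects))
  # per-subject amplitude gain: power gain exp(N(0, subject_sd))
  subj_gain <- exp(stats::rnorm(length(subj_ids), 0, config$subject_sd) / 2)

  env <- profile_envelope(config$temporal_profile, ns, fs)
  reg_idx <- lapply(scalp_regions(), function(r) region_channels(mont, r))
  names(reg_idx) <- scalp_regions()

  # trial counts drawn up-front so the data array can be preallocated
  grid <- expand.grid(cond = config$conditions, si = seq_along(subj_ids),
                      stringsAsFactors = FALSE)[, c("si", "cond")]
  grid <- grid[order(grid$si), ]
  n_t_all <- vapply(seq_len(nrow(grid)), function(i) {
    ms <- config$trial_counts[[grid$cond[i]]]
    max(10L, as.integer(round(stats::rnorm(1, ms[1], ms[2]))))
  }, integer(1))
  total <- sum(n_t_all)
  data <- array(0, c(total, nch, ns))
  meta <- list()
  at <- 1L
  for (i in seq_len(nrow(grid))) {
    si <- grid$si[i]
    cond <- grid$cond[i]
    {
      n_t <- n_t_all[i]
      arr <- array(0, c(n_t, nch, ns))
      bb <- ar1_noise(ns, nch * n_t, config$ar_phi, config$noise_sd)
      dim(bb) <- c(ns, nch, n_t)
      for (ch in seq_len(nch)) arr[, ch, ] <- t(bb[, ch, ])
      for (r in scalp_regions()) {
        osc <- matrix(0, ns, n_t)
        for (b in names(bands)) {
          osc <- osc + config$osc_amp *
            bandlimited_noise(ns, n_t, fs, bands[[b]])
        }
        for (ch in reg_idx[[r]]) arr[, ch, ] <- arr[, ch, ] + t(osc)
      }
      amp <- config$beta_amp * subj_gain[si] *
        (if (subj_grp[si] == "risky") 1 - config$beta_effect else 1)
      src <- amp * env * bandlimited_noise(ns, n_t, fs, bands$beta)
      for (ch in reg_idx$prefrontal) arr[, ch, ] <- arr[, ch, ] + t(src)

      if (cond == "Rest") {
        rt <- rep(NA_real_, n_t)
        ok <- rep(NA, n_t)
      } else {
        rt <- round(stats::rlnorm(n_t, log(550), 0.25))
        ok <- stats::runif(n_t) < 0.92
      }
      data[at:(at + n_t - 1L), , ] <- arr
      at <- at + n_t
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = subj_ids[si], group = subj_grp[si], condition = cond,
        response_time = rt, correct = ok, stringsAsFactors = FALSE
      )
    }
  }
  epoch_set(data, fs = fs, t0_offset_ms = config$epoch_window_ms[1],
            channel_names = mont$channel_names, montage = mont,
            trials_meta = do.call(rbind, meta))
}
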