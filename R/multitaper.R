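#' Multitaper time-frequency parameters
#'
#' Defaults follow the analysis settings: time-bandwidth product `NW = 4`,
#' `K = 7` tapers, 64-sample windows with 32-sample overlap, and a 512-point
#' FFT grid (frequency spacing `fs / nfft`). At most `2*NW - 1` tapers are
#' well concentrated, so `K <= 2*NW - 1` is enforced.
#'
#' @param nw Time-bandwidth product.
#' @param k Number of Slepian tapers.
#' @param nperseg Samples per window.
#' @param noverlap Overlapping samples between consecutive windows.
#' @param nfft FFT length (power of 2, `>= nperseg`).
#' @return A `MultitaperConfig`.
#' @export
multitaper_config <- function(nw = 4, k = 7, nperseg = 64, noverlap = 32,
                              nfft = 512) {
  stopifnot(nw > 0, k >= 1, nperseg > 1, noverlap >= 0)
  if (k > 2 * nw - 1) {
    stop("K must not exceed 2*NW - 1 (poorly concentrated tapers)")
  }
  if (noverlap >= nperseg) stop("noverlap must be smaller than nperseg")
  if (nfft < nperseg) stop("nfft must be at least nperseg")
  if (bitwAnd(nfft, nfft - 1L) != 0L) stop("nfft must be a power of 2")
  structure(list(nw = nw, k = k, nperseg = as.integer(nperseg),
                 noverlap = as.integer(noverlap), nfft = as.integer(nfft)),
            class = "MultitaperConfig")
}

#' Compute a bank of Slepian (DPSS) tapers
#'
#' Discrete prolate spheroidal sequences: the length-`nperseg` sequences
#' maximizing energy concentration in the band `|f| <= W = NW/nperseg`
#' (in cycles/sample). They are computed as eigenvectors of the standard
#' symmetric tridiagonal formulation of the concentration problem, which is
#' numerically stable and shares its eigenvectors with the concentration
#' operator. The reported eigenvalues are the true in-band concentration
#' ratios, obtained from the sinc-kernel quadratic form, and are returned
#' in decreasing order.
#'
#' @param nperseg Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (`<= 2*nw - 1`).
#' @return A `TaperBank`: list with `tapers` (k x nperseg, unit energy,
#'   first non-zero element of each taper positive) and `eigenvalues`
#'   (concentration ratios in (0, 1), decreasing).
#' @export
compute_tapers <- function(nperseg = 64, nw = 4, k = 7) {
  stopifnot(nperseg > 1, nw > 0, nw < nperseg / 2)
  if (k > 2 * nw - 1) {
    stop("K must not exceed 2*NW - 1 (poorly concentrated tapers)")
  }
  n <- as.integer(nperseg)
  w <- nw / n
  i <- seq_len(n) - 1
  # symmetric tridiagonal commuting with the concentration operator
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  tri <- diag(diag_main)
  tri[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  tri[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  es <- eigen(tri, symmetric = TRUE)
  vecs <- es$vectors[, seq_len(k), drop = FALSE]
  # unit energy and sign convention
  for (j in seq_len(k)) {
    v <- vecs[, j]
    v <- v / sqrt(sum(v^2))
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v
    vecs[, j] <- v
  }
  # concentration ratios from the sinc kernel quadratic form
  dm <- outer(i, i, "-")
  kern <- ifelse(dm == 0, 2 * w, sin(2 * pi * w * dm) / (pi * dm))
  lambda <- vapply(seq_len(k), function(j) {
    drop(crossprod(vecs[, j], kern %*% vecs[, j]))
  }, numeric(1))
  ord <- order(lambda, decreasing = TRUE)
  structure(list(tapers = t(vecs[, ord, drop = FALSE]),
                 eigenvalues = lambda[ord],
                 nw = nw, nperseg = n),
            class = "TaperBank")
}

#' One-sided frequency grid of the spectral estimates
#' @param nfft FFT length.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of `nfft/2 + 1` bin center frequencies.
#' @export
psd_freqs <- function(nfft, fs) {
  (0:(nfft / 2)) * fs / nfft
}

# fold a two-sided power vector/matrix (bins along `margin`) to one-sided
# with doubled power at non-DC, non-Nyquist bins
onesided_scale <- function(nfft) {
  s <- rep(2, nfft / 2 + 1)
  s[1] <- 1
  s[nfft / 2 + 1] <- 1
  s
}

#' Single-taper power spectrum of one window
#'
#' The squared magnitude of the DFT of the tapered window, scaled to power
#' per Hz on the one-sided grid (power at non-DC/non-Nyquist bins doubled).
#' With a unit-energy taper, the integral of the one-sided spectrum over
#' frequency recovers the windowed signal power.
#'
#' @param x Numeric vector, the window samples.
#' @param taper Numeric vector of the same length (unit energy).
#' @param nfft FFT length.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of `nfft/2 + 1` power densities.
#' @export
per_taper_spectrum <- function(x, taper, nfft, fs) {
  if (length(x) != length(taper)) stop("x and taper lengths differ")
  y <- stats::fft(c(x * taper, rep(0, nfft - length(x))))
  p <- Mod(y[1:(nfft / 2 + 1)])^2 / fs
  p * onesided_scale(nfft)
}

#' Multitaper PSD of one window
#'
#' The unweighted mean of the per-taper spectra over the `K` tapers of the
#' bank (no adaptive eigenvalue weighting).
#'
#' @param x Numeric vector, the window samples.
#' @param bank A [compute_tapers()] bank.
#' @param nfft FFT length.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of `nfft/2 + 1` power densities.
#' @export
multitaper_psd <- function(x, bank, nfft, fs) {
  stopifnot(inherits(bank, "TaperBank"))
  k <- nrow(bank$tapers)
  if (k < 1) stop("empty taper bank")
  acc <- numeric(nfft / 2 + 1)
  for (j in seq_len(k)) {
    acc <- acc + per_taper_spectrum(x, bank$tapers[j, ], nfft, fs)
  }
  acc / k
}

# number of sliding windows for a given epoch length
n_windows <- function(n_samples, nperseg, noverlap) {
  if (n_samples < nperseg) stop("epoch shorter than one window")
  floor((n_samples - nperseg) / (nperseg - noverlap)) + 1
}

# window center times (s) relative to stimulus onset
window_center_times <- function(n_win, nperseg, noverlap, fs, t0_offset_ms) {
  step <- nperseg - noverlap
  t0_offset_ms / 1000 + ((seq_len(n_win) - 1) * step + (nperseg - 1) / 2) / fs
}

# tapered Fourier bases for GEMM evaluation of per-taper power at `bins`
# (1-based one-sided bin indices). Returns list of K (nperseg x nbins) pairs.
taper_bases <- function(bank, nfft, bins) {
  n <- bank$nperseg
  tt <- seq_len(n) - 1
  ang <- outer(tt, bins - 1) * (2 * pi / nfft)
  co <- cos(ang)
  si <- sin(ang)
  lapply(seq_len(nrow(bank$tapers)), function(j) {
    list(c = bank$tapers[j, ] * co, s = bank$tapers[j, ] * si)
  })
}

# mean per-taper power of a windows-matrix X (rows = signals, cols = samples)
# at the selected bins; returns rows x bins, power per Hz, one-sided scaling
# applied for the given bins.
gemm_power <- function(X, bases, nfft, fs, bins) {
  acc <- 0
  for (b in bases) {
    acc <- acc + (X %*% b$c)^2 + (X %*% b$s)^2
  }
  scale <- onesided_scale(nfft)[bins]
  sweep(acc / (length(bases) * fs), 2, scale, "*")
}

#' Multitaper spectrogram of an EpochSet
#'
#' Slides windows of `nperseg` samples with step `nperseg - noverlap` over
#' each epoch and computes the multitaper PSD per channel and window. For
#' the analysis defaults (320-sample epochs, 64/32 windowing) this yields 9
#' time windows and 257 one-sided frequency bins of the 512-point grid.
#'
#' @param epochs An [epoch_set()].
#' @param config A [multitaper_config()].
#' @return A `TFR` object: `psd` array trials x channels x freq_bins x
#'   windows (power per Hz), `freqs`, `window_times` (s, window centers
#'   relative to stimulus onset), plus the epochs' metadata and montage.
#' @export
spectrogram <- function(epochs, config = multitaper_config()) {
  stopifnot(inherits(epochs, "EpochSet"), inherits(config, "MultitaperConfig"))
  d <- dim(epochs$data)
  n_win <- n_windows(d[3], config$nperseg, config$noverlap)
  step <- config$nperseg - config$noverlap
  nbins <- config$nfft / 2 + 1
  bank <- compute_tapers(config$nperseg, config$nw, config$k)
  bases <- taper_bases(bank, config$nfft, seq_len(nbins))
  psd <- array(0, c(d[1], d[2], nbins, n_win))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * step + 1):((w - 1) * step + config$nperseg)
    X <- matrix(epochs$data[, , idx], d[1] * d[2], config$nperseg)
    psd[, , , w] <- gemm_power(X, bases, config$nfft, epochs$fs,
                               seq_len(nbins))
  }
  structure(
    list(psd = psd,
         freqs = psd_freqs(config$nfft, epochs$fs),
         window_times = window_center_times(n_win, config$nperseg,
                                            config$noverlap, epochs$fs,
                                            epochs$t0_offset_ms),
         fs = epochs$fs, config = config,
         channel_names = epochs$channel_names, montage = epochs$montage,
         trials_meta = epochs$trials_meta),
    class = "TFR"
  )
}

#' @export
print.TFR <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf("TFR: %d trials x %d channels x %d bins x %d windows\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
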