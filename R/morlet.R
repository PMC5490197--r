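# Complex Morlet wavelet transform at a single centre frequency, the basis
# of the primary spindle detector.

#' Complex Morlet wavelet specification
#'
#' The wavelet is parameterized by its centre frequency `F_C` (the frequency
#' targeted most strongly) and its number of cycles `n`. The time-domain
#' Gaussian envelope has standard deviation `s = n / (2 pi F_C)` and the
#' bandwidth parameter is `F_B = 2 s^2`; larger `n` narrows the frequency
#' response at the cost of time resolution.
#'
#' @param fc Centre frequency in Hz (8-18 for spindle work).
#' @param n_cycles Number of cycles (7 for the canonical analysis, 12 for
#'   the frequency sweep).
#' @return A list with `fc`, `n_cycles`, `s`, `fb`.
#' @export
wavelet_spec <- function(fc = 13.5, n_cycles = 7) {
  stopifnot(fc > 0, n_cycles > 0)
  s <- n_cycles / (2 * pi * fc)
  list(fc = fc, n_cycles = n_cycles, s = s, fb = 2 * s^2)
}

# Sampled complex Morlet kernel psi(t) = (pi F_B)^(-1/2) e^{2 i pi F_C t} e^{-t^2/F_B},
# truncated at +/- 5 envelope SDs. The overall amplitude normalization is
# immaterial to detection (the threshold is adaptive).
.morlet_kernel <- function(spec, rate) {
  half <- ceiling(5 * spec$s * rate)
  t <- (-half:half) / rate
  (pi * spec$fb)^(-0.5) * exp(2i * pi * spec$fc * t) * exp(-t^2 / spec$fb) / rate
}

#' Magnitude of the complex Morlet wavelet transform
#'
#' Convolves the signal with the complex Morlet kernel (FFT-based) and
#' returns the modulus, an envelope of band-limited activity around the
#' wavelet's centre frequency. Same length as the input; samples within
#' half a kernel of either end are edge-affected (attribute `edge`).
#'
#' @param x Numeric signal at `rate` Hz (band-pass filtered EEG).
#' @param spec A [wavelet_spec()].
#' @param rate Sampling rate in Hz.
#' @return Numeric magnitude series with attribute `edge` (samples).
#' @export
cmor_magnitude <- function(x, spec = wavelet_spec(), rate = 128) {
  k <- .morlet_kernel(spec, rate)
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (n < length(k)) stop("signal shorter than wavelet support")
  N <- nextn(n + length(k) - 1L)
  X <- fft(c(x, rep(0, N - n)))
  K <- fft(c(k, rep(0, N - length(k))))
  full <- fft(X * K, inverse = TRUE) / N
  out <- Mod(full[(half + 1L):(half + n)])
  attr(out, "edge") <- half
  out
}

#' Smooth a coefficient series and compute the individual baseline
#'
#' Applies a centered moving average of `smooth_s` seconds (13 samples at
#' 128 Hz; edges use the samples that exist) and returns the baseline: the
#' mean of the smoothed series across all retained (artifact-free N2)
#' samples for this individual/channel. The detection statistic is the
#' smoothed series divided by this baseline, which makes detection
#' invariant to overall signal scale.
#'
#' @param mag Coefficient magnitude series from [cmor_magnitude()].
#' @param keep Logical sample mask of retained N2 (or NULL for all).
#' @param rate Sampling rate in Hz.
#' @param smooth_s Smoothing window in seconds (default 0.1).
#' @return A list with `smoothed` and `baseline`.
#' @export
smooth_and_baseline <- function(mag, keep = NULL, rate = 128, smooth_s = 0.1) {
  w <- max(1L, as.integer(round(smooth_s * rate)))
  sm <- as.numeric(stats::filter(mag, rep(1, w), sides = 2))
  cnt <- as.numeric(stats::filter(rep(1, length(mag)), rep(1, w), sides = 2))
  # edge-aware: normalize by the number of samples actually in the window
  na <- is.na(sm)
  if (any(na)) {
    csum <- cumsum(c(0, mag))
    half <- w %/% 2
    idx <- which(na)
    lo <- pmax(1L, idx - half)
    hi <- pmin(length(mag), idx + half)
    sm[na] <- (csum[hi + 1L] - csum[lo]) ; cnt[na] <- hi - lo + 1L
  }
  sm <- sm / cnt
  if (is.null(keep)) keep <- rep(TRUE, length(mag))
  if (!any(keep)) stop("empty retained-sample mask")
  list(smoothed = sm, baseline = mean(sm[keep]))
}
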