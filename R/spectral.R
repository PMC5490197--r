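# Welch spectral estimation and band power over retained N2 epochs.

# periodic Hann (DFT-even), the convention of standard Welch implementations
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Segment a vector (or list of equal-rate vectors) into windowed chunks.
.welch_segments <- function(x, L, step) {
  xs <- if (is.list(x)) x else list(x)
  out <- list()
  for (v in xs) {
    if (length(v) < L) next
    starts <- seq(1L, length(v) - L + 1L, by = step)
    out <- c(out, lapply(starts, function(s) v[s:(s + L - 1L)]))
  }
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann window, 4-s segments and 50%
#' overlap by default (0.25 Hz resolution at 128 Hz). When `x` is a list of
#' epochs, segments are taken within each epoch and averaged across all of
#' them, so removed epochs never contribute.
#'
#' @param x Numeric vector, or list of numeric vectors (e.g. retained 30-s
#'   epochs), in microvolts.
#' @param rate Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 4).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param detrend Remove each segment's mean before windowing (default TRUE).
#' @return A tibble with `freq` (Hz) and `psd` (uV^2/Hz, one-sided).
#' @export
welch_psd <- function(x, rate = 128, window_s = 4, overlap = 0.5, detrend = TRUE) {
  L <- as.integer(round(window_s * rate))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  segs <- .welch_segments(x, L, step)
  if (!length(segs)) stop("no segment of length ", L, " available")
  w <- .hann(L)
  U <- sum(w^2)
  nf <- L %/% 2 + 1L
  mat <- vapply(segs, function(s) {
    if (detrend) s <- s - mean(s)
    a <- Mod(fft(s * w))[seq_len(nf)]^2
    a <- a / (rate * U)
    a[2:(nf - 1L)] <- 2 * a[2:(nf - 1L)]  # one-sided
    a
  }, numeric(nf))
  tibble(freq = (seq_len(nf) - 1) * rate / L,
         psd = rowMeans(mat))
}

#' Welch magnitude-squared coherence
#'
#' @inheritParams welch_psd
#' @param y Second signal (vector or epoch list congruent with `x`).
#' @return A tibble with `freq` and `coherence` in `[0, 1]`.
#' @export
welch_coherence <- function(x, y, rate = 128, window_s = 4, overlap = 0.5) {
  L <- as.integer(round(window_s * rate))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  sx <- .welch_segments(x, L, step)
  sy <- .welch_segments(y, L, step)
  if (length(sx) != length(sy) || !length(sx)) stop("x and y must segment identically")
  w <- .hann(L)
  nf <- L %/% 2 + 1L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (i in seq_along(sx)) {
    X <- fft((sx[[i]] - mean(sx[[i]])) * w)[seq_len(nf)]
    Y <- fft((sy[[i]] - mean(sy[[i]])) * w)[seq_len(nf)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  coh <- Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.xmin)
  tibble(freq = (seq_len(nf) - 1) * rate / L, coherence = coh)
}

.band_table <- tibble::tibble(
  band = c("slow", "delta", "theta", "alpha", "sigma", "beta"),
  low = c(0.5, 1, 4, 8, 12, 15),
  high = c(1, 4, 8, 12, 15, 30)
)

#' Absolute and relative spectral band power
#'
#' Integrates the PSD over the six conventional bands - slow (0.5-1 Hz),
#' delta (1-4), theta (4-8), alpha (8-12), sigma (12-15), beta (15-30) -
#' with half-open `[low, high)` edges so shared endpoints are not counted
#' twice. Absolute power is stored as its natural log; relative power is the
#' log of the band's share of the six-band sum, so the exponentiated
#' relative powers sum to one.
#'
#' @param spectrum A tibble from [welch_psd()].
#' @return A tibble with `band`, `abs_power` (uV^2), `abs_log`, `rel_log`.
#' @export
band_power <- function(spectrum) {
  df <- diff(spectrum$freq[1:2])
  pow <- vapply(seq_len(nrow(.band_table)), function(i) {
    sel <- spectrum$freq >= .band_table$low[i] & spectrum$freq < .band_table$high[i]
    sum(spectrum$psd[sel]) * df
  }, 0)
  if (any(pow <= 0)) warning("zero power in band(s): ",
                             paste(.band_table$band[pow <= 0], collapse = ", "))
  total <- sum(pow)
  tibble(band = .band_table$band, abs_power = pow,
         abs_log = ifelse(pow > 0, log(pow), NA_real_),
         rel_log = ifelse(pow > 0, log(pow / total), NA_real_))
}
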