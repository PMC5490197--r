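# Cardiac interference handling: R-peak detection (Pan-Tompkins style),
# per-individual/channel QRS-locked EEG signature estimation, ensemble
# average subtraction, implausible-heart-rate epoch filtering and
# sigma-band EEG/ECG coherence.

#' Detect R peaks in an ECG channel
#'
#' A Pan-Tompkins style detector scaled to 128 Hz: zero-phase 5-15 Hz
#' band-pass, differentiation, squaring, 150-ms moving-window integration,
#' then adaptive signal/noise thresholding with a 250-ms refractory period.
#' Detection is polarity-robust (squaring) and each accepted beat is
#' refined to the local maximum of the absolute band-passed ECG.
#'
#' @param ecg Numeric ECG signal.
#' @param rate Sampling rate in Hz (default 128).
#' @return Numeric vector of R-peak times in seconds (strictly increasing).
#' @export
detect_r_peaks <- function(ecg, rate = 128) {
  n <- length(ecg)
  if (n < 3 * rate || sd(ecg) == 0) return(numeric(0))
  hp <- signal::butter(2, 5 / (rate / 2), type = "high")
  lp <- signal::butter(2, 15 / (rate / 2), type = "low")
  bp <- as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, ecg)))
  sq <- c(0, diff(bp))^2
  w <- max(3L, round(0.150 * rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) return(numeric(0))
  refractory <- round(0.250 * rate)
  init <- integ[seq_len(min(n, 2 * rate))]
  spki <- max(init)
  npki <- mean(init)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr && (i - last) > refractory) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) return(numeric(0))
  # refine to the sharp deflection of the band-passed ECG
  half <- round(0.100 * rate)
  ref <- vapply(peaks, function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    as.integer(a + which.max(abs(bp[a:b])) - 1L)
  }, 0L)
  ref <- sort(unique(ref))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(ref) > refractory)
  (ref[keep] - 1) / rate
}

#' Per-epoch heart rate from R-R intervals
#'
#' @param peak_times R-peak times in seconds.
#' @param n_epochs Number of 30-s epochs.
#' @return Numeric vector of beats/min (`NA` where fewer than 2 peaks fall
#'   in the epoch).
#' @export
heart_rate_by_epoch <- function(peak_times, n_epochs) {
  vapply(seq_len(n_epochs) - 1L, function(e) {
    p <- peak_times[peak_times >= e * 30 & peak_times < (e + 1) * 30]
    if (length(p) < 2) NA_real_ else 60 / mean(diff(p))
  }, 0)
}

#' Drop epochs with implausible sleeping heart rate
#'
#' @param hr Per-epoch heart rate (beats/min; `NA` allowed).
#' @param hr_min,hr_max Plausible range bounds; epochs are dropped iff
#'   `hr < hr_min` or `hr > hr_max` (strict, so exactly 40 or 100 is kept).
#'   Epochs with undefined heart rate are retained.
#' @return Logical exclusion vector.
#' @export
heart_rate_epoch_filter <- function(hr, hr_min = 40, hr_max = 100) {
  !is.na(hr) & (hr < hr_min | hr > hr_max)
}

#' Build the QRS-locked EEG signature for one channel
#'
#' Averages EEG intervals synchronized by R peaks, spanning `window_s`
#' seconds total of which `pre_s` precedes the peak (the pre-R portion
#' captures the Q dip and rising R edge of the leaked complex). Each
#' interval is truncated where the next beat's window begins. Each time
#' point of the signature is the mean over however many intervals reached
#' that point, so late points (beyond the shortest R-R interval) are
#' averages of fewer contributions.
#'
#' @param eeg Numeric EEG signal.
#' @param peak_times R-peak times (s).
#' @param keep Logical sample mask (TRUE inside retained N2 epochs).
#' @param rate Sampling rate (Hz).
#' @param window_s Total signature window in seconds (default 2).
#' @param pre_s Portion of the window before the R peak (default 0.25 s).
#' @param min_peaks Minimum usable peaks; fewer returns `NULL` (the
#'   individual proceeds uncorrected, flagged upstream).
#' @return A list with `template` (uV), `counts`, `pre` (samples before
#'   the peak), `n_peaks`; or `NULL`.
#' @export
build_signature <- function(eeg, peak_times, keep = NULL, rate = 128,
                            window_s = 2, pre_s = 0.25, min_peaks = 30) {
  n <- length(eeg)
  if (is.null(keep)) keep <- rep(TRUE, n)
  L <- as.integer(round(window_s * rate))
  pre <- as.integer(round(pre_s * rate))
  p <- round(peak_times * rate) + 1L
  p <- p[p >= 1 & p <= n]
  usable <- p[keep[p]]
  if (length(usable) < min_peaks) return(NULL)
  nxt <- c(p[-1], n + L)[match(usable, p)]
  acc <- cnt <- numeric(L)
  for (j in seq_along(usable)) {
    from <- max(usable[j] - pre, 1L)
    stop_at <- min(usable[j] - pre + L - 1L, nxt[j] - pre - 1L, n)
    if (stop_at < from) next
    k <- from:stop_at
    kk <- k[keep[k]]
    if (!length(kk)) next
    off <- kk - (usable[j] - pre) + 1L
    acc[off] <- acc[off] + eeg[kk]
    cnt[off] <- cnt[off] + 1
  }
  template <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  list(template = template, counts = cnt, pre = pre, n_peaks = length(usable))
}

#' Subtract the QRS-locked signature at every R peak
#'
#' The signature is aligned with each R peak and subtracted from the EEG,
#' truncated at the next R peak (symmetric with how it was built), yielding
#' the cardiac-corrected signal.
#'
#' @param eeg Numeric EEG signal.
#' @param peak_times R-peak times (s).
#' @param signature Result of [build_signature()].
#' @param rate Sampling rate (Hz).
#' @return Corrected EEG of the same length.
#' @export
subtract_signature <- function(eeg, peak_times, signature, rate = 128) {
  if (is.null(signature)) return(eeg)
  n <- length(eeg)
  tmpl <- signature$template
  pre <- signature$pre %||% 0L
  L <- length(tmpl)
  p <- round(peak_times * rate) + 1L
  p <- p[p >= 1 & p <= n]
  nxt <- c(p[-1], n + L)
  out <- eeg
  for (j in seq_along(p)) {
    from <- max(p[j] - pre, 1L)
    stop_at <- min(p[j] - pre + L - 1L, nxt[j] - pre - 1L, n)
    if (stop_at < from) next
    k <- from:stop_at
    out[k] <- out[k] - tmpl[k - (p[j] - pre) + 1L]
  }
  out
}

#' Sigma-band EEG/ECG coherence
#'
#' Mean Welch magnitude-squared coherence between an EEG channel and the ECG
#' over 12-15 Hz, computed on retained N2 epochs only. High values indicate
#' cardiac leakage into the EEG.
#'
#' @param eeg,ecg Signals at `rate` Hz.
#' @param mask Epoch mask tibble (or NULL to use the whole signals).
#' @param grid Epoch grid (required with `mask`).
#' @param rate Sampling rate (Hz).
#' @return Scalar coherence in `[0, 1]` (`NA` if undefined).
#' @export
sigma_coherence <- function(eeg, ecg, mask = NULL, grid = NULL, rate = 128) {
  if (is.null(mask)) {
    ex <- list(eeg); cx <- list(ecg)
  } else {
    rows <- which(mask$keep)
    if (!length(rows)) return(NA_real_)
    ex <- lapply(rows, function(i) eeg[grid$start_sample[i]:grid$stop_sample[i]])
    cx <- lapply(rows, function(i) ecg[grid$start_sample[i]:grid$stop_sample[i]])
  }
  coh <- welch_coherence(ex, cx, rate = rate)
  mean(coh$coherence[coh$freq >= 12 & coh$freq <= 15])
}

#' Full cardiac-interference correction for a recording
#'
#' Detects R peaks, drops retained epochs with implausible heart rate
#' (adding reason `heart_rate` to the mask), builds the per-channel
#' QRS-locked signature from the remaining N2 sleep and subtracts it.
#' Recordings without ECG pass through unchanged with
#' `corrected = FALSE`.
#'
#' @param recording A [psg_recording()] including an `ECG` channel at 128 Hz.
#' @param mask Epoch mask from [qc_epochs()].
#' @param grid Epoch grid.
#' @param channels EEG channels to correct.
#' @param config Configuration list ([spindle_config()]).
#' @return A list: `recording` (corrected), `mask` (with heart-rate drops),
#'   `peaks`, `signatures`, `corrected` (logical).
#' @export
ecg_correct <- function(recording, mask, grid, channels = c("C3", "C4"),
                        config = spindle_config()) {
  channels <- intersect(channels, names(recording$signals))
  if (!("ECG" %in% names(recording$signals))) {
    return(list(recording = recording, mask = mask, peaks = numeric(0),
                signatures = NULL, corrected = FALSE))
  }
  rate <- attr(grid, "rate")
  peaks <- detect_r_peaks(recording$signals$ECG, rate)
  hr <- heart_rate_by_epoch(peaks, nrow(mask))
  mask <- .mask_drop(mask, heart_rate_epoch_filter(hr, config$ecg$hr_min,
                                                   config$ecg$hr_max),
                     "heart_rate")
  n <- min(lengths(recording$signals[channels]))
  keep <- sample_mask(mask, grid, n)
  sigs <- list()
  corrected <- FALSE
  for (ch in channels) {
    sig <- build_signature(recording$signals[[ch]], peaks, keep, rate,
                           window_s = config$ecg$window_s,
                           pre_s = config$ecg$pre_s,
                           min_peaks = config$ecg$min_peaks)
    sigs[[ch]] <- sig
    if (!is.null(sig)) {
      recording$signals[[ch]] <-
        subtract_signature(recording$signals[[ch]], peaks, sig, rate)
      corrected <- TRUE
    }
  }
  list(recording = recording, mask = mask, peaks = peaks,
       signatures = sigs, corrected = corrected)
}
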