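# Spindle detection and characterization: thresholding of the smoothed
# wavelet magnitude, event merging, per-spindle properties, the alternative
# band-pass/RMS detector, the frequency sweep with cross-frequency merging,
# dispersion-index QC, bilateral matching and per-recording summaries.

.runs_of <- function(flag) {
  r <- rle(flag)
  stop_ <- cumsum(r$lengths)
  start_ <- stop_ - r$lengths + 1L
  tibble(start = start_[r$values], stop = stop_[r$values])
}

# union-merge overlapping/adjacent sample intervals
.union_intervals <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$start), ]
  out_s <- ev$start[1]; out_e <- ev$stop[1]
  res_s <- res_e <- integer(0)
  for (i in 2:nrow(ev)) {
    if (ev$start[i] <= out_e + 1L) {
      out_e <- max(out_e, ev$stop[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- ev$start[i]; out_e <- ev$stop[i]
    }
  }
  tibble(start = c(res_s, out_s), stop = c(res_e, out_e))
}

#' Detect spindles from a smoothed wavelet magnitude series
#'
#' Computes the adaptive detection statistic `x = smoothed / baseline` and
#' applies the threshold rules. In the standard variant, runs of samples
#' with `x > th` (default 4.5) lasting 0.3-3.0 s form putative cores; each
#' core is extended outward while `x > th2` (default 2) and the extended
#' event must last at least 0.5 s. The sensitivity variants replace the
#' core rule: `T_L` flags `1 < x < 2` and `T_A` flags `x > 1`, both without
#' a separate extension threshold. Events closer than 1 s are merged when
#' the merged event stays under 3.0 s. Events not wholly inside retained
#' epochs are discarded.
#'
#' @param smoothed Smoothed magnitude series ([smooth_and_baseline()]).
#' @param baseline Individual/channel baseline mean.
#' @param rate Sampling rate (Hz).
#' @param keep Logical retained-sample mask (or NULL).
#' @param variant `"standard"`, `"TL"` or `"TA"`.
#' @param config Configuration list ([spindle_config()]); the `spindle`
#'   section supplies thresholds and duration rules.
#' @return Tibble of events: `start_s`, `stop_s` (half-open), `duration`.
#' @export
detect_spindles <- function(smoothed, baseline, rate = 128, keep = NULL,
                            variant = c("standard", "TL", "TA"),
                            config = spindle_config()) {
  variant <- match.arg(variant)
  stopifnot(baseline > 0)
  p <- config$spindle
  x <- smoothed / baseline
  core_flag <- switch(variant,
    standard = x > p$th,
    TL = x > 1 & x < 2,
    TA = x > 1
  )
  core_flag[is.na(core_flag)] <- FALSE
  runs <- .runs_of(core_flag)
  if (nrow(runs)) {
    dur <- (runs$stop - runs$start + 1L) / rate
    runs <- runs[dur >= p$dur_min & dur <= p$dur_max, , drop = FALSE]
  }
  if (!nrow(runs)) {
    return(tibble(start_s = numeric(), stop_s = numeric(), duration = numeric()))
  }

  if (variant == "standard" && is.finite(p$th2)) {
    ext_flag <- !is.na(x) & x > p$th2
    n <- length(x)
    for (i in seq_len(nrow(runs))) {
      a <- runs$start[i]; b <- runs$stop[i]
      while (a > 1L && ext_flag[a - 1L]) a <- a - 1L
      while (b < n && ext_flag[b + 1L]) b <- b + 1L
      runs$start[i] <- a; runs$stop[i] <- b
    }
    runs <- .union_intervals(runs)
  }
  runs <- runs[(runs$stop - runs$start + 1L) / rate >= p$min_total, , drop = FALSE]

  # gap merge: events within merge_gap of each other, capped at dur_max
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      gap <- (runs$start[i] - merged$stop[last] - 1L) / rate
      span <- (runs$stop[i] - merged$start[last] + 1L) / rate
      if (gap < p$merge_gap && span < p$dur_max) {
        merged$stop[last] <- runs$stop[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
    runs <- merged
  }

  if (!is.null(keep)) {
    inside <- vapply(seq_len(nrow(runs)), function(i) {
      all(keep[runs$start[i]:runs$stop[i]])
    }, TRUE)
    runs <- runs[inside, , drop = FALSE]
  }
  tibble(start_s = (runs$start - 1) / rate,
         stop_s = runs$stop / rate,
         duration = (runs$stop - runs$start + 1L) / rate)
}

#' Zero-phase sigma band-pass used for property extraction
#'
#' Fourier-domain band-pass with unit passband gain and raised-cosine
#' transition edges (`trans` Hz wide), so in-band amplitudes - which feed
#' the peak-to-peak spindle amplitude - are not attenuated and the filter
#' has exactly zero phase.
#'
#' @param x Signal.
#' @param rate Sampling rate (Hz).
#' @param band Two-element band in Hz (default 11-15).
#' @param trans Transition width in Hz (default 1).
#' @return Filtered signal.
#' @export
sigma_bandpass <- function(x, rate = 128, band = c(11, 15), trans = 1) {
  n <- length(x)
  X <- fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * rate / n  # two-sided frequency axis
  g <- numeric(n)
  g[f >= band[1] & f <= band[2]] <- 1
  lo <- f >= band[1] - trans & f < band[1]
  hi <- f > band[2] & f <= band[2] + trans
  g[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / trans))
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / trans))
  Re(fft(X * g, inverse = TRUE)) / n
}

#' Extract per-spindle properties
#'
#' On the 11-15 Hz filtered signal within each event interval: amplitude is
#' the largest peak-to-peak difference between adjacent extrema (uV);
#' frequency is the modal frequency of the zero-padded spectrum (0.25 Hz
#' grid, parabolic peak interpolation); the oscillation count is
#' `floor((peaks + troughs) / 2)`; symmetry locates the maximum
#' peak-to-peak change relative to the start (0) and end (1) of the event.
#'
#' @param events Event tibble from [detect_spindles()].
#' @param raw_signal The (corrected) EEG signal, unfiltered by the sigma band.
#' @param rate Sampling rate (Hz).
#' @param band Property extraction band (Hz).
#' @return `events` with `amplitude`, `frequency`, `n_oscillations`,
#'   `symmetry`, `low_confidence` columns added.
#' @export
spindle_properties <- function(events, raw_signal, rate = 128, band = c(11, 15)) {
  if (!nrow(events)) {
    return(dplyr::mutate(events, amplitude = numeric(0), frequency = numeric(0),
                         n_oscillations = integer(0), symmetry = numeric(0),
                         low_confidence = logical(0)))
  }
  filt <- sigma_bandpass(raw_signal, rate, band)
  nfft <- as.integer(round(rate / 0.25))
  props <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    a <- as.integer(round(events$start_s[i] * rate)) + 1L
    b <- as.integer(round(events$stop_s[i] * rate))
    seg <- filt[a:b]
    m <- length(seg)
    d <- diff(seg)
    ext <- which(d[-1] * d[-length(d)] < 0) + 1L  # interior extrema
    n_peaks <- sum(d[ext - 1L] > 0)
    n_troughs <- length(ext) - n_peaks
    if (length(ext) >= 2) {
      p2p <- abs(diff(seg[ext]))
      j <- which.max(p2p)
      amplitude <- p2p[j]
      symmetry <- ((ext[j] + ext[j + 1L]) / 2 - 1) / max(m - 1, 1)
    } else {
      amplitude <- max(seg) - min(seg)
      symmetry <- NA_real_
    }
    pad <- max(nfft, 2^ceiling(log2(m)))
    spec <- Mod(fft(c(seg - mean(seg), rep(0, pad - m))))[seq_len(pad %/% 2 + 1)]^2
    fgrid <- (seq_along(spec) - 1) * rate / pad
    inb <- which(fgrid >= band[1] - 1 & fgrid <= band[2] + 1)
    k <- inb[which.max(spec[inb])]
    freq <- fgrid[k]
    if (k > 1 && k < length(spec)) {  # parabolic interpolation on log power
      y <- log(pmax(spec[(k - 1):(k + 1)], .Machine$double.xmin))
      denom <- y[1] - 2 * y[2] + y[3]
      if (is.finite(denom) && denom < 0) {
        freq <- freq + 0.5 * (y[1] - y[3]) / denom * (rate / pad)
      }
    }
    tibble(amplitude = amplitude, frequency = freq,
           n_oscillations = as.integer(floor((n_peaks + n_troughs) / 2)),
           symmetry = symmetry,
           low_confidence = length(ext) < 3)
  })
  dplyr::bind_cols(events, props)
}

#' Wavelet spindle detection for one channel, end to end
#'
#' Convenience wrapper: wavelet transform, smoothing, baseline, detection
#' and property extraction for a single channel and centre frequency.
#'
#' @param signal Band-passed EEG at `rate` Hz.
#' @param keep Logical retained-sample mask.
#' @param rate Sampling rate (Hz).
#' @param spec A [wavelet_spec()].
#' @param variant Threshold variant (see [detect_spindles()]).
#' @param config Configuration list.
#' @return Event tibble with properties and an `fc` column.
#' @export
detect_channel_spindles <- function(signal, keep = NULL, rate = 128,
                                    spec = wavelet_spec(), variant = "standard",
                                    config = spindle_config()) {
  mag <- cmor_magnitude(signal, spec, rate)
  sb <- smooth_and_baseline(mag, keep, rate, config$spindle$smooth_s)
  ev <- detect_spindles(sb$smoothed, sb$baseline, rate, keep,
                        variant = variant, config = config)
  band <- config$spindle$prop_band
  if (spec$fc < band[1] || spec$fc > band[2]) band <- spec$fc + c(-2, 2)
  ev <- spindle_properties(ev, signal, rate, band)
  ev$fc <- rep(spec$fc, nrow(ev))
  ev
}

#' Band-pass/RMS spindle detector
#'
#' The alternative detector: 11-15 Hz band-pass, root-mean-square in
#' non-overlapping 0.25-s windows, flagging windows above the individual's
#' 95th percentile (computed over retained N2 windows), then forming events
#' from runs of consecutive flagged windows lasting 0.3-3.0 s, with the
#' same gap-merge rule as the wavelet detector.
#'
#' @param signal EEG at `rate` Hz.
#' @param keep Logical retained-sample mask.
#' @param rate Sampling rate (Hz).
#' @param band Band in Hz (default 11-15).
#' @param percentile Flagging quantile (default 0.95).
#' @param config Configuration list.
#' @return Event tibble: `start_s`, `stop_s`, `duration`.
#' @export
rms_detector <- function(signal, keep = NULL, rate = 128, band = c(11, 15),
                         percentile = 0.95, config = spindle_config()) {
  p <- config$spindle
  filt <- sigma_bandpass(signal, rate, band)
  w <- as.integer(round(0.25 * rate))
  nw <- length(filt) %/% w
  if (is.null(keep)) keep <- rep(TRUE, length(filt))
  win_start <- (seq_len(nw) - 1L) * w + 1L
  rms <- vapply(win_start, function(s) sqrt(mean(filt[s:(s + w - 1L)]^2)), 0)
  win_keep <- vapply(win_start, function(s) all(keep[s:(s + w - 1L)]), TRUE)
  if (!any(win_keep)) return(tibble(start_s = numeric(), stop_s = numeric(),
                                    duration = numeric()))
  thr <- quantile(rms[win_keep], percentile, names = FALSE)
  flag <- win_keep & rms > thr
  runs <- .runs_of(flag)
  if (nrow(runs)) {
    dur <- (runs$stop - runs$start + 1L) * 0.25
    runs <- runs[dur >= p$dur_min & dur <= p$dur_max, , drop = FALSE]
  }
  if (!nrow(runs)) return(tibble(start_s = numeric(), stop_s = numeric(),
                                 duration = numeric()))
  ev <- tibble(start = (runs$start - 1L) * w + 1L, stop = runs$stop * w)
  if (nrow(ev) > 1) {
    merged <- ev[1, ]
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      gap <- (ev$start[i] - merged$stop[last] - 1L) / rate
      span <- (ev$stop[i] - merged$start[last] + 1L) / rate
      if (gap < p$merge_gap && span < p$dur_max) {
        merged$stop[last] <- ev$stop[i]
      } else {
        merged <- dplyr::bind_rows(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  tibble(start_s = (ev$start - 1) / rate, stop_s = ev$stop / rate,
         duration = (ev$stop - ev$start + 1L) / rate)
}

#' Sweep the wavelet centre frequency
#'
#' Repeats detection for `F_C` from 8 to 18 Hz in 0.25 Hz steps with a
#' 12-cycle wavelet (narrower bandwidth than the canonical 7 cycles).
#' `F_C = 11` targets slow and `F_C = 15` fast spindles.
#'
#' @param signal Band-passed EEG.
#' @param keep Retained-sample mask.
#' @param rate Sampling rate (Hz).
#' @param mask Epoch mask tibble (for the density denominator).
#' @param config Configuration list; `sweep` section controls the grid.
#' @return Tibble with one row per `fc`: `fc`, `n_events`, `density`
#'   (events per retained N2 minute) and `events` (list column).
#' @export
frequency_sweep <- function(signal, keep, rate = 128, mask, config = spindle_config()) {
  minutes <- sum(mask$keep) * 0.5
  purrr::map_dfr(config$sweep$fc_grid, function(fc) {
    ev <- detect_channel_spindles(signal, keep, rate,
                                  wavelet_spec(fc, config$sweep$n_cycles),
                                  config = config)
    tibble(fc = fc, n_events = nrow(ev),
           density = if (minutes > 0) nrow(ev) / minutes else NA_real_,
           events = list(ev))
  })
}

#' Merge spindles detected at different centre frequencies
#'
#' Two same-channel events merge when (a) their intersection exceeds 50% of
#' their union, or (b) more than 80% of either one is overlapped by the
#' other. The merge relation is closed transitively; each merged event
#' spans the union of its members. Counts of merged events estimate the
#' total spindle density across frequencies.
#'
#' @param events Tibble with `start_s`, `stop_s` and (optionally) `fc`.
#' @return Tibble of unique events: `start_s`, `stop_s`, `duration`,
#'   `n_members`, `fc_min`, `fc_max`.
#' @export
merge_across_frequencies <- function(events) {
  n <- nrow(events)
  if (!("fc" %in% names(events))) events$fc <- NA_real_
  if (n == 0) {
    return(tibble(start_s = numeric(), stop_s = numeric(), duration = numeric(),
                  n_members = integer(), fc_min = numeric(), fc_max = numeric()))
  }
  ev <- events[order(events$start_s), ]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  len <- ev$stop_s - ev$start_s
  for (i in seq_len(n - 1)) {
    j <- i + 1L
    while (j <= n && ev$start_s[j] < max(ev$stop_s[i:j])) {
      inter <- max(0, min(ev$stop_s[i], ev$stop_s[j]) - max(ev$start_s[i], ev$start_s[j]))
      if (inter > 0) {
        uni <- len[i] + len[j] - inter
        if (inter > 0.5 * uni || inter > 0.8 * len[i] || inter > 0.8 * len[j]) {
          parent[find(i)] <- find(j)
        }
      }
      j <- j + 1L
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- dplyr::group_by(dplyr::mutate(ev, .comp = comp), .data$.comp)
  out <- dplyr::summarise(out,
    start_s = min(.data$start_s), stop_s = max(.data$stop_s),
    n_members = dplyr::n(),
    fc_min = suppressWarnings(min(.data$fc, na.rm = TRUE)),
    fc_max = suppressWarnings(max(.data$fc, na.rm = TRUE)),
    .groups = "drop")
  out$duration <- out$stop_s - out$start_s
  out$fc_min[!is.finite(out$fc_min)] <- NA_real_
  out$fc_max[!is.finite(out$fc_max)] <- NA_real_
  dplyr::arrange(out[, c("start_s", "stop_s", "duration", "n_members",
                         "fc_min", "fc_max")], .data$start_s)
}

#' Match detected events against ground-truth events
#'
#' An event pair matches when their intervals overlap (or, failing that,
#' onsets lie within `tol` seconds). Recall is the fraction of truth
#' events matched by at least one detection; precision the fraction of
#' detections matching at least one truth event. A single detection may
#' cover two gap-merged truth events.
#'
#' @param detected Tibble with `start_s`, `stop_s`.
#' @param truth Tibble with `start_s` and `duration` (or `stop_s`).
#' @param tol Onset tolerance fallback in seconds (default 0.5).
#' @return A list: `recall`, `precision`, `truth_matched` (logical),
#'   `det_matched` (logical).
#' @export
match_events <- function(detected, truth, tol = 0.5) {
  if (!("stop_s" %in% names(truth))) truth$stop_s <- truth$start_s + truth$duration
  hit_t <- vapply(seq_len(nrow(truth)), function(i) {
    any(detected$start_s < truth$stop_s[i] & detected$stop_s > truth$start_s[i]) ||
      any(abs(detected$start_s - truth$start_s[i]) <= tol)
  }, TRUE)
  hit_d <- vapply(seq_len(nrow(detected)), function(i) {
    any(truth$start_s < detected$stop_s[i] & truth$stop_s > detected$start_s[i]) ||
      any(abs(truth$start_s - detected$start_s[i]) <= tol)
  }, TRUE)
  list(recall = if (nrow(truth)) mean(hit_t) else NA_real_,
       precision = if (nrow(detected)) mean(hit_d) else NA_real_,
       truth_matched = hit_t, det_matched = hit_d)
}

#' Poisson dispersion index of per-epoch spindle counts
#'
#' Heterogeneous mixtures of epochs with clustered spurious detections show
#' as overdispersion relative to the Poisson expectation of 1.0. The index
#' is the sample variance over the mean; the overdispersion test refers
#' `(n - 1) * DI` to the upper tail of a chi-squared distribution with
#' `n - 1` degrees of freedom. Channels with `DI > di_max` (default 2.0)
#' fail QC.
#'
#' @param counts Integer vector of per-epoch spindle counts.
#' @param di_max QC threshold on the dispersion index.
#' @return A list: `di`, `p`, `qc_pass`, `n`.
#' @export
dispersion_index <- function(counts, di_max = 2.0) {
  n <- length(counts)
  if (n < 10 || mean(counts) == 0) {
    return(list(di = NA_real_, p = NA_real_, qc_pass = FALSE, n = n))
  }
  di <- var(counts) / mean(counts)
  p <- pchisq((n - 1) * di, df = n - 1, lower.tail = FALSE)
  list(di = di, p = p, qc_pass = di <= di_max, n = n)
}

#' Match spindles bilaterally between C3 and C4
#'
#' Greedy one-to-one matching by onset proximity: candidate pairs with
#' onsets within `tol` seconds are accepted in order of increasing onset
#' difference, each event used at most once.
#'
#' @param events_c3,events_c4 Event tibbles (with `start_s`).
#' @param tol Onset tolerance in seconds (default 0.5).
#' @return A list: `pairs` (tibble of matched indices and `delta`),
#'   `frac_c3`, `frac_c4` (fraction of each channel's events matched).
#' @export
bilateral_match <- function(events_c3, events_c4, tol = 0.5) {
  n3 <- nrow(events_c3); n4 <- nrow(events_c4)
  if (n3 == 0 || n4 == 0) {
    return(list(pairs = tibble(i3 = integer(), i4 = integer(), delta = numeric()),
                frac_c3 = if (n3) 0 else NA_real_,
                frac_c4 = if (n4) 0 else NA_real_))
  }
  cand <- tidyr::expand_grid(i3 = seq_len(n3), i4 = seq_len(n4))
  cand$delta <- abs(events_c3$start_s[cand$i3] - events_c4$start_s[cand$i4])
  cand <- cand[cand$delta <= tol, ]
  cand <- cand[order(cand$delta), ]
  used3 <- logical(n3); used4 <- logical(n4)
  sel <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used3[cand$i3[r]] && !used4[cand$i4[r]]) {
      sel[r] <- TRUE
      used3[cand$i3[r]] <- TRUE
      used4[cand$i4[r]] <- TRUE
    }
  }
  pairs <- cand[sel, ]
  list(pairs = pairs, frac_c3 = sum(used3) / n3, frac_c4 = sum(used4) / n4)
}

#' Summarize detected spindles for one channel
#'
#' Density is events per minute of retained N2 (equivalently, twice the
#' mean per-30-s-epoch count); property means are over events; the
#' per-epoch count vector (events assigned by onset) feeds the dispersion
#' QC.
#'
#' @param events Event tibble with properties.
#' @param mask Epoch mask tibble.
#' @param min_epochs Minimum retained epochs for a usable summary.
#' @param di_max Dispersion-index QC threshold.
#' @return One-row tibble: `n_events`, `minutes`, `density`, property
#'   means, `di`, `di_p`, `qc_pass`, `enough_data`, plus the count vector
#'   as attribute `epoch_counts`.
#' @export
summarize_spindles <- function(events, mask, min_epochs = 10, di_max = 2.0) {
  ret <- which(mask$keep)
  minutes <- length(ret) * 0.5
  counts <- vapply(ret, function(i) {
    e <- mask$epoch[i]
    sum(events$start_s >= e * 30 & events$start_s < (e + 1) * 30)
  }, 0L)
  dsp <- dispersion_index(counts, di_max)
  mprop <- function(col) {
    if (nrow(events) && col %in% names(events)) mean(events[[col]], na.rm = TRUE) else NA_real_
  }
  out <- tibble(
    n_events = nrow(events), minutes = minutes,
    density = if (minutes > 0) nrow(events) / minutes else NA_real_,
    mean_amplitude = mprop("amplitude"), mean_duration = mprop("duration"),
    mean_frequency = mprop("frequency"),
    mean_oscillations = mprop("n_oscillations"), mean_symmetry = mprop("symmetry"),
    di = dsp$di, di_p = dsp$p, qc_pass = dsp$qc_pass,
    enough_data = length(ret) >= min_epochs
  )
  attr(out, "epoch_counts") <- counts
  out
}
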