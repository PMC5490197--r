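# Epoch-level quality control for N2 analyses. Filters are applied in a
# fixed order - stage/annotation, spectral aberrance (Buckelmueller-style
# delta/beta ratios), iterative Hjorth/RMS outlier removal, clipping - and
# every removal carries a reason code so the mask is auditable. Epochs
# flagged on either EEG channel are removed from both, so all downstream
# analyses share one epoch set.

.mask_drop <- function(mask, idx, reason) {
  idx <- idx & mask$keep
  mask$keep[idx] <- FALSE
  mask$reason[idx] <- ifelse(mask$reason[idx] == "", reason,
                             paste(mask$reason[idx], reason, sep = ","))
  mask
}

#' Retain N2 epochs free of scored events
#'
#' Keeps epochs whose stage matches `stage` and which are not intersected by
#' any arousal, movement or artifact annotation. An entire 30-s epoch is
#' removed even if the event covers only a fraction of a second of it.
#'
#' @param grid Epoch grid from [build_epoch_grid()].
#' @param annotations An [annotation_set()].
#' @param stage Stage to retain (default `"N2"`).
#' @return An epoch mask tibble: `epoch`, `stage`, `keep`, `reason`.
#' @export
mask_by_stage_and_events <- function(grid, annotations, stage = "N2") {
  mask <- tibble(epoch = grid$epoch, stage = grid$stage,
                 keep = TRUE, reason = "")
  mask <- .mask_drop(mask, mask$stage != stage, "stage")
  ev <- annotations$events
  if (nrow(ev)) {
    e_start <- grid$epoch * 30
    e_stop <- e_start + 30
    hit <- vapply(seq_len(nrow(mask)), function(i) {
      any(ev$start < e_stop[i] & (ev$start + ev$duration) > e_start[i])
    }, TRUE)
    mask <- .mask_drop(mask, hit, "annotation")
  }
  mask
}

#' Spectral aberrance filter on per-epoch delta and beta power
#'
#' Compares each epoch's delta (1-4 Hz) and beta (15-30 Hz) Welch power to a
#' local average over up to 15 contiguous epochs (7 either side, index epoch
#' included; boundary epochs use the neighbours that exist). An epoch is
#' excluded when delta exceeds `delta_ratio` (default 2.5) times, or beta
#' `beta_ratio` (default 2.0) times, its local average.
#'
#' @param delta,beta Per-epoch band power vectors (same length).
#' @param delta_ratio,beta_ratio Exclusion ratios.
#' @return Logical exclusion vector.
#' @export
buckelmueller_filter <- function(delta, beta, delta_ratio = 2.5, beta_ratio = 2.0) {
  n <- length(delta)
  stopifnot(length(beta) == n)
  if (n < 2) {
    warning("fewer than 2 epochs; spectral aberrance filter skipped")
    return(rep(FALSE, n))
  }
  local_mean <- function(v) {
    vapply(seq_len(n), function(i) {
      w <- max(1L, i - 7L):min(n, i + 7L)
      mean(v[w])
    }, 0)
  }
  delta > delta_ratio * local_mean(delta) | beta > beta_ratio * local_mean(beta)
}

#' Hjorth parameters and RMS of one epoch
#'
#' Activity is the signal variance (uV^2); mobility is
#' `sqrt(var(diff(x))/var(x))`; complexity is the mobility of the first
#' difference divided by the mobility of the signal. Derivatives are plain
#' first differences without rate scaling: the two ratio parameters are used
#' as relative outlier metrics, for which the scaling cancels.
#'
#' @param x Numeric epoch signal.
#' @return A list with `activity`, `mobility`, `complexity`, `rms` and
#'   `degenerate` (TRUE for constant input, where the ratios are undefined).
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  v0 <- var(x)
  if (v0 == 0) {
    return(list(activity = 0, mobility = NA_real_, complexity = NA_real_,
                rms = sqrt(mean(x^2)), degenerate = TRUE))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- var(d1)
  v2 <- var(d2)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob,
       complexity = if (v1 > 0) sqrt(v2 / v1) / mob else NA_real_,
       rms = sqrt(mean(x^2)), degenerate = FALSE)
}

#' Iterative +/-2 SD outlier filter over per-epoch metrics
#'
#' Drops any epoch whose value on any metric column lies beyond
#' `mean +/- k * SD`, with mean and SD recomputed on the surviving epochs at
#' each of `iterations` passes. Columns with zero SD in a pass exclude
#' nothing on that pass. Iteration stops early (with a flag) if fewer than
#' `min_epochs` survivors remain.
#'
#' @param metrics Numeric matrix or data frame, epochs x metrics (e.g. RMS
#'   and the three Hjorth parameters for each channel).
#' @param k SD multiplier (default 2).
#' @param iterations Number of passes (default 3).
#' @param min_epochs Minimum survivors to continue (default 10).
#' @return A list: `drop` (logical per epoch), `flagged` (TRUE if iteration
#'   stopped early), `iterations_run`.
#' @export
iterative_sd_filter <- function(metrics, k = 2, iterations = 3, min_epochs = 10) {
  m <- as.matrix(metrics)
  n <- nrow(m)
  alive <- rep(TRUE, n)
  flagged <- FALSE
  it <- 0L
  for (pass in seq_len(iterations)) {
    if (sum(alive) < min_epochs) { flagged <- TRUE; break }
    it <- pass
    bad <- rep(FALSE, n)
    for (j in seq_len(ncol(m))) {
      v <- m[alive, j]
      mu <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      bad <- bad | (alive & (is.na(m[, j]) | abs(m[, j] - mu) > k * s))
    }
    # undefined metrics (e.g. degenerate epochs) always drop
    bad <- bad | (alive & rowSums(is.na(m)) > 0)
    if (!any(bad)) next
    alive[bad] <- FALSE
  }
  list(drop = !alive, flagged = flagged, iterations_run = it)
}

#' Detect clipped (saturated) epochs
#'
#' Flags an epoch when more than `frac` of its sample points are tied at the
#' epoch minimum or maximum. Ties are exact equality on the stored
#' (EDF-quantized) values, which is how amplifier saturation manifests.
#'
#' @param x Numeric epoch signal.
#' @param frac Tied-sample fraction threshold (default 0.05).
#' @return Logical flag.
#' @export
clipped_epoch_detector <- function(x, frac = 0.05) {
  r <- range(x)
  if (r[1] == r[2]) return(TRUE)
  (sum(x == r[1]) + sum(x == r[2])) / length(x) > frac
}

#' Run the full epoch QC cascade for the EEG channels
#'
#' Applies, in order: stage/annotation mask, the delta/beta spectral
#' aberrance filter, the iterative +/-2 SD filter on RMS + Hjorth metrics
#' (both channels jointly, recomputed each pass), and clipping detection.
#' An epoch flagged on either channel is removed for both.
#'
#' @param recording A [psg_recording()] with EEG channels at 128 Hz.
#' @param grid Epoch grid from [build_epoch_grid()].
#' @param annotations An [annotation_set()].
#' @param channels EEG channel names (default `c("C3", "C4")`, intersected
#'   with what the recording has).
#' @param config Configuration list, see [spindle_config()].
#' @return The epoch mask tibble with per-channel metric columns attached.
#' @export
qc_epochs <- function(recording, grid, annotations,
                      channels = c("C3", "C4"), config = spindle_config()) {
  channels <- intersect(channels, names(recording$signals))
  stopifnot(length(channels) >= 1)
  rate <- attr(grid, "rate")
  mask <- mask_by_stage_and_events(grid, annotations, stage = config$qc$stage)

  epoch_slices <- function(ch, rows) {
    x <- recording$signals[[ch]]
    lapply(rows, function(i) x[grid$start_sample[i]:grid$stop_sample[i]])
  }

  # -- spectral aberrance on retained epochs, per channel, OR-combined
  ret <- which(mask$keep)
  if (length(ret) >= 2) {
    for (ch in channels) {
      sl <- epoch_slices(ch, ret)
      pw <- vapply(sl, function(e) {
        sp <- welch_psd(e, rate = rate, window_s = config$qc$welch_window_s,
                        overlap = config$qc$welch_overlap)
        df <- diff(sp$freq[1:2])
        c(delta = sum(sp$psd[sp$freq >= 1 & sp$freq < 4]) * df,
          beta = sum(sp$psd[sp$freq >= 15 & sp$freq < 30]) * df)
      }, c(delta = 0, beta = 0))
      excl <- buckelmueller_filter(pw["delta", ], pw["beta", ],
                                   config$qc$delta_ratio, config$qc$beta_ratio)
      drop_idx <- rep(FALSE, nrow(mask))
      drop_idx[ret[excl]] <- TRUE
      mask <- .mask_drop(mask, drop_idx, "buckelmueller")
    }
  }

  # -- iterative SD filter on RMS + Hjorth, all channels jointly
  ret <- which(mask$keep)
  if (length(ret)) {
    met <- do.call(cbind, lapply(channels, function(ch) {
      sl <- epoch_slices(ch, ret)
      t(vapply(sl, function(e) {
        h <- hjorth_params(e)
        c(rms = h$rms, activity = h$activity,
          mobility = h$mobility, complexity = h$complexity)
      }, c(rms = 0, activity = 0, mobility = 0, complexity = 0)))
    }))
    res <- iterative_sd_filter(met, k = config$qc$sd_k,
                               iterations = config$qc$sd_iterations)
    drop_idx <- rep(FALSE, nrow(mask))
    drop_idx[ret[res$drop]] <- TRUE
    mask <- .mask_drop(mask, drop_idx, "hjorth_iter")
    attr(mask, "sd_filter_flagged") <- res$flagged
  }

  # -- clipping
  ret <- which(mask$keep)
  if (length(ret)) {
    for (ch in channels) {
      sl <- epoch_slices(ch, ret)
      clip <- vapply(sl, clipped_epoch_detector, TRUE,
                     frac = config$qc$clip_fraction)
      drop_idx <- rep(FALSE, nrow(mask))
      drop_idx[ret[clip]] <- TRUE
      mask <- .mask_drop(mask, drop_idx, "clipped")
    }
  }
  mask
}

#' Sample-level keep mask from an epoch mask
#'
#' @param mask Epoch mask tibble.
#' @param grid Epoch grid.
#' @param n Total signal length in samples.
#' @return Logical vector of length `n`, TRUE inside retained epochs.
#' @export
sample_mask <- function(mask, grid, n) {
  keep <- rep(FALSE, n)
  for (i in which(mask$keep)) {
    keep[grid$start_sample[i]:min(grid$stop_sample[i], n)] <- TRUE
  }
  keep
}
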