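# End-to-end per-recording analysis: QC, cardiac correction, spindle
# detection on both channels, band power, coherence and the hypnogram
# context, bundled in a `spindle_analysis` object with broom-style
# accessors.

#' Run the full spindle characterization pipeline on one recording
#'
#' Band-passes the EEG (0.3-35 Hz), builds the 30-s epoch grid aligned to
#' the annotations, applies the epoch QC cascade, corrects cardiac
#' interference when an ECG channel is present, detects spindles with the
#' Morlet wavelet detector on each EEG channel, extracts per-spindle
#' properties, and computes Welch band power, sigma EEG/ECG coherence and
#' per-channel summaries with dispersion QC.
#'
#' @param recording A [psg_recording()]; channels are resampled to 128 Hz
#'   if needed.
#' @param annotations An [annotation_set()].
#' @param channels EEG channels (default `c("C3", "C4")`).
#' @param config Configuration list ([spindle_config()]).
#' @param ecg_correction Apply cardiac correction when possible (default
#'   TRUE).
#' @return A `spindle_analysis` object: list with `events` (tibble over
#'   channels), `summary` (per-channel tibble), `mask`, `grid`,
#'   `band_power`, `coherence`, `bilateral`, `context`, `corrected`.
#' @export
spindle_analysis <- function(recording, annotations, channels = c("C3", "C4"),
                             config = spindle_config(), ecg_correction = TRUE) {
  rate <- 128
  for (ch in names(recording$signals)) {
    r <- recording$rates[match(ch, names(recording$signals))]
    if (r != rate) {
      recording$signals[[ch]] <- resample_to(recording$signals[[ch]], r, rate)
    }
  }
  recording$rates <- rep(rate, length(recording$signals))
  channels <- intersect(channels, names(recording$signals))
  for (ch in channels) {
    recording$signals[[ch]] <- bandpass_eeg(recording$signals[[ch]], rate)
  }
  grid <- build_epoch_grid(recording, annotations, rate)
  mask <- qc_epochs(recording, grid, annotations, channels, config)

  corrected <- FALSE
  coh_pre <- coh_post <- NA_real_
  if (ecg_correction && "ECG" %in% names(recording$signals)) {
    coh_pre <- sigma_coherence(recording$signals[[channels[1]]],
                               recording$signals$ECG, mask, grid, rate)
    cc <- ecg_correct(recording, mask, grid, channels, config)
    recording <- cc$recording
    mask <- cc$mask
    corrected <- cc$corrected
    coh_post <- sigma_coherence(recording$signals[[channels[1]]],
                                recording$signals$ECG, mask, grid, rate)
  }

  n <- min(lengths(recording$signals[channels]))
  keep <- sample_mask(mask, grid, n)
  spec <- wavelet_spec(config$spindle$fc, config$spindle$n_cycles)
  events <- purrr::map_dfr(channels, function(ch) {
    ev <- detect_channel_spindles(recording$signals[[ch]], keep, rate, spec,
                                  config = config)
    ev$channel <- rep(ch, nrow(ev))
    ev
  })
  summary <- purrr::map_dfr(channels, function(ch) {
    sm <- summarize_spindles(events[events$channel == ch, ], mask,
                             config$aggregate$min_epochs,
                             config$spindle$di_max)
    dplyr::bind_cols(tibble(channel = ch), sm)
  })
  ret_rows <- which(mask$keep)
  bp <- purrr::map_dfr(channels, function(ch) {
    if (!length(ret_rows)) return(tibble())
    sl <- lapply(ret_rows, function(i) {
      recording$signals[[ch]][grid$start_sample[i]:grid$stop_sample[i]]
    })
    dplyr::bind_cols(tibble(channel = ch),
                     band_power(welch_psd(sl, rate,
                                          config$spectral$window_s,
                                          config$spectral$overlap)))
  })
  bil <- if (length(channels) >= 2) {
    bilateral_match(events[events$channel == channels[1], ],
                    events[events$channel == channels[2], ])
  } else NULL

  structure(list(
    events = events, summary = summary, mask = mask, grid = grid,
    band_power = bp, coherence = c(pre = coh_pre, post = coh_post),
    bilateral = bil, context = epoch_context(annotations$stages,
                                             recording$start_time),
    corrected = corrected, config = config, channels = channels
  ), class = "spindle_analysis")
}

#' @export
print.spindle_analysis <- function(x, ...) {
  cat("<spindle_analysis> ", paste(x$channels, collapse = "/"),
      "; ", sum(x$mask$keep), "/", nrow(x$mask), " epochs retained",
      if (x$corrected) "; ECG-corrected" else "", "\n", sep = "")
  print(x$summary[, c("channel", "n_events", "minutes", "density",
                      "mean_amplitude", "mean_frequency", "di", "qc_pass")])
  invisible(x)
}

#' Tidy the detected spindle events
#'
#' @param x A `spindle_analysis` object.
#' @param ... Unused.
#' @return Tibble of events (one row per spindle).
#' @export
tidy.spindle_analysis <- function(x, ...) {
  as_tibble(x$events)
}

#' One-row overview of a spindle analysis
#'
#' @param x A `spindle_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: retained minutes, channel-averaged density and
#'   amplitude, bilateral fraction, sigma coherence, QC status.
#' @export
glance.spindle_analysis <- function(x, ...) {
  tibble(
    n_epochs_retained = sum(x$mask$keep),
    minutes = sum(x$mask$keep) * 0.5,
    density = mean(x$summary$density, na.rm = TRUE),
    mean_amplitude = mean(x$summary$mean_amplitude, na.rm = TRUE),
    mean_frequency = mean(x$summary$mean_frequency, na.rm = TRUE),
    frac_bilateral = if (!is.null(x$bilateral)) {
      mean(c(x$bilateral$frac_c3, x$bilateral$frac_c4), na.rm = TRUE)
    } else NA_real_,
    sigma_coherence = unname(x$coherence["post"]),
    qc_pass = all(x$summary$qc_pass),
    ecg_corrected = x$corrected
  )
}

#' Plot a hypnogram with detected cycles
#'
#' @param object An [epoch_context()] tibble (or `spindle_analysis`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spindle_analysis <- function(object, ...) {
  ctx <- object$context
  lev <- c("N3", "N2", "N1", "R", "W")
  ctx$stage_f <- factor(ctx$stage, levels = lev)
  ev <- object$events
  p <- ggplot2::ggplot(ctx, ggplot2::aes(x = .data$epoch * 0.5,
                                         y = .data$stage_f, group = 1)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(x = "minutes", y = NULL,
                  title = "Hypnogram with detected spindles") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_rug(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(x = .data$start_s / 60), sides = "b", alpha = 0.4)
  }
  p
}

#' Plot the per-channel spindle density across the frequency sweep
#'
#' @param sweep Result of [frequency_sweep()] (optionally with a `channel`
#'   column when several are bound together).
#' @return A ggplot object.
#' @export
plot_frequency_sweep <- function(sweep) {
  aes <- if ("channel" %in% names(sweep)) {
    ggplot2::aes(x = .data$fc, y = .data$density, colour = .data$channel)
  } else {
    ggplot2::aes(x = .data$fc, y = .data$density)
  }
  ggplot2::ggplot(sweep, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(11, 15), linetype = 3) +
    ggplot2::labs(x = expression(F[C] ~ "(Hz)"),
                  y = "spindles / min N2",
                  title = "Spindle density by targeted frequency") +
    ggplot2::theme_minimal()
}
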