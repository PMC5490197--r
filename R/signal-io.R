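# Recording container, resampling, zero-phase band-pass and the 30-s epoch
# grid that aligns signals with the staged annotations.

#' Construct a PSG recording
#'
#' @param signals Named list of numeric sample vectors in microvolts.
#' @param rates Per-channel sampling rates in Hz (recycled).
#' @param start_time Clock time of the first sample, `"hh:mm:ss"`.
#' @return A `psg_recording` object.
#' @export
psg_recording <- function(signals, rates, start_time = NA_character_) {
  stopifnot(is.list(signals), !is.null(names(signals)))
  rates <- rep_len(as.numeric(rates), length(signals))
  if (any(rates <= 0)) stop("sampling rates must be positive")
  structure(list(signals = signals, rates = rates, start_time = start_time),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$signals), " channel(s): ",
      paste(sprintf("%s (%g Hz, %.1f min)", names(x$signals), x$rates,
                    lengths(x$signals) / x$rates / 60), collapse = ", "),
      "\n  start ", x$start_time, "\n", sep = "")
  invisible(x)
}

#' Read a polysomnogram: EDF signals plus stage/event annotations
#'
#' Loads the requested channels (through the 10-20 alias table), parses the
#' annotation file (NSRR-style XML or the two-column stage CSV dialect) and
#' collapses R&K NREM4 into N3. A missing ECG channel is tolerated with a
#' warning - downstream cardiac correction is then skipped and the recording
#' carries `ecg_available = FALSE`; a missing EEG channel is fatal.
#'
#' @param edf_path EDF file path.
#' @param annotation_path Annotation file path (`.xml` or `.csv`).
#' @param channels Channels to load; default `c("C3", "C4", "ECG")`.
#' @param events_path Optional events CSV when `annotation_path` is a CSV.
#' @return A list with `recording` ([psg_recording()]) and `annotations`
#'   ([annotation_set()], N4 collapsed with sidecar).
#' @export
read_psg <- function(edf_path, annotation_path, channels = c("C3", "C4", "ECG"),
                     events_path = NULL) {
  hdr <- read_edf(edf_path)
  eeg_req <- setdiff(channels, "ECG")
  idx <- vapply(channels, function(ch) resolve_channel_alias(ch, hdr$labels_raw), 0L)
  if (anyNA(idx[eeg_req])) {
    stop("required EEG channel(s) missing from EDF: ",
         paste(eeg_req[is.na(idx[eeg_req])], collapse = ", "))
  }
  ecg_ok <- !("ECG" %in% channels) || !is.na(idx[["ECG"]])
  if (!ecg_ok) {
    warning("ECG channel missing; cardiac correction will be skipped and uncorrected values retained")
    channels <- setdiff(channels, "ECG")
  }
  got <- read_edf(edf_path, channels = channels)
  rec <- psg_recording(got$signals, got$rates, got$start_time)
  rec$ecg_available <- ecg_ok
  annot <- if (grepl("\\.xml$", annotation_path, ignore.case = TRUE)) {
    read_nsrr_xml(annotation_path)
  } else {
    read_stage_csv(annotation_path, events_path)
  }
  list(recording = rec, annotations = collapse_stages(annot))
}

#' Resample a signal to a target rate
#'
#' Fourier-domain rational resampling: the spectrum is truncated (down) or
#' zero-padded (up) so that band-limited content below the output Nyquist is
#' reproduced with exact amplitude and intrinsic anti-alias protection.
#' Output duration equals input duration within one sample.
#'
#' @param x Numeric signal.
#' @param from Source rate in Hz.
#' @param to Target rate in Hz (default 128, the common analysis rate).
#' @return Resampled numeric vector of length `round(length(x) * to / from)`.
#' @export
resample_to <- function(x, from, to = 128) {
  if (from <= 0 || to <= 0) stop("sampling rates must be positive")
  if (from == to) return(x)
  n <- length(x)
  m <- round(n * to / from)
  X <- fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- floor((keep - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0) {
    # split the shared Nyquist bin to keep the output real-valued
    ny <- X[keep / 2 + 1]
    if (m > n) {
      Y[keep / 2 + 1] <- ny / 2
      Y[m - keep / 2 + 1] <- Conj(ny) / 2
    } else {
      Y[m / 2 + 1] <- Re(ny)
    }
  }
  Re(fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Zero-phase band-pass filter for EEG
#'
#' Cascaded 4th-order Butterworth high-pass and low-pass, each applied
#' forward-backward (`filtfilt`), so the composite response has zero phase
#' and an effective 8th-order roll-off on either side.
#'
#' @param x Numeric signal at `rate` Hz.
#' @param rate Sampling rate in Hz.
#' @param low,high Passband edges in Hz (defaults 0.3 and 35).
#' @return Filtered signal, same length.
#' @export
bandpass_eeg <- function(x, rate = 128, low = 0.3, high = 35) {
  if (length(x) < 3 * rate) stop("signal too short for band-pass warm-up")
  hp <- signal::butter(4, low / (rate / 2), type = "high")
  lp <- signal::butter(4, high / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
}

#' Build the 30-s epoch grid
#'
#' Aligns epochs to the annotation grid: epoch `i` (0-based) spans samples
#' `[i*30*rate, (i+1)*30*rate)`, half-open, starting at the first staged
#' epoch. Trailing partial epochs are not emitted; staged epochs beyond the
#' recording are dropped.
#'
#' @param recording A [psg_recording()] (all channels already at `rate`).
#' @param annotations An [annotation_set()].
#' @param rate Common sampling rate in Hz.
#' @return A tibble with columns `epoch` (0-based), `start_sample`,
#'   `stop_sample` (1-based, inclusive/exclusive+1 convention: the epoch is
#'   `start_sample:(stop_sample)` with `stop_sample - start_sample + 1`
#'   samples), and `stage`; attribute `rate` and `epoch_length`.
#' @export
build_epoch_grid <- function(recording, annotations, rate = 128) {
  n <- min(lengths(recording$signals))
  spe <- as.integer(30 * rate)
  if (n < spe) stop("recording shorter than one 30-s epoch")
  n_sig_epochs <- n %/% spe
  n_epochs <- min(n_sig_epochs, length(annotations$stages))
  g <- tibble(
    epoch = seq_len(n_epochs) - 1L,
    start_sample = (seq_len(n_epochs) - 1L) * spe + 1L,
    stop_sample = seq_len(n_epochs) * spe,
    stage = annotations$stages[seq_len(n_epochs)]
  )
  attr(g, "rate") <- rate
  attr(g, "epoch_length") <- 30
  g
}
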