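# Minimal reader/writer for European Data Format (EDF) continuous recordings.
# 16-bit integer samples with per-signal physical/digital scaling; ASCII header
# of 256 bytes plus 256 bytes per signal. Only the features needed for
# single-montage PSG files are implemented (no EDF+ discontinuous files).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Write signals to a European Data Format (EDF) file
#'
#' Writes a multi-channel recording as a plain EDF file with one-second data
#' records. Samples are quantized to 16-bit integers using a per-channel
#' physical range that spans the data, so the round-trip error is bounded by
#' half a quantization step.
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors, amplitudes in microvolts
#'   (or millivolts for ECG; the unit string is stored per channel).
#' @param rates Integer vector of per-channel sampling rates in Hz (recycled).
#' @param start_time Recording onset as `"hh:mm:ss"` clock time.
#' @param units Character vector of physical dimension strings (recycled).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, rates, start_time = "22:00:00", units = "uV") {
  stopifnot(is.list(signals), length(signals) > 0, !is.null(names(signals)))
  ns <- length(signals)
  rates <- rep_len(as.integer(rates), ns)
  units <- rep_len(units, ns)
  if (any(rates <= 0)) stop("sampling rates must be positive")

  # whole one-second records; truncate ragged tails
  n_rec <- min(floor(lengths(signals) / rates))
  if (n_rec < 1) stop("signals shorter than one EDF record")

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_rec * rates[i])]
    r <- range(x, finite = TRUE)
    if (!all(is.finite(r))) stop("non-finite samples in channel ", names(signals)[i])
    span <- max(r[2] - r[1], 1e-6)
    pmin_[i] <- r[1] - 0.01 * span
    pmax_[i] <- r[2] + 0.01 * span
    scale <- (pmax_[i] - pmin_[i]) / 65535
    dig[[i]] <- as.integer(round((x - pmin_[i]) / scale) - 32768L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.01", 8), .edf_pad(gsub(":", ".", start_time), 8),
    .edf_num(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_num(n_rec, 8), .edf_num(1, 8), .edf_num(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, .edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(names(signals), 16), field(rep("", ns), 80), field(units, 8),
    field(format(pmin_, trim = TRUE, digits = 8, scientific = FALSE), 8),
    field(format(pmax_, trim = TRUE, digits = 8, scientific = FALSE), 8),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(as.character(rates), 8), field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep;
#'   labels are matched through [resolve_channel_alias()] so `"C3"` finds a
#'   channel stored as `"C3-A2"` or `"EEG C3-M2"`.
#' @return A list with `signals` (named list of numeric vectors, physical
#'   units), `rates` (Hz), `units`, `start_time` (`"hh:mm:ss"`) and
#'   `duration` (seconds).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  start_time <- gsub("\\.", ":", trimws(substr(fixed, 177, 184)))
  n_rec <- as.integer(trimws(substr(fixed, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(fixed, 245, 252)))
  ns <- as.integer(trimws(substr(fixed, 253, 256)))

  rd <- function(width) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
  }
  labels <- rd(16); rd(80); units <- rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80); spr <- as.integer(rd(8)); rd(32)

  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- vapply(channels, function(ch) resolve_channel_alias(ch, labels), 0L)
    if (anyNA(keep)) {
      stop("channel(s) not found in EDF: ",
           paste(channels[is.na(keep)], collapse = ", "))
    }
  }

  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                     signed = TRUE, endian = "little")
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  signals <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    idx <- as.vector(outer((offs[i] + 1L):offs[i + 1L], (seq_len(n_rec) - 1L) * rec_len, `+`))
    gain <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    signals[[j]] <- (raw_all[idx] - dmin[i]) * gain + pmin_[i]
  }
  names(signals) <- if (is.null(channels)) labels[keep] else channels
  list(signals = signals, rates = spr[keep] / rec_dur, units = units[keep],
       start_time = start_time, duration = n_rec * rec_dur,
       labels_raw = labels[keep])
}

#' Resolve a canonical 10-20 channel name against stored EDF labels
#'
#' PSG studies label the central EEG derivations inconsistently
#' (`C3`, `C3-A2`, `C3-M2`, `EEG C3-A2`, ...). Given a requested canonical
#' name, returns the index of the first stored label that refers to it.
#'
#' @param channel Requested name, e.g. `"C3"`, `"C4"` or `"ECG"`.
#' @param labels Character vector of labels stored in the EDF.
#' @return Integer index into `labels`, or `NA` if unmatched.
#' @export
resolve_channel_alias <- function(channel, labels) {
  lab <- toupper(trimws(labels))
  ch <- toupper(trimws(channel))
  pats <- switch(ch,
    "C3" = c("^C3$", "^C3-(A2|M2)$", "^EEG[ _]?C3([-_ ](A2|M2))?$"),
    "C4" = c("^C4$", "^C4-(A1|M1)$", "^EEG[ _]?C4([-_ ](A1|M1))?$"),
    "ECG" = c("^ECG[0-9]*$", "^EKG[0-9]*$", "^ECG[ _-]?L?[0-9]*$", "ECG|EKG"),
    c(paste0("^", ch, "$"))
  )
  for (p in pats) {
    hit <- grep(p, lab)
    if (length(hit)) return(hit[1])
  }
  NA_integer_
}
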