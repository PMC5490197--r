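# Independent rule interpreters and small fixture builders used across the
# suite. The oracles re-express the scoring rules in a different style from
# the package implementation (precomputed run-length vectors, direct
# walks) so transcription errors in either show up as disagreement.

# --- brute-force sleep-cycle interpreter -------------------------------------
oracle_cycles <- function(st) {
  st[!(st %in% c("W", "N1", "N2", "N3", "R"))] <- "W"
  n <- length(st)
  # run length of consecutive W/N1 ending at each epoch (precomputed)
  wn1 <- integer(n)
  for (i in seq_len(n)) {
    wn1[i] <- if (st[i] %in% c("W", "N1")) (if (i > 1) wn1[i - 1] else 0L) + 1L else 0L
  }
  res <- list()
  pos <- 1L
  repeat {
    rest <- which(st[pos:n] %in% c("N2", "N3"))
    if (!length(rest)) break
    on <- pos + rest[1] - 1L
    j <- on
    nrem <- 0L
    done <- FALSE
    while (j <= n) {
      if (st[j] %in% c("N1", "N2", "N3")) nrem <- nrem + 1L
      if (wn1[j] > 30L) {
        # a W/N1 run breached 15 min inside the period (it cannot extend
        # before `on`, which is N2/N3): skipped-REM termination
        res[[length(res) + 1L]] <- c(on, j - wn1[j], NA, NA)
        pos <- j + 1L
        done <- TRUE
        break
      }
      if (st[j] == "R") {
        # REM episode: continues while trailing non-R stays <= 30 epochs
        k <- j
        lastr <- j
        remc <- 1L
        while (k < n && (k + 1L) - lastr <= 30L) {
          k <- k + 1L
          if (st[k] == "R") { remc <- remc + 1L; lastr <- k }
        }
        first <- length(res) == 0L
        if (nrem >= 30L && (first || remc >= 10L)) {
          res[[length(res) + 1L]] <- c(on, j - 1L, j, lastr)
          pos <- lastr + 1L
          done <- TRUE
          break
        } else {
          while (j <= n && st[j] == "R") j <- j + 1L
          next
        }
      }
      j <- j + 1L
    }
    if (!done) {
      if (nrem >= 30L) res[[length(res) + 1L]] <- c(on, n, NA, NA)
      break
    }
    if (pos > n) break
  }
  if (!length(res)) {
    return(data.frame(nrem_start = integer(), nrem_stop = integer(),
                      rem_start = integer(), rem_stop = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(nrem_start = m[, 1], nrem_stop = m[, 2],
             rem_start = m[, 3], rem_stop = m[, 4])
}

# --- brute-force ascending/descending score ----------------------------------
oracle_asc_desc <- function(st, i) {
  val <- function(s) if (s == "N3") 1 else -1
  prev <- c()
  j <- i - 1
  while (j >= 1 && st[j] != "N2" && length(prev) < 10) {
    prev <- c(prev, val(st[j])); j <- j - 1
  }
  nxt <- c()
  j <- i + 1
  while (j <= length(st) && st[j] != "N2" && length(nxt) < 10) {
    nxt <- c(nxt, -val(st[j])); j <- j + 1
  }
  sides <- c(if (length(prev)) mean(prev), if (length(nxt)) mean(nxt))
  if (!length(sides)) NA_real_ else mean(sides)
}

# --- closed-form truncated-normal cascade for the +/-2 SD filter -------------
oracle_sd_cascade <- function(k = 2, passes = 3) {
  keep <- 1
  s <- 1
  lim <- Inf
  for (p in seq_len(passes)) {
    lim <- min(lim, k * s)
    keep <- 2 * pnorm(lim) - 1
    s <- sqrt(1 - 2 * lim * dnorm(lim) / keep)
  }
  1 - keep  # fraction dropped
}

# --- small helpers -----------------------------------------------------------
pure_n2_eeg <- function(minutes, config = synth_config(), seed = 1, ...) {
  set.seed(seed)
  stages <- rep("N2", minutes * 2)
  list(stages = stages, eeg = gen_eeg(stages, config, ...))
}

detect_standalone <- function(x, variant = "standard", fc = 13.5, n_cycles = 7,
                              config = spindle_config()) {
  sb <- smooth_and_baseline(cmor_magnitude(x, wavelet_spec(fc, n_cycles), 128),
                            NULL, 128, config$spindle$smooth_s)
  detect_spindles(sb$smoothed, sb$baseline, 128, variant = variant,
                  config = config)
}

random_hypnogram <- function(n_epochs = 120,
                             alphabet = c("W", "N1", "N2", "N3", "R")) {
  # block-structured random stages so cycles actually form sometimes
  out <- character(0)
  while (length(out) < n_epochs) {
    st <- sample(alphabet, 1)
    out <- c(out, rep(st, sample(1:40, 1)))
  }
  out[seq_len(n_epochs)]
}
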