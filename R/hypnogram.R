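# Hypnogram analyses: stage summaries, NREM/REM cycle segmentation,
# ascending/descending N2 scoring, persistent sleep and per-epoch temporal
# covariates. All durations are counted in 30-s epochs (2 epochs = 1 min).

.is_sleep <- function(s) s %in% c("N1", "N2", "N3", "R")

#' Stage durations and percentages
#'
#' @param stages Character stage vector (one label per 30-s epoch).
#' @return Tibble with `stage`, `epochs`, `minutes` and `pct_tst`
#'   (percentage of total sleep time; wake excluded from the denominator).
#' @export
stage_summary <- function(stages) {
  lev <- c("N1", "N2", "N3", "R")
  cnt <- vapply(lev, function(s) sum(stages == s), 0L, USE.NAMES = FALSE)
  tst <- sum(cnt)
  if (tst == 0) stop("no sleep epochs")
  tibble(stage = lev, epochs = cnt, minutes = cnt * 0.5,
         pct_tst = 100 * cnt / tst)
}

#' Segment a hypnogram into NREM/REM sleep cycles
#'
#' Implements the conventional rules: a cycle requires at least 15 min of
#' NREM sleep in an episode beginning with the onset of N2 or N3, followed
#' by at least 5 min of REM - except that the first cycle accepts a REM
#' period of any duration. A contiguous run of more than 15 min of wake or
#' N1 terminates the cycle (skipped REM). A REM period may contain up to
#' 15 min of NREM or wake and still count as one episode. A final NREM
#' episode of at least 15 min at the end of the night counts as a terminal
#' cycle without REM. Unscored epochs are treated as wake.
#'
#' @param stages Character stage vector.
#' @return Tibble with one row per cycle: `cycle`, `nrem_start`,
#'   `nrem_stop`, `rem_start`, `rem_stop` (1-based epoch indices, `NA` for
#'   skipped REM), `nrem_min`, `rem_min`, and `label` (cycles 5 and above
#'   collapsed to `"5+"`).
#' @export
segment_cycles <- function(stages) {
  s <- stages
  s[!(s %in% c("W", "N1", "N2", "N3", "R"))] <- "W"
  n <- length(s)
  empty <- tibble(cycle = integer(), nrem_start = integer(), nrem_stop = integer(),
                  rem_start = integer(), rem_stop = integer(),
                  nrem_min = numeric(), rem_min = numeric(), label = character())
  cycles <- empty
  emit <- function(ns, ne, rs, re) {
    k <- nrow(cycles) + 1L
    nrem_ep <- sum(s[ns:ne] %in% c("N1", "N2", "N3"))
    rem_ep <- if (is.na(rs)) 0L else sum(s[rs:re] == "R")
    cycles <<- dplyr::bind_rows(cycles, tibble(
      cycle = k, nrem_start = ns, nrem_stop = ne,
      rem_start = rs, rem_stop = re,
      nrem_min = nrem_ep * 0.5, rem_min = rem_ep * 0.5,
      label = if (k >= 5) "5+" else as.character(k)))
  }

  i <- 1L
  while (i <= n) {
    nxt <- which(s[i:n] %in% c("N2", "N3"))
    if (!length(nxt)) break
    ns <- i + nxt[1] - 1L
    j <- ns
    nrem_count <- 0L
    run_wn1 <- 0L
    closed <- FALSE
    while (j <= n) {
      st <- s[j]
      if (st %in% c("W", "N1")) run_wn1 <- run_wn1 + 1L else run_wn1 <- 0L
      if (st %in% c("N1", "N2", "N3")) nrem_count <- nrem_count + 1L
      if (run_wn1 > 30L) {
        # skipped REM: cycle ends before the terminating wake/N1 run
        emit(ns, j - run_wn1, NA_integer_, NA_integer_)
        i <- j + 1L
        closed <- TRUE
        break
      }
      if (st == "R") {
        first_cycle <- nrow(cycles) == 0L
        k <- j; last_r <- j; rem_count <- 0L; run_nonr <- 0L
        while (k <= n) {
          if (s[k] == "R") { rem_count <- rem_count + 1L; last_r <- k; run_nonr <- 0L }
          else run_nonr <- run_nonr + 1L
          if (run_nonr > 30L) break
          k <- k + 1L
        }
        qualifies <- nrem_count >= 30L &&
          (if (first_cycle) rem_count >= 1L else rem_count >= 10L)
        if (qualifies) {
          emit(ns, j - 1L, j, last_r)
          i <- last_r + 1L
          closed <- TRUE
          break
        } else {
          # REM too short (or NREM requirement unmet): absorb this R run
          while (j <= n && s[j] == "R") j <- j + 1L
          run_wn1 <- 0L
          next
        }
      }
      j <- j + 1L
    }
    if (!closed) {
      # end of recording inside a NREM episode
      if (nrem_count >= 30L) emit(ns, n, NA_integer_, NA_integer_)
      break
    }
  }
  cycles
}

#' Ascending/descending score of an N2 epoch
#'
#' Collects the contiguous run of non-N2 epochs immediately preceding the
#' epoch (up to 5 min, i.e. 10 epochs, nearest first), coding N3 as +1 and
#' N1/W/R as -1, and averages; a second score from the contiguous
#' following non-N2 run uses reversed coding. The epoch score is the mean
#' of the available side scores; epochs scoring above +0.5 are ascending
#' (leaving deep sleep), below -0.5 descending (entering it), otherwise
#' neither. Epochs deep inside an N2 run have no adjacent non-N2 epochs
#' and score `NA` (neither).
#'
#' @param stages Character stage vector.
#' @param epoch 1-based epoch index (must be N2).
#' @return A list with `score` (in `[-1, 1]` or `NA`), `label`
#'   (`"ascending"`, `"descending"` or `"neither"`), and `one_sided`.
#' @export
asc_desc_score <- function(stages, epoch) {
  stopifnot(stages[epoch] == "N2")
  code <- function(st, reversed) {
    v <- ifelse(st == "N3", 1, -1)
    if (reversed) -v else v
  }
  side <- function(idx_seq, reversed) {
    run <- character(0)
    for (i in idx_seq) {
      if (i < 1 || i > length(stages) || stages[i] == "N2") break
      run <- c(run, stages[i])
      if (length(run) >= 10) break
    }
    if (!length(run)) NA_real_ else mean(code(run, reversed))
  }
  prev <- side(seq(epoch - 1, by = -1, length.out = min(epoch - 1, 10)), FALSE)
  nxt <- side(seq(epoch + 1, by = 1,
                  length.out = min(length(stages) - epoch, 10)), TRUE)
  vals <- c(prev, nxt)
  score <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  label <- if (is.na(score)) "neither"
    else if (score > 0.5) "ascending"
    else if (score < -0.5) "descending"
    else "neither"
  list(score = score, label = label, one_sided = sum(!is.na(vals)) == 1)
}

#' Persistent-sleep flag
#'
#' Sleep is persistent once 10 or more minutes (20 epochs) have elapsed
#' since the previous wake epoch, and at least 10 min since sleep onset.
#'
#' @param stages Character stage vector.
#' @param epoch 1-based epoch index.
#' @return Logical.
#' @export
persistent_sleep_flag <- function(stages, epoch) {
  if (!.is_sleep(stages[epoch])) return(FALSE)
  onset <- which(.is_sleep(stages))[1]
  prior_w <- which(stages[seq_len(epoch - 1L)] == "W")
  last_w <- if (length(prior_w)) max(prior_w) else 0L
  (epoch - last_w > 20L) && (epoch - onset >= 20L)
}

.clock_to_sec <- function(hms) {
  p <- as.numeric(strsplit(hms, ":")[[1]])
  p[1] * 3600 + p[2] * 60 + ifelse(length(p) > 2, p[3], 0)
}

#' Per-epoch temporal covariates and cycle context
#'
#' Annotates every epoch with elapsed time since lights-out, elapsed sleep,
#' elapsed N2/N3/REM (minutes, counted up to the epoch start), clock time
#' as minutes past 20:00 (epochs before 20:00 are flagged for removal),
#' cycle membership with the within-cycle position bin (six 10-min bins
#' plus `">60min"`), ascending/descending scores for N2 epochs, and the
#' persistent-sleep flag.
#'
#' @param stages Character stage vector.
#' @param start_time Clock time of epoch 1 (`"hh:mm:ss"`, or `NA`).
#' @param lights_out 1-based epoch index of lights-out; defaults to the
#'   first staged epoch.
#' @return Tibble with one row per epoch.
#' @export
epoch_context <- function(stages, start_time = NA_character_, lights_out = 1L) {
  n <- length(stages)
  cyc <- segment_cycles(stages)
  cycle_idx <- rep(NA_integer_, n)
  cycle_bin <- rep(NA_character_, n)
  for (r in seq_len(nrow(cyc))) {
    span <- cyc$nrem_start[r]:(if (is.na(cyc$rem_stop[r])) cyc$nrem_stop[r] else cyc$rem_stop[r])
    cycle_idx[span] <- cyc$cycle[r]
    mins <- (span - cyc$nrem_start[r]) * 0.5
    cycle_bin[span] <- ifelse(mins >= 60, ">60min",
                              as.character(floor(mins / 10) + 1))
  }
  before <- function(flag) c(0, cumsum(flag)[-n]) * 0.5
  elapsed_sleep <- before(.is_sleep(stages))
  asc <- purrr::map(seq_len(n), function(i) {
    if (stages[i] == "N2") asc_desc_score(stages, i)
    else list(score = NA_real_, label = NA_character_, one_sided = NA)
  })
  clock_min <- rep(NA_real_, n)
  remove_pre20 <- rep(FALSE, n)
  if (!is.na(start_time)) {
    t0 <- .clock_to_sec(start_time)
    tmin <- (t0 + (seq_len(n) - 1) * 30) / 60 - 1200  # minutes past 20:00
    tmin[tmin < -240] <- tmin[tmin < -240] + 1440     # past midnight
    clock_min <- tmin
    remove_pre20 <- tmin < 0
  }
  tibble(
    epoch = seq_len(n), stage = stages,
    cycle = cycle_idx, cycle_bin = cycle_bin,
    asc_score = vapply(asc, `[[`, 0, "score"),
    asc_label = vapply(asc, function(a) a$label %||% NA_character_, ""),
    persistent = vapply(seq_len(n), function(i) persistent_sleep_flag(stages, i), TRUE),
    elapsed_lights_out = pmax(0, (seq_len(n) - lights_out) * 0.5),
    elapsed_sleep = elapsed_sleep,
    elapsed_n2 = before(stages == "N2"),
    elapsed_n3 = before(stages == "N3"),
    elapsed_rem = before(stages == "R"),
    clock_min = clock_min,
    remove_pre20 = remove_pre20
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
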