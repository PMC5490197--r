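test_that("stage summary computes minutes and percentages of total sleep time", {
  s <- c(rep("N2", 100), rep("W", 100))
  ss <- stage_summary(s)
  expect_equal(ss$minutes[ss$stage == "N2"], 50)
  expect_equal(ss$pct_tst[ss$stage == "N2"], 100)
  eq <- stage_summary(rep(c("N1", "N2", "N3", "R"), each = 25))
  expect_true(all(eq$pct_tst == 25))
  expect_equal(sum(eq$pct_tst), 100)
  expect_error(stage_summary(rep("W", 10)), "no sleep")
})

test_that("cycle segmentation hand traces", {
  # 20 min N2 then 6 min REM: one full cycle
  c1 <- segment_cycles(c(rep("N2", 40), rep("R", 12)))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$nrem_min, 20)
  expect_equal(c1$rem_min, 6)
  # short first REM allowed; second cycle needs >= 5 min REM
  c2 <- segment_cycles(c(rep("N2", 40), rep("R", 4), rep("N2", 40), rep("R", 12)))
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$rem_min, c(2, 6))
  # >15 min wake terminates the first cycle with skipped REM
  c3 <- segment_cycles(c(rep("N2", 40), rep("W", 32), rep("N2", 40)))
  expect_equal(nrow(c3), 2L)
  expect_true(is.na(c3$rem_start[1]))
  expect_equal(c3$nrem_start[2], 73L)
  # no qualifying NREM: empty
  expect_equal(nrow(segment_cycles(rep("W", 50))), 0L)
  # a REM run before any NREM episode does not start a cycle
  c4 <- segment_cycles(c(rep("R", 12), rep("N2", 40), rep("R", 12)))
  expect_equal(c4$nrem_start[1], 13L)
  # REM period tolerates < 15 min interruptions as one episode
  c5 <- segment_cycles(c(rep("N2", 40), rep("R", 6), rep("N2", 10), rep("R", 6)))
  expect_equal(nrow(c5), 1L)
  expect_equal(c5$rem_min, 6)
  expect_equal(c5$rem_stop, 62L)
})

test_that("cycle segmentation agrees with the brute-force interpreter", {
  # exhaustive over all hypnograms of length <= 8 on a 3-letter alphabet
  alph <- c("W", "N2", "R")
  for (len in 1:8) {
    grid <- do.call(expand.grid, c(rep(list(alph), len),
                                   stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      st <- as.character(grid[r, ])
      got <- segment_cycles(st)
      ora <- oracle_cycles(st)
      expect_equal(nrow(got), nrow(ora))
    }
  }
  # seeded random hypnograms at realistic length, full alphabet
  set.seed(42)
  for (i in 1:60) {
    st <- random_hypnogram(120)
    got <- segment_cycles(st)
    ora <- oracle_cycles(st)
    expect_equal(nrow(got), nrow(ora), info = paste(st, collapse = ""))
    if (nrow(got)) {
      expect_equal(got$nrem_start, ora$nrem_start)
      expect_equal(got$nrem_stop, ora$nrem_stop)
      expect_equal(got$rem_start, ora$rem_start)
      expect_equal(got$rem_stop, ora$rem_stop)
    }
  }
})

test_that("segmentation is deterministic", {
  set.seed(9)
  st <- random_hypnogram(200)
  expect_identical(segment_cycles(st), segment_cycles(st))
})

test_that("ascending/descending scores follow the flanking-run coding", {
  st <- c(rep("N3", 10), "N2", rep("R", 10))
  a <- asc_desc_score(st, 11)
  expect_equal(a$score, 1)
  expect_equal(a$label, "ascending")
  st2 <- c(rep("W", 10), "N2", rep("N3", 10))
  d <- asc_desc_score(st2, 11)
  expect_equal(d$score, -1)
  expect_equal(d$label, "descending")
  # prev 5 N3 + 5 N1 (adjacent N1 first) -> prev 0; next REM -> +1; mean +0.5 strict
  st3 <- c(rep("N3", 5), rep("N1", 5), "N2", rep("R", 10))
  m <- asc_desc_score(st3, 11)
  expect_equal(m$score, 0.5)
  expect_equal(m$label, "neither")
  # mid-run N2 with no adjacent non-N2: undefined score, neither
  st4 <- rep("N2", 21)
  mid <- asc_desc_score(st4, 11)
  expect_true(is.na(mid$score))
  expect_equal(mid$label, "neither")
})

test_that("ascending/descending agrees with its brute-force oracle on random hypnograms", {
  set.seed(10)
  for (i in 1:40) {
    st <- random_hypnogram(80)
    for (e in which(st == "N2")) {
      got <- asc_desc_score(st, e)
      expect_equal(got$score, oracle_asc_desc(st, e))
      if (!is.na(got$score)) {
        expect_gte(got$score, -1)
        expect_lte(got$score, 1)
      }
    }
  }
})

test_that("persistent sleep starts 10 min after the last wake", {
  st <- c(rep("W", 5), rep("N2", 40))
  flags <- vapply(seq_along(st), function(i) persistent_sleep_flag(st, i), TRUE)
  expect_false(any(flags[1:25]))       # includes the first 20 sleep epochs
  expect_true(all(flags[26:45]))       # 21st sleep epoch onwards
  st2 <- c(rep("W", 5), rep("N2", 30), "W", rep("N2", 30))
  f2 <- vapply(seq_along(st2), function(i) persistent_sleep_flag(st2, i), TRUE)
  expect_false(f2[36])
  expect_false(any(f2[37:56]))
  expect_true(f2[57])
})

test_that("temporal covariates and within-cycle bins are correct", {
  st <- c(rep("N2", 40), rep("N3", 24), rep("N2", 10), rep("R", 12))
  ctx <- epoch_context(st, start_time = "22:00:00")
  expect_equal(ctx$clock_min[1], 120)
  expect_equal(ctx$clock_min[7], 123)
  # 31st minute of the cycle -> bin 4 (epoch 62 starts at minute 30.5)
  expect_equal(ctx$cycle_bin[63], "4")
  expect_equal(ctx$cycle_bin[1], "1")
  # past 60 min into a long terminal NREM cycle
  long <- epoch_context(rep("N2", 130))
  expect_equal(long$cycle_bin[125], ">60min")
  # elapsed N3 constant across the REM run
  expect_equal(length(unique(ctx$elapsed_n3[77:86])), 1L)
  # elapsed counters non-decreasing
  expect_true(all(diff(ctx$elapsed_sleep) >= 0))
  expect_true(all(diff(ctx$elapsed_n2) >= 0))
  # epochs before 20:00 flagged
  ctx2 <- epoch_context(rep("N2", 4), start_time = "19:30:00")
  expect_true(all(ctx2$remove_pre20[1:2]))
  expect_equal(ctx2$clock_min[1], -30)
})

test_that("asc/desc labels are mutually exclusive on random hypnograms", {
  set.seed(11)
  st <- random_hypnogram(150)
  ctx <- epoch_context(st)
  lab <- ctx$asc_label[ctx$stage == "N2"]
  expect_true(all(lab %in% c("ascending", "descending", "neither")))
})
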