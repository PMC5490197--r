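test_that("generated hypnograms contain exactly the configured cycle count", {
  for (k in c(2, 4, 5)) {
    st <- gen_hypnogram(k)
    expect_equal(nrow(segment_cycles(st)), k)
  }
  expect_equal(nrow(segment_cycles(gen_hypnogram(0))), 0L)
  # a 4-min first REM still closes the first cycle
  st <- gen_hypnogram(2, first_rem_epochs = 8)
  expect_equal(nrow(segment_cycles(st)), 2L)
})

test_that("spindle arrivals are Poisson at the configured rate with unit dispersion", {
  set.seed(1)
  stages <- rep("N2", 120)  # 60 min
  ee <- gen_eeg(stages, synth_config(spindle_rate = 2))
  tr <- ee$truth[ee$truth$channel == "C3", ]
  expect_lt(abs(nrow(tr) - 120), 3 * sqrt(120))
  counts <- vapply(0:119, function(e) {
    sum(tr$start_s >= e * 30 & tr$start_s < (e + 1) * 30)
  }, 0L)
  di <- var(counts) / mean(counts)
  expect_lt(abs(di - 1), 0.45)  # ~3 SD of the DI at n = 120
  # truth events lie within N2 epochs
  ee2 <- gen_eeg(c(rep("W", 10), rep("N2", 20), rep("R", 10)), synth_config())
  ep <- floor(ee2$truth$start_s / 30)
  expect_true(all(ep >= 10 & ep < 30))
})

test_that("per-epoch true counts pass the dispersion QC under defaults", {
  set.seed(2)
  ee <- gen_eeg(rep("N2", 120), synth_config())
  tr <- ee$truth[ee$truth$channel == "C3", ]
  counts <- vapply(0:119, function(e) {
    sum(tr$start_s >= e * 30 & tr$start_s < (e + 1) * 30)
  }, 0L)
  expect_true(dispersion_index(counts)$qc_pass)
})

test_that("zero leakage leaves the EEG untouched; truth R times are recorded", {
  set.seed(3)
  cfg <- synth_config(ecg_leak_uv = 0)
  ee <- gen_eeg(rep("N2", 6), cfg)
  before <- ee$signals$C3
  ec <- gen_ecg_and_leak(ee$signals, cfg, 128)
  expect_identical(ec$signals$C3, before)
  expect_gt(length(ec$r_times), 150)  # ~3 min at 60 bpm
  expect_true(all(diff(ec$r_times) > 0))
})

test_that("fixtures round-trip deterministically through EDF and CSV", {
  cfg <- synth_config(n_cycles = 1)
  psg <- gen_psg(cfg, seed = 99)
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  f1 <- write_fixture(psg, d1)
  psg_again <- gen_psg(cfg, seed = 99)
  f2 <- write_fixture(psg_again, d2)
  expect_identical(readBin(f1["edf"], "raw", file.size(f1["edf"])),
                   readBin(f2["edf"], "raw", file.size(f2["edf"])))
  back <- read_psg(f1["edf"], f1["stages"])
  expect_named(back$recording$signals, c("C3", "C4", "ECG"))
  span <- diff(range(psg$recording$signals$C3))
  expect_lt(max(abs(back$recording$signals$C3 -
                    psg$recording$signals$C3[seq_along(back$recording$signals$C3)])),
            span * 1.02 / 65535)
  tr <- read.csv(f1["truth"])
  expect_equal(nrow(tr), nrow(psg$truth))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort parameters are reproducible and within configured ranges", {
  p1 <- gen_cohort_params(10, seed = 7)
  p2 <- gen_cohort_params(10, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$spindle_rate >= 1 & p1$spindle_rate <= 3))
  expect_true(all(p1$seed < 2^31))
})

test_that("skewed envelopes shift the detected symmetry statistic", {
  set.seed(8)
  cfg <- synth_config(spindle_rate = 3, amp_sd = 0)
  ee_sym <- gen_eeg(rep("N2", 16), cfg, envelope = "gaussian", envelope_skew = 0)
  set.seed(8)
  ee_skw <- gen_eeg(rep("N2", 16), cfg, envelope = "gaussian", envelope_skew = 0.9)
  # properties over the true burst intervals: detected windows centre on the
  # envelope peak, so skew must be assessed on the generated support
  sym_of <- function(ee) {
    x <- bandpass_eeg(ee$signals$C3)
    tr <- ee$truth[ee$truth$channel == "C3", ]
    ev <- tibble::tibble(start_s = tr$start_s,
                         stop_s = tr$start_s + tr$duration,
                         duration = tr$duration)
    pr <- spindle_properties(ev, x, 128)
    mean(pr$symmetry, na.rm = TRUE)
  }
  expect_gt(sym_of(ee_skw), sym_of(ee_sym) + 0.1)
})

test_that("end-to-end analysis object exposes tidy/glance/autoplot", {
  psg <- gen_psg(synth_config(n_cycles = 2), seed = 5)
  fit <- spindle_analysis(psg$recording, psg$annotations)
  expect_s3_class(fit, "spindle_analysis")
  td <- tidy(fit)
  expect_true(all(c("channel", "start_s", "amplitude", "frequency") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$density, 0)
  expect_true(gl$ecg_corrected)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_frequency_sweep(tibble::tibble(fc = seq(8, 18, 0.25),
                                            density = runif(41)))
  expect_s3_class(p2, "ggplot")
})
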