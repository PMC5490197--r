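test_that("EDF write/read round-trips samples within format quantization", {
  set.seed(1)
  sig <- list(C3 = rnorm(128 * 35, 0, 30), C4 = rnorm(128 * 35, 0, 30),
              ECG = rnorm(256 * 35, 0, 400))
  path <- tempfile(fileext = ".edf")
  write_edf(path, sig, rates = c(128, 128, 256), start_time = "23:15:00")
  got <- read_edf(path)
  expect_equal(names(got$signals), c("C3", "C4", "ECG"))
  expect_equal(got$rates, c(128, 128, 256))
  expect_equal(got$start_time, "23:15:00")
  for (ch in names(sig)) {
    span <- diff(range(sig[[ch]]))
    qstep <- span * 1.02 / 65535
    expect_lt(max(abs(got$signals[[ch]] - sig[[ch]][seq_along(got$signals[[ch]])])),
              qstep)
  }
})

test_that("channel aliasing resolves 10-20 label variants", {
  labs <- c("EEG C3-A2", "EEG C4-A1", "EKG1")
  expect_equal(resolve_channel_alias("C3", labs), 1L)
  expect_equal(resolve_channel_alias("C4", labs), 2L)
  expect_equal(resolve_channel_alias("ECG", labs), 3L)
  expect_true(is.na(resolve_channel_alias("O1", labs)))
})

test_that("read_psg resolves aliases, errors on missing EEG, warns on missing ECG", {
  set.seed(2)
  path <- tempfile(fileext = ".edf")
  stg <- tempfile(fileext = ".csv")
  write_edf(path, list(`C3-A2` = rnorm(128 * 65, 0, 20),
                       `C4-A1` = rnorm(128 * 65, 0, 20)), rates = 128)
  write_stage_csv(annotation_set(c("N2", "N2")), stg)
  expect_warning(psg <- read_psg(path, stg), "ECG")
  expect_named(psg$recording$signals, c("C3", "C4"))
  expect_false(psg$recording$ecg_available)

  ecg_only <- tempfile(fileext = ".edf")
  write_edf(ecg_only, list(ECG = rnorm(128 * 65)), rates = 128)
  expect_error(read_psg(ecg_only, stg), "C3")
})

test_that("collapse_stages folds N4 into N3 with a sidecar and maps unknowns to ?", {
  a <- annotation_set(c("N3", "N4", "N4", "W", "N2", "MOVEMENT"))
  out <- collapse_stages(a)
  expect_equal(out$stages, c("N3", "N3", "N3", "W", "N2", "?"))
  expect_equal(out$n4_sidecar, c(0L, 1L, 1L, 0L, 0L, 0L))
  aasm <- collapse_stages(annotation_set(c("W", "N1", "N2", "N3", "R")))
  expect_equal(aasm$stages, c("W", "N1", "N2", "N3", "R"))
})

test_that("NSRR-style XML annotations parse stages and event classes", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<CMPStudyConfig>",
    "<SleepStages><SleepStage>0</SleepStage><SleepStage>2</SleepStage>",
    "<SleepStage>4</SleepStage><SleepStage>5</SleepStage></SleepStages>",
    "<ScoredEvents>",
    "<ScoredEvent><EventType>Arousals|Arousals</EventType><EventConcept>Arousal|Arousal ()</EventConcept><Start>61.0</Start><Duration>1.0</Duration></ScoredEvent>",
    "<ScoredEvent><EventType>Limb Movement</EventType><EventConcept>Limb Movement</EventConcept><Start>100</Start><Duration>2.5</Duration></ScoredEvent>",
    "<ScoredEvent><EventType>Respiratory</EventType><EventConcept>Hypopnea</EventConcept><Start>10</Start><Duration>12</Duration></ScoredEvent>",
    "</ScoredEvents></CMPStudyConfig>"), xml)
  a <- read_nsrr_xml(xml)
  expect_equal(a$stages, c("W", "N2", "N4", "R"))
  expect_equal(nrow(a$events), 2L)  # respiratory event dropped
  expect_setequal(a$events$class, c("arousal", "movement"))
})

test_that("resampling preserves band-limited content and duration", {
  t <- (0:(256 * 4 - 1)) / 256
  s <- sin(2 * pi * 10 * t)
  y <- resample_to(s, 256, 128)
  expect_length(y, 128 * 4)
  interior <- y[40:(length(y) - 40)]
  expect_lt(abs(max(abs(interior)) - 1), 0.01)
  expect_identical(resample_to(s, 128, 128), s)
  expect_error(resample_to(s, -1, 128), "positive")

  set.seed(5)
  wn <- rnorm(125 * 30)
  y2 <- resample_to(wn, 125, 128)
  expect_length(y2, round(length(wn) * 128 / 125))
  p1 <- welch_psd(wn, 125)
  p2 <- welch_psd(y2, 128)
  b1 <- sum(p1$psd[p1$freq < 40]) * diff(p1$freq[1:2])
  b2 <- sum(p2$psd[p2$freq < 40]) * diff(p2$freq[1:2])
  expect_lt(abs(b2 / b1 - 1), 0.05)
})

test_that("band-pass is zero-phase, removes DC and attenuates out-of-band", {
  t <- (0:(128 * 30 - 1)) / 128
  s13 <- sin(2 * pi * 13 * t)
  f13 <- bandpass_eeg(s13)
  core <- seq(128 * 2, 128 * 28)
  expect_lt(abs(max(abs(f13[core])) - 1), 0.02)
  # zero phase: any 1-sample lag at 13 Hz would cap the correlation at ~0.8
  expect_gt(cor(f13[core], s13[core]), 0.999)
  s60 <- sin(2 * pi * 60 * t)
  expect_lt(sqrt(mean(bandpass_eeg(s60)[core]^2)), 0.1 * sqrt(0.5))
  dc <- bandpass_eeg(rep(100, 128 * 30) + s13)
  expect_lt(abs(mean(dc)), 1)
  # idempotence on band-limited content
  expect_lt(max(abs(bandpass_eeg(f13)[core] - f13[core])), 0.05)
})

test_that("epoch grid is contiguous, aligned, and truncates partial epochs", {
  rec <- psg_recording(list(C3 = numeric(128 * 617)), 128)  # 10 min + 17 s
  ann <- annotation_set(rep("N2", 21))
  g <- build_epoch_grid(rec, ann)
  expect_equal(nrow(g), 20L)
  expect_equal(g$start_sample[1], 1L)
  expect_true(all(g$stop_sample - g$start_sample + 1L == 30L * 128L))
  expect_equal(g$start_sample[-1], g$stop_sample[-20] + 1L)
  short <- psg_recording(list(C3 = numeric(100)), 128)
  expect_error(build_epoch_grid(short, ann), "shorter")
})
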