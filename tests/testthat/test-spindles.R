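rate <- 128

test_that("wavelet magnitude is flat on its centre frequency and selective off it", {
  t <- (0:(rate * 20 - 1)) / rate
  m <- cmor_magnitude(sin(2 * pi * 13.5 * t), wavelet_spec(13.5, 7), rate)
  core <- m[500:(length(m) - 500)]
  expect_lt(sd(core) / mean(core), 0.05)
  resp <- function(f, n_cyc) {
    mean(cmor_magnitude(sin(2 * pi * f * t), wavelet_spec(13.5, n_cyc),
                        rate)[1000:1500])
  }
  r7 <- resp(13.5, 7) / resp(16.5, 7)
  r12 <- resp(13.5, 12) / resp(16.5, 12)
  expect_gt(r7, 2)
  expect_gt(r12, r7)
})

test_that("12-cycle wavelets are more selective than 7-cycle at every centre frequency", {
  t <- (0:(rate * 12 - 1)) / rate
  for (fc in c(8, 10.5, 13.5, 15, 18)) {
    resp <- function(f, n_cyc) {
      mean(cmor_magnitude(sin(2 * pi * f * t), wavelet_spec(fc, n_cyc),
                          rate)[600:900])
    }
    sel7 <- resp(fc, 7) / resp(fc + 2, 7)
    sel12 <- resp(fc, 12) / resp(fc + 2, 12)
    expect_gt(sel12, sel7)
  }
})

test_that("smoothing is a 13-sample centred average with scale-equivariant baseline", {
  const <- rep(4, 1000)
  sb <- smooth_and_baseline(const, NULL, rate, 0.1)
  expect_equal(sb$smoothed, const)
  expect_equal(sb$baseline, 4)
  imp <- numeric(1001); imp[501] <- 1
  sbi <- smooth_and_baseline(imp, NULL, rate, 0.1)
  expect_equal(sum(sbi$smoothed > 0), 13L)
  expect_equal(max(sbi$smoothed), 1 / 13, tolerance = 1e-12)
  set.seed(1)
  x <- abs(rnorm(5000)) + 1
  a <- smooth_and_baseline(x, NULL, rate, 0.1)
  b <- smooth_and_baseline(2 * x, NULL, rate, 0.1)
  expect_equal(b$baseline, 2 * a$baseline)
  expect_equal(b$smoothed / b$baseline, a$smoothed / a$baseline)
  expect_error(smooth_and_baseline(x, rep(FALSE, 5000), rate), "empty")
})

test_that("core, extension and gap-merge rules follow the duration bounds", {
  mk <- function(spans, level = 6, n = rate * 20) {
    x <- rep(1, n)
    for (s in spans) x[(round(s[1] * rate) + 1):(round(s[2] * rate))] <- level
    x
  }
  # single 1-s core
  ev <- detect_spindles(mk(list(c(5, 6))), 1, rate)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 1, tolerance = 0.01)
  # two cores 0.5 s apart, combined span 2.4 s -> merged
  ev2 <- detect_spindles(mk(list(c(5, 5.9), c(6.4, 7.4))), 1, rate)
  expect_equal(nrow(ev2), 1L)
  expect_gt(ev2$duration, 2.3)
  # combined span 3.4 s -> NOT merged
  ev3 <- detect_spindles(mk(list(c(5, 6.4), c(6.9, 8.4))), 1, rate)
  expect_equal(nrow(ev3), 2L)
  # core shorter than 0.3 s rejected; longer than 3 s rejected
  expect_equal(nrow(detect_spindles(mk(list(c(5, 5.2))), 1, rate)), 0L)
  expect_equal(nrow(detect_spindles(mk(list(c(5, 8.5))), 1, rate)), 0L)
  # core extended by the t=2 shoulder to reach the 0.5 s minimum
  x <- rep(1, rate * 20)
  x[641:684] <- 6          # 0.34 s core
  x[616:640] <- 3          # contiguous shoulders above 2x baseline
  x[685:704] <- 3
  ev4 <- detect_spindles(x, 1, rate)
  expect_equal(nrow(ev4), 1L)
  expect_gte(ev4$duration, 0.5)
})

test_that("threshold variants bracket the detection statistic", {
  x <- rep(1, rate * 30)
  x[(5 * rate + 1):(6 * rate)] <- 6     # strong burst
  x[(15 * rate + 1):(16 * rate)] <- 1.5 # weak burst
  std <- detect_spindles(x, 1, rate, variant = "standard")
  tl <- detect_spindles(x, 1, rate, variant = "TL")
  ta <- detect_spindles(x, 1, rate, variant = "TA")
  expect_equal(nrow(std), 1L)
  expect_equal(round(std$start_s), 5)
  expect_equal(nrow(tl), 1L)
  expect_equal(round(tl$start_s), 15)
  expect_equal(nrow(ta), 2L)
})

test_that("detections are invariant to overall signal scale", {
  set.seed(2)
  ee <- gen_eeg(rep("N2", 10), synth_config())
  x <- bandpass_eeg(ee$signals$C3)
  ev1 <- detect_standalone(x)
  ev2 <- detect_standalone(3.7 * x)
  expect_equal(ev1, ev2)
})

test_that("events straddling removed epochs are discarded", {
  x <- rep(1, rate * 90)
  x[(29.7 * rate + 1):(30.5 * rate)] <- 6   # spans the epoch-0/1 boundary
  x[(40 * rate + 1):(41 * rate)] <- 6       # inside epoch 1
  keep <- rep(c(FALSE, TRUE, TRUE), each = rate * 30)
  ev <- detect_spindles(x, 1, rate, keep = keep)
  expect_equal(nrow(ev), 1L)
  expect_equal(round(ev$start_s), 40)
})

test_that("spindle properties recover an analytic burst", {
  t <- (0:(rate * 10 - 1)) / rate
  x <- numeric(length(t))
  idx <- (4 * rate + 1):(5 * rate)
  x[idx] <- 20 * sin(2 * pi * 13 * t[idx])   # 20 uV amplitude, 40 uV p2p
  ev <- tibble::tibble(start_s = 4, stop_s = 5, duration = 1)
  pr <- spindle_properties(ev, x, rate)
  expect_equal(pr$amplitude, 40, tolerance = 0.05 * 40)
  expect_equal(pr$frequency, 13, tolerance = 0.25)
  expect_equal(pr$n_oscillations, 13L, tolerance = 1)

  # symmetric Gaussian envelope -> symmetry ~ 0.5
  env <- exp(-((t[idx] - 4.5) / 0.15)^2)
  x2 <- numeric(length(t)); x2[idx] <- 20 * env * sin(2 * pi * 13 * t[idx])
  pr2 <- spindle_properties(ev, x2, rate)
  expect_equal(pr2$symmetry, 0.5, tolerance = 0.1)

  # waxing-only envelope -> symmetry past the midpoint
  x3 <- numeric(length(t)); x3[idx] <- 20 * seq(0.05, 1, length.out = rate) *
    sin(2 * pi * 13 * t[idx])
  pr3 <- spindle_properties(ev, x3, rate)
  expect_gt(pr3$symmetry, 0.5)
})

test_that("cross-frequency merging follows the 50%-union / 80%-overlap rule", {
  ev <- tibble::tibble(start_s = c(0, 0), stop_s = c(1, 1), fc = c(12, 13))
  expect_equal(nrow(merge_across_frequencies(ev)), 1L)
  ev2 <- tibble::tibble(start_s = c(0, 0.6), stop_s = c(1, 1.6), fc = c(12, 13))
  expect_equal(nrow(merge_across_frequencies(ev2)), 2L)
  ev3 <- tibble::tibble(start_s = c(0, 0.1), stop_s = c(1, 0.9), fc = c(12, 13))
  m3 <- merge_across_frequencies(ev3)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start_s, m3$stop_s), c(0, 1))
  # idempotence
  set.seed(3)
  evr <- tibble::tibble(start_s = sort(runif(40, 0, 100)))
  evr$stop_s <- evr$start_s + runif(40, 0.4, 1.5)
  evr$fc <- sample(seq(10, 16, 0.25), 40, replace = TRUE)
  once <- merge_across_frequencies(evr)
  twice <- merge_across_frequencies(once)
  expect_equal(twice$start_s, once$start_s)
  expect_equal(twice$stop_s, once$stop_s)
})

test_that("RMS detector flags the top 5% of windows and needs two consecutive windows", {
  set.seed(4)
  x <- rnorm(rate * 600, 0, 10)
  ev <- rms_detector(x, rate = rate)
  # windows above the 95th percentile: ~5% flagged by construction
  filt <- sigma_bandpass(x, rate)
  w <- 32
  rms <- vapply(seq(1, length(filt) - w + 1, by = w),
                function(s) sqrt(mean(filt[s:(s + w - 1)]^2)), 0)
  expect_equal(mean(rms > quantile(rms, 0.95)), 0.05, tolerance = 0.01)
  # isolated flagged windows (0.25 s) cannot form events
  if (nrow(ev)) expect_true(all(ev$duration >= 0.3))
})

test_that("wavelet and RMS densities correlate across synthetic individuals", {
  dens <- t(vapply(1:6, function(i) {
    set.seed(200 + i)
    cfg <- synth_config(spindle_rate = runif(1, 0.8, 3.2))
    ee <- gen_eeg(rep("N2", 16), cfg)
    x <- bandpass_eeg(ee$signals$C3)
    c(wav = nrow(detect_standalone(x)), rms = nrow(rms_detector(x, rate = rate)))
  }, c(wav = 0, rms = 0)))
  expect_gt(cor(dens[, "wav"], dens[, "rms"]), 0)
})

test_that("dispersion index matches hand computations and flags overdispersion", {
  expect_equal(dispersion_index(rep(c(0, 1, 2, 3), 3))$di,
               var(rep(c(0, 1, 2, 3), 3)) / 1.5)
  d <- dispersion_index(c(0, 1, 2, 3))  # < 10 epochs: undefined
  expect_true(is.na(d$di))
  expect_equal(dispersion_index(rep(2, 20))$di, 0)
  set.seed(5)
  p <- dispersion_index(rpois(1e4, 1))
  expect_equal(p$di, 1, tolerance = 0.05)
  expect_true(p$qc_pass)
  over <- dispersion_index(c(rep(0, 50), rep(10, 10)))
  expect_gt(over$di, 2)
  expect_false(over$qc_pass)
  expect_lt(over$p, 0.001)
})

test_that("bilateral matching is one-to-one within 0.5 s", {
  ev <- tibble::tibble(start_s = c(10, 20, 30), stop_s = c(11, 21, 31))
  same <- bilateral_match(ev, ev)
  expect_equal(same$frac_c3, 1)
  far <- dplyr::mutate(ev, start_s = start_s + 5)
  expect_equal(bilateral_match(ev, far)$frac_c3, 0)
  # known bilateral probability recovered from generator truth
  set.seed(6)
  ee <- gen_eeg(rep("N2", 40), synth_config(bilateral_prob = 0.5))
  tr3 <- ee$truth[ee$truth$channel == "C3", ]
  tr4 <- ee$truth[ee$truth$channel == "C4", ]
  bm <- bilateral_match(tibble::tibble(start_s = tr3$start_s, stop_s = tr3$start_s + tr3$duration),
                        tibble::tibble(start_s = tr4$start_s, stop_s = tr4$start_s + tr4$duration))
  p_hat <- bm$frac_c3
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(tr3)) + 0.05)
})

test_that("summaries report density per retained N2 minute", {
  mask <- tibble::tibble(epoch = 0:29, stage = "N2",
                         keep = TRUE, reason = "")
  ev <- tibble::tibble(start_s = seq(1, 890, length.out = 30),
                       stop_s = seq(2, 891, length.out = 30),
                       duration = 1)
  s <- summarize_spindles(ev, mask)
  expect_equal(s$density, 2)
  expect_equal(s$minutes, 15)
  s0 <- summarize_spindles(ev[0, ], mask)
  expect_equal(s0$density, 0)
  expect_true(is.na(s0$mean_amplitude))
})

test_that("frequency sweep peaks at the generated spindle frequency", {
  set.seed(7)
  cfg <- synth_config(freq_mean = 11, freq_sd = 0.2, spindle_rate = 3)
  ee <- gen_eeg(rep("N2", 12), cfg)
  x <- bandpass_eeg(ee$signals$C3)
  mask <- tibble::tibble(epoch = 0:23, stage = "N2", keep = TRUE, reason = "")
  cfg2 <- spindle_config(sweep = list(fc_grid = seq(9, 17, by = 1)))
  sw <- frequency_sweep(x, NULL, rate, mask, cfg2)
  expect_equal(sw$fc[which.max(sw$density)], 11, tolerance = 1)
  expect_lt(sw$density[sw$fc == 15], max(sw$density) / 2)
})
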