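#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their default values. The
#' defaults are the canonical analysis settings: 13.5 Hz centre frequency
#' with a 7-cycle wavelet, adaptive thresholds of 4.5 (core) and 2
#' (extension) times the individual/channel baseline, 0.3-3.0 s cores with
#' at least 0.5 s total duration, and a 1-s gap merge capped at 3.0 s.
#'
#' @param ... Named overrides of the form `section$key`, e.g.
#'   `spindle = list(fc = 11)` (overrides are merged shallowly per section).
#' @return Nested named list of configuration sections.
#' @export
spindle_config <- function(...) {
  cfg <- list(
    qc = list(
      stage = "N2", delta_ratio = 2.5, beta_ratio = 2.0,
      sd_k = 2, sd_iterations = 3, clip_fraction = 0.05,
      welch_window_s = 4, welch_overlap = 0.5
    ),
    ecg = list(window_s = 2.0, pre_s = 0.25, hr_min = 40, hr_max = 100,
               min_peaks = 30),
    spindle = list(
      fc = 13.5, n_cycles = 7, th = 4.5, th2 = 2,
      dur_min = 0.3, dur_max = 3.0, min_total = 0.5,
      merge_gap = 1.0, smooth_s = 0.1,
      prop_band = c(11, 15), di_max = 2.0
    ),
    sweep = list(fc_grid = seq(8, 18, by = 0.25), n_cycles = 12,
                 merge_range = c(10, 16)),
    spectral = list(window_s = 4, overlap = 0.5),
    aggregate = list(min_epochs = 10, outlier_sd = 3, merge_sd_mult = 3)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    stopifnot(nm %in% names(cfg))
    cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
  }
  cfg
}
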