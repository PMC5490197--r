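# Per-individual measure finalization: minimum-data rules, +/-3 SD outlier
# trimming, C3/C4 channel merging with a discrepancy rule, the one-way
# ANOVA sibling intraclass correlation and covariate-adjusted test-retest
# correlation.

#' Minimum-data rule
#'
#' An individual contributes a measure only with at least `min_epochs`
#' (default 10, i.e. 5 min) of cleaned epochs of the relevant stage.
#'
#' @param n_retained Number of retained epochs.
#' @param min_epochs Threshold (default 10).
#' @return Logical keep flag.
#' @export
min_data_rule <- function(n_retained, min_epochs = 10) {
  n_retained >= min_epochs
}

#' Qualify NREM4 epochs by the flanking rule
#'
#' The deep slow-wave sub-analysis uses only NREM4 epochs flanked by two
#' other NREM4 epochs on either side.
#'
#' @param n4 Integer/logical vector marking original NREM4 epochs.
#' @return Logical vector: TRUE where the epoch qualifies.
#' @export
nrem4_flanked <- function(n4) {
  n4 <- as.logical(n4)
  n <- length(n4)
  vapply(seq_len(n), function(i) {
    if (!n4[i] || i < 3 || i > n - 2) return(FALSE)
    all(n4[(i - 2):(i + 2)])
  }, TRUE)
}

#' Trim outliers beyond +/- k SD
#'
#' Single pass: mean and SD from the non-missing values; values with
#' `|z| > k` are set missing.
#'
#' @param x Numeric vector.
#' @param k SD multiplier (default 3).
#' @return `x` with outliers replaced by `NA`.
#' @export
outlier_trim <- function(x, k = 3) {
  ok <- !is.na(x)
  if (sum(ok) < 3) return(x)
  mu <- mean(x[ok])
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0) return(x)
  x[ok & abs(x - mu) > k * s] <- NA
  x
}

#' Merge C3 and C4 estimates of a measure
#'
#' The merged value is the channel average, set to missing when the two
#' channels are highly discrepant: `|C3 - C4|` greater than `mult` (default
#' 3) times the average of the cross-individual SDs of the measure on each
#' channel. A single available channel is used as-is.
#'
#' @param c3,c4 Per-individual channel values (vectors, `NA` allowed).
#' @param sd_c3,sd_c4 Cross-individual SDs of the measure per channel
#'   (computed from `c3`/`c4` when omitted).
#' @param mult Discrepancy multiplier.
#' @return Vector of merged values.
#' @export
merge_channels <- function(c3, c4, sd_c3 = sd(c3, na.rm = TRUE),
                           sd_c4 = sd(c4, na.rm = TRUE), mult = 3) {
  lim <- mult * (sd_c3 + sd_c4) / 2
  merged <- (c3 + c4) / 2
  disc <- !is.na(c3) & !is.na(c4) & abs(c3 - c4) > lim
  merged[disc] <- NA
  merged[is.na(c3) & !is.na(c4)] <- c4[is.na(c3) & !is.na(c4)]
  merged[is.na(c4) & !is.na(c3)] <- c3[is.na(c4) & !is.na(c3)]
  merged
}

.residualize <- function(values, covariates) {
  if (is.null(covariates) || !NCOL(covariates)) return(values)
  d <- data.frame(.y = values, covariates)
  fit <- lm(.y ~ ., data = d, na.action = stats::na.exclude)
  as.numeric(residuals(fit))
}

#' Sibling intraclass correlation from one-way ANOVA
#'
#' Residualizes the measure on the covariates (ordinary least squares),
#' then estimates the intraclass correlation from a one-way analysis of
#' variance over families: `(MSB - MSW) / (MSB + (k0 - 1) MSW)` with `k0`
#' the effective family size, i.e. the share of variance attributable to
#' family means.
#'
#' @param values Numeric measure per individual.
#' @param family Family identifier per individual.
#' @param covariates Optional data frame of adjustment covariates
#'   (e.g. age, sex).
#' @return A list: `icc`, `n_families`, `k0`.
#' @export
sibling_icc <- function(values, family, covariates = NULL) {
  y <- .residualize(values, covariates)
  ok <- !is.na(y) & !is.na(family)
  y <- y[ok]
  fam <- factor(family[ok])
  sizes <- table(fam)
  if (sum(sizes >= 2) < 2) {
    return(list(icc = NA_real_, n_families = length(sizes), k0 = NA_real_))
  }
  fit <- aov(y ~ fam)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  N <- length(y); a <- nlevels(fam)
  k0 <- (N - sum(sizes^2) / N) / (a - 1)
  list(icc = (msb - msw) / (msb + (k0 - 1) * msw),
       n_families = a, k0 = k0)
}

#' Covariate-adjusted test-retest correlation
#'
#' Residualizes each visit's scores on the covariates within study and
#' returns the Pearson correlation of the paired residuals.
#'
#' @param visit1,visit2 Paired per-individual scores.
#' @param covariates Optional data frame of covariates (same rows).
#' @return Pearson correlation (`NA` for fewer than 3 complete pairs).
#' @export
adjusted_retest_correlation <- function(visit1, visit2, covariates = NULL) {
  r1 <- .residualize(visit1, covariates)
  r2 <- .residualize(visit2, covariates)
  ok <- !is.na(r1) & !is.na(r2)
  if (sum(ok) < 3) return(NA_real_)
  cor(r1[ok], r2[ok])
}
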