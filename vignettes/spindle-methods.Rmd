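---
title: "Methods: automated N2 spindle characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated N2 spindle characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spindlekit` characterizes sleep spindles — thalamocortical sigma-band
(11–15 Hz) bursts of N2 sleep — from central-derivation EEG (C3/C4), with
the epoch hygiene, cardiac correction and per-individual aggregation
needed before spindle traits can be treated as stable phenotypes. This
vignette records the model, its assumptions, the parameters that matter,
and the design decisions taken where more than one reading was possible.

## The detection model

The primary detector convolves the 0.3–35 Hz band-passed EEG with a
complex Morlet wavelet

$$\psi(t) = (\pi F_B)^{-1/2}\, e^{2\pi i F_C t}\, e^{-t^2/F_B},
\qquad F_B = 2s^2,\quad s = \frac{n}{2\pi F_C},$$

whose modulus is an envelope of oscillatory activity centred on $F_C$.
The canonical analysis uses $F_C = 13.5$ Hz with $n = 7$ cycles — a
conventional compromise between time and frequency resolution; the
frequency sweep (8–18 Hz in 0.25 Hz steps, `"slow"` = 11 Hz, `"fast"` =
15 Hz) uses $n = 12$ for narrower frequency response at the cost of
temporal smearing. The envelope is smoothed with a 0.1-s moving average
and divided by its mean over all retained N2 samples for that
individual/channel. This adaptive baseline makes detection exactly
scale-invariant (multiplying the night by any constant changes nothing),
which is essential across recordings with differing amplifier gains, but
it also couples detectability to the amplitude distribution: raising
true spindle amplitudes raises detected density at the standard
threshold while *lowering* it in the low-amplitude band (see "threshold
variants").

Detection thresholds, on the ratio $x$ of smoothed envelope to baseline:
a core is a run with $x > 4.5$ lasting 0.3–3.0 s; the core is extended
contiguously while $x > 2$ and must reach 0.5 s total; events separated
by less than 1 s merge when the merged span stays under 3.0 s. The
wavelet's amplitude normalization is immaterial (the threshold is
adaptive), so no particular normalization constant is claimed. We extend
cores first and merge second; overlapping extended cores collapse into
one event before gap-merging.

Per event, on the 11–15 Hz filtered signal: amplitude is the largest
peak-to-peak difference between adjacent extrema; frequency is the modal
frequency of the zero-padded spectrum (0.25 Hz grid) refined by
parabolic interpolation of log power — short events have coarse native
resolution, and interpolation removes the grid bias; oscillations are
$\lfloor(\text{peaks}+\text{troughs})/2\rfloor$; symmetry maps the
location of the maximal peak-to-peak transition to $[0, 1]$. Events with
fewer than three extrema are flagged low-confidence. During the
frequency sweep the property band is 11–15 Hz while $F_C$ lies inside
it, else $F_C \pm 2$ Hz.

Threshold variants: $T_L$ flags $1 < x < 2$ and $T_A$ flags $x > 1$,
both keeping the duration and merge rules but (having no headroom above
their bands) no separate extension threshold.

## Epoch quality control

Filters run in a fixed order — stage/annotation, spectral aberrance,
iterative statistical filter, clipping, heart-rate plausibility — and an
epoch flagged on either EEG channel is removed for both, so all
downstream analyses share one epoch set. Specifics:

* Any scored arousal/movement/artifact intersecting an epoch, however
  briefly, removes the whole 30-s epoch (deliberately conservative).
* The aberrance filter compares per-epoch delta (1–4 Hz) and beta
  (15–30 Hz) Welch power to a local average over up to 15 contiguous
  epochs (7 either side). We include the index epoch in the local mean —
  the simplest reading of a centred 15-epoch window; ratios are 2.5
  (delta) and 2.0 (beta), strict.
* The iterative filter drops epochs beyond ±2 SD of the individual's
  mean on any of RMS, Hjorth activity, mobility, complexity, on either
  channel, recomputing mean and SD on survivors for three passes (a
  single pass under-removes when gross outliers inflate the variance).
  On a clean normal trait, three passes remove ≈ 10% per metric — the
  closed-form truncated-normal cascade gives 10.0%, and the test suite
  checks the implementation against it. Metrics with zero SD in a pass
  exclude nothing (otherwise constant metrics would drop everything);
  epochs with undefined metrics (degenerate, constant signal) always
  drop. Hjorth derivatives are plain first differences without rate
  scaling — the two ratio parameters are used as relative outlier
  metrics, for which the scaling cancels.
* Clipping is > 5% of samples tied (exact equality on stored,
  EDF-quantized values) at the epoch minimum or maximum.

## Cardiac interference

QRS complexes (0.06–0.1 s, i.e. spectrally near 16 Hz) leak into the EEG
roughly in the sigma band; the leak raises the adaptive baseline and
suppresses detected density. Correction: R peaks from a Pan-Tompkins
style detector (zero-phase 5–15 Hz band-pass, derivative, squaring,
150-ms integration, adaptive signal/noise thresholds, 250-ms refractory,
polarity-robust), then ensemble-average subtraction of the per-
individual/channel R-peak-locked mean EEG waveform. The 2-s signature
window spans $[-0.25, +1.75)$ s around the R peak: a biphasic QRS has
pre-R deflections (Q dip, R rise) that a purely causal window cannot
represent, and which would cap the removable artifact power well below
what the subtraction can otherwise achieve. Windows truncate where the
next beat's window begins, symmetrically in estimation and subtraction;
each signature point is the mean of however many intervals reached it.
The signature is estimated once from filtered N2 and applied night-wide
(no time-varying template). Epochs with estimated heart rate below 40 or
above 100 bpm (strict) are excluded; recordings without ECG proceed
uncorrected with a provenance flag. Sigma-band (12–15 Hz) Welch
coherence between EEG and ECG quantifies residual leakage.

## Spectra, dispersion QC and bilateral matching

Welch estimation uses 4-s Hann segments with 50% overlap (0.25 Hz
resolution), averaged within retained N2 epochs only; QC band power and
spectral band power use the same settings but are kept as two named
configurations. Band power integrates half-open bands
(slow 0.5–1, delta 1–4, theta 4–8, alpha 8–12, sigma 12–15, beta
15–30 Hz) so shared printed edges are not double-counted; absolute power
is natural-log transformed and relative power is the log share of the
six-band sum (the exponentiated shares sum to one by construction).

Per-epoch spindle counts from a well-behaved recording should be
near-Poisson; clustered spurious detections (movement, detached
electrodes) produce overdispersion. The dispersion index is sample
variance over mean; $(n-1)\,\mathrm{DI}$ is referred to the upper
$\chi^2_{n-1}$ tail, and channels with DI > 2 fail QC.

Bilateral matching pairs C3 and C4 events greedily by onset proximity
within 0.5 s, one-to-one, nearest first; the matching algorithm was an
open choice and greedy nearest-onset is the simplest order-independent
rule. Cross-frequency merging (sweep events, $F_C$ 10–16 Hz) unifies
events whose intersection exceeds 50% of their union or where more than
80% of either is covered by the other, closed transitively; merged
events span the union.

## Hypnogram rules

Cycle segmentation: a cycle needs ≥ 15 min of NREM sleep in an episode
beginning at N2 or N3 onset, then ≥ 5 min REM (first cycle: any REM). A
contiguous run of more than 15 min of wake or N1 — evaluated on the
combined W/N1 run — terminates the cycle (skipped REM). REM periods
tolerate interruptions of up to 15 min of NREM or wake. Where the rules
are silent we decided: a REM run before any qualifying NREM episode
starts no cycle; a sub-threshold REM episode is absorbed into the
ongoing NREM period; a final NREM episode of ≥ 15 min at the end of the
night counts as a terminal cycle without REM. Cycles five and above are
collapsed into a `"5+"` label for analysis. The implementation is
checked against an independently coded brute-force interpreter on
exhaustively enumerated short hypnograms and seeded realistic ones.

Ascending/descending N2: the contiguous non-N2 run immediately adjacent
to the epoch (up to 10 epochs, i.e. 5 min) is coded N3 = +1,
N1/W/R = −1 before the epoch and with reversed coding after; the epoch
score is the mean of the available sides (one-sided when only one flank
has adjacent non-N2 epochs — the rules are silent here, and using the
available side alone keeps edge epochs scoreable; such epochs are
flagged). Scores above +0.5 are ascending, below −0.5 descending, strict
inequalities. Epochs deep inside an N2 run have no adjacent non-N2
epochs and are "neither". Persistent sleep begins 10 min (20 epochs)
after the last wake. Clock time is minutes past 20:00 with epochs before
20:00 flagged for removal; lights-out defaults to the first staged epoch
when unannotated. Within-cycle position uses six 10-min bins plus a
`">60 min"` bin.

## Aggregation

Per measure: individuals need ≥ 10 clean epochs (5 min); values beyond
±3 SD of the cross-individual mean are set missing (single pass); C3/C4
merge as the average unless they differ by more than three times the
mean of the two channels' cross-individual SDs (computed within study by
default — the within-individual alternative is undefined for a single
night). NREM4 sub-analyses use only N4 epochs flanked by two N4 epochs
on each side. The sibling intraclass correlation residualizes on
covariates by ordinary least squares (listwise deletion) and applies the
one-way ANOVA estimator with the effective family size $k_0$;
test–retest correlations are Pearson correlations of per-visit OLS
residuals. Association modelling beyond this (age curves, mixed models)
is deliberately out of scope: the package emits tidy per-epoch and
per-individual tables for standard statistics tooling.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
not real physiology: stage-labelled hypnograms with exactly recoverable
cycle structure; two EEG channels of spectrally shaped Gaussian noise
(default exponent 1, RMS 10 µV — a stationary 1/f floor with a realistic
sigma-band noise level); spindle bursts arriving as a homogeneous
Poisson process within N2 at 2/min by default, with frequency
13.5 ± 0.5 Hz, peak-to-peak amplitude 30 ± 5 µV, duration 1.0 ± 0.25 s
(truncated to 0.5–2.5 s); a QRS train at 60 bpm with jittered R–R
intervals, sample-aligned true R times, and leakage into the EEG at a
configurable gain; and per-channel event rates with a configurable
bilateral sharing probability (default 0.5, onset jitter under 0.5 s).

The default burst envelope is a Tukey window (flat top, 30% cosine
tapers): its above-threshold span tracks the nominal duration and its
maximal peak-to-peak excursion equals the configured amplitude, so
ground truth and detector output are commensurable. A Gaussian envelope
with a skew option exists to exercise the symmetry statistic; with
peaked envelopes the detector's thresholded span is systematically
shorter than the support, which is a property of threshold detection,
not an error. What the generator does **not** emulate: non-stationary
background (drowsiness, arousals), slow oscillations and their coupling
to spindles, age or topography structure, real artifact morphology.
Passing tests therefore demonstrate correctness of the rules and
calibration of the statistics under the stated model — not detector
validity on clinical data.

For parameter-recovery checks, the cohort draws per-individual rates
(1–3/min) and amplitudes in the clearly detectable regime (28–45 µV
means with 2 µV within-individual SD): the adaptive core threshold
corresponds to roughly 21 µV peak-to-peak over the default background,
and amplitude distributions straddling the threshold re-introduce the
amplitude/detectability confound that the sweep analyses measure
deliberately.

## Numerical choices

* **Resampling** is Fourier-domain rational resampling (spectrum
  truncation/zero-padding): exact amplitude for band-limited content,
  intrinsic anti-aliasing, duration preserved within a sample. A
  polyphase FIR design was considered and rejected after its passband
  ripple (a few percent) exceeded the 1% amplitude contract.
* **Band-pass (0.3–35 Hz)** is a cascade of 4th-order Butterworth
  high- and low-pass sections, each applied forward–backward: zero
  phase, and numerically far better conditioned than a single
  transfer-function band-pass with a 0.3 Hz edge at 128 Hz.
* **Property-extraction band-pass (11–15 Hz)** is a Fourier-domain
  brick-wall with 1-Hz raised-cosine transitions: a Butterworth cascade
  applied forward–backward attenuates the passband interior enough
  (gain ≈ 0.6 at 13.5 Hz) to corrupt peak-to-peak amplitudes.
* **Welch** uses the periodic Hann convention; values are cross-checked
  in the tests against frozen reference values from an independent
  implementation.
* **Smoothing** uses edge-aware normalization (partial windows average
  the samples that exist).
* Degenerate inputs: constant epochs have undefined Hjorth ratios and
  are dropped; empty masks and missing ECG are explicit errors or
  flagged pass-throughs, never silent.
* RMS-detector windows are non-overlapping 0.25-s blocks (the
  overlapping alternative is unstated in the source detector; fixed
  blocks keep the 95th-percentile flagging fraction exact).

## Problem sizes in the test suite

The suite validates at desk scale: 60 synthetic minutes of N2 for
detector fidelity, 30 for cardiac correction, ten 15-minute individuals
for the amplitude sweep, twenty ~35-minute individuals for cohort
recovery, 10⁴–10⁵ draws for the statistical calibrations, and
exhaustive rule-oracle enumeration up to length-8 hypnograms plus seeded
realistic ones. These sizes give the calibration statistics sampling
errors comfortably inside the asserted tolerances.

## Known limitations

Single-channel-pair focus (C3/C4) without re-referencing; no slow
oscillation coupling; the cycle and ascending/descending rules encode
one defensible reading of conventions that vary across laboratories; the
cardiac template is night-stationary, so beat-morphology drift leaves
residual; EDF support covers continuous recordings only. The headline
epidemiological quantities of large cohort studies (mean densities,
test–retest correlations, heritabilities) depend on access-controlled
recordings and are not reproduced here; the package reproduces the
*method* and calibrates it on ground-truthed synthetic data.
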