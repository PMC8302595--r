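---
title: "Methods: quantifying induced epileptiform activity and calcium-ECoG phase locking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying induced epileptiform activity and calcium-ECoG phase locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphase)
```

## Scope and data model

`epiphase` quantifies optogenetic seizure-induction experiments in which a
light pulse triggers generalized epileptiform activity (EA), recorded as
ECoG, together with single-unit spiking and one-photon calcium imaging. All
signals are uniformly sampled `time_series` / `multi_trace` objects; time is
in seconds, sample *k* (0-based) lies at `t0 + k/fs`, and every analysis
window is half-open `[start, stop)`. Half-open windows remove all
double-counting ambiguity: windows tile, and `segment()` is idempotent.
Missing samples are rejected rather than imputed — the analysis chain
assumes gapless recordings, and silent interpolation would bias the spectral
and PTA statistics. Plain EDF (16-bit, no annotations) is supported for
ECoG interchange; delimited tables carry everything else.

## ECoG band power

Band power uses a short-time Blackman-tapered FFT: by default ten windows of
512 samples with 50 % overlap, anchored at the start of the analysis
interval. At the 400 Hz ECoG sampling rate this spans exactly
`(512 + 9*256)/400 = 7.04` s, the package's standard analysis epoch. Per
window the mean is removed, the Blackman taper applied, and a one-sided
periodogram computed with power-spectrum scaling `|X|^2 * s / (N * sum(w^2))`
(s = 2 except at DC/Nyquist). Two properties motivate this scaling:

- the bins sum exactly to the taper-normalized mean square of the window
  (a Parseval identity, tested to 1e-6 relative), so band powers over a
  partition of `[0, Nyquist)` are additive; and
- a unit-amplitude sinusoid totals ~0.5 independent of taper choice, so
  *ratios* — the quantity actually reported — are scaling-independent.

Bands are half-open (`theta [4, 8)`, `alpha [8, 13)`, `beta [13, 30)` Hz) so
adjacent bands partition the axis. Stimulation-epoch power is normalized as
a plain ratio to the same band's baseline power (no dB, no percent change);
a unity ratio means "unchanged from baseline". Whether the windows should be
anchored at stimulus onset or centered on it is not determined by the
source conventions; anchoring at the interval start is the default and the
layout is fully parameterized.

## Morlet theta tracking

Time-resolved theta power convolves the signal with the complex Morlet
wavelet `psi(t) = (pi*fb)^(-1/2) exp(2i*pi*fc*t) exp(-t^2/fb)` with
`fc = 4` Hz and bandwidth parameter `fb = 0.5` — the classic
`cmor`-convention parameterization, which is the most literal reading of a
"bandwidth 0.5, center 4 Hz" Morlet specification; both parameters are
exposed. Power is the squared coefficient magnitude ("power" is taken as
squared magnitude, not amplitude). The kernel is truncated at
`|t| <= 5*sqrt(fb/2)`, the convolution uses mean padding, and samples within
half the truncated support of an edge are flagged unreliable rather than
dropped. A stationary unit 4 Hz tone yields interior power 0.25 with
< 1 % ripple; power scales exactly as amplitude squared.

## EA episodes

Discrete epileptiform peaks are detected threshold-based: the default
threshold is `median + 5*MAD` of a caller-chosen pre-stimulus baseline
(robust against the EA's own outliers, one tunable constant), a peak is the
maximum sample of each contiguous supra-threshold run (ties to the earliest
sample), and runs closer than a 0.1 s refractory period — half a theta
period at typical ~5 Hz discharge rates — merge into the larger one. Peak
counts are monotonically non-increasing in the threshold.

Episode boundaries in the source experiments are scored visually; the
automated stand-in `suggest_ea_bounds()` takes the first supra-threshold
peak after stimulation as onset and ends the episode at the last
supra-threshold run followed by at least `quiet_gap` (default 2 s) of quiet
signal. It can therefore only be validated against synthetic ground truth,
not against visually scored episodes. On the generator's conditions
(peak SNR 10, 5 Hz peak rate) the mean absolute onset error is ~0.2 s —
dominated by the exponential waiting time to the first discharge, mean
`1/peak_rate` — and the mean absolute duration error is ~0.4 s.

Delay is EA onset minus the onset of the latest stimulation at or before
it; duration is onset to offset. Severity uses the fixed 5-level modified
Racine rubric, which the package only encodes and validates — scoring
itself requires video and stays a manual input. Pulse-train protocols
(e.g. 40 Hz for 10 s, 13 ms on / 12 ms off = 400 intervals) are validated
against the declared period to 1e-9.

## Calcium-ECoG phase locking

The core statistic asks, per imaged cell, whether calcium activity is
synchronized with the discrete ECoG discharges:

1. **PTA.** Segments of the cell's trace ±500 ms around each ECoG peak
   (nearest-sample snapped to the calcium grid; peaks whose window leaves
   the recording are dropped and counted) are averaged, and the average's
   own mean subtracted. Subtraction makes the statistic invariant to
   constant offsets.
2. **Peak ratio.** Max − min of the averaged trace within ±200 ms (closed
   interval) — the effect size.
3. **Shuffled null.** 1000 surrogate PTAs are built from trigger times
   drawn uniformly *with replacement* between the first and last real ECoG
   peak (the simplest exchangeable null preserving the number of triggers),
   snapped to the same grid, and pushed through exactly the same PTA and
   ratio code path, including the edge-retention rule. `sigma` is the
   population SD of the 1000 surrogate ratios — the surrogates *are* the
   null sample, not an estimate of a larger one.
4. **Decision.** `z = (ratio - mu)/sigma`; a cell is phase-locked iff
   `z > 1.96`, strictly. A constant trace gives a degenerate null
   (`sigma = 0`) and an explicit error rather than a silent verdict.

The seed protocol is part of the contract: after `set.seed(seed)`,
replicate *r* consumes the *r*-th block of `n_peaks` uniform variates. This
makes the null bit-reproducible and lets an independently coded brute-force
implementation agree *exactly*, which the test suite and acceptance script
both verify at 50 shuffles.

Calibration on synthetic data uses EA windows of ~27 s carrying ~40-50
discrete peaks (≈1.7 Hz), matching the per-episode counts of
threshold-detected peaks in the motivating experiments, with cells pooled
over several episodes as cells are pooled over episodes (and animals) in
practice. Under these conditions uncoupled cells (background transients at
0.2 Hz, noise SD 0.2) are flagged in ~3-6 % of cases — above the nominal
one-sided 2.5 % because the range statistic's null is right-skewed, within
the 8 % budget — while cells coupled at probability 0.9 with 20 ms jitter
and unit-amplitude transients (5x the noise SD) are flagged essentially
always. A caveat discovered during design: at the generator's default 5 Hz
peak rate the ~1 s GCaMP-like transient decay piles up between discharges
and the PTA loses contrast, so dense-discharge episodes genuinely carry
less per-peak phase information; the statistic's power is a function of
discharge spacing relative to indicator kinetics, not of coupling alone.
Increasing coupling jitter from 20 ms to 0.5 s strictly lowers the mean z.

Calcium AUC integrates the raw trace (trapezoid) over 50 s from
stimulation onset; no baseline subtraction is applied by default (an
optional pre-stimulus-mean subtraction flag exists) because inventing
preprocessing the source analysis does not state would change the numbers
silently. The integration range is closed so a constant unit trace over
50 s yields exactly 50.

## Spike trains and behavior

Spike detection mirrors the peak detector (threshold magnitude, polarity
flag, extremum timestamp, 1 ms refractory merging). PSTHs use half-open
contiguous bins (1 s for display, 3 s for criteria) and conserve spike
counts by construction. The responsiveness rule computes per-trial pre- and
post-stimulus mean rates over 12 s windows (3 s bins tile them exactly, so
binned and unbinned means coincide) and calls a cell responsive when the
post mean strictly exceeds the pre mean in at least 2 trials; "increased"
has deliberately no effect-size floor (a floor is exposed as an option).
Note the rule is permissive by construction: with no rate step at all,
6-trial experiments satisfy it ~85 % of the time
(P(post > pre) ≈ 0.46 per trial, so ≥2 successes out of 6 are likely); it
is an inclusion filter, not a hypothesis test. A 1→5 Hz step is detected
essentially always.

Input resistance is the least-squares I-V slope over the closed
[−100, −40] pA range; mV/pA equals GΩ, reported in MΩ. The
discrimination index is `100*(t_rel - t_unmoved)/(t_rel + t_unmoved)`,
antisymmetric and bounded in ±100, with training-phase exclusion above 20.

## The synthetic generator and what passing tests mean

`make_ecog()` shapes white Gaussian noise to a `1/f` spectrum in the
frequency domain and renormalizes to the target SD exactly, then adds
biphasic peaks — derivative-of-Gaussian waveforms (zero mean, sharp), time
shifted so the positive extremum (+1 before scaling) sits exactly on the
truth peak time, making "maximum of the peak" unambiguous for recovery
tests. `make_calcium()` sums unit-peak double-exponential transients
`(1 - e^(-t/rise)) e^(-t/decay)` (rise 0.1 s, decay 1.0 s) at coupled
and/or background Poisson event times plus white noise; coupled events
jittered outside the EA window are kept — the PTA edge rule handles them.
One integer seed per generator call fans out to per-cell substreams, so
outputs are byte-reproducible while cells stay independent. Defaults that
the source material does not pin down (calcium rate 20 Hz, background
transient rate 0.2 Hz, peak amplitude/rate statistics) were chosen once as
field-typical values and are documented as assumptions, exposed as
parameters.

The generator reproduces the statistical structure the analysis *assumes*:
stationary 1/f background, discrete stereotyped discharges, linear
transient summation, homogeneous Poisson spiking. It does not emulate
motion artifacts, photobleaching, ΔF/F preprocessing, electrode drift,
interictal/postictal structure, or cell-extraction crosstalk — so passing
tests demonstrate correctness of the statistics under their own
assumptions, not robustness to those real-data pathologies.

## Problem sizes and numerical choices

Validation suites use 200 uncoupled cells (4 episodes x 50 cells) and 100
coupled cells (2 x 50) at 1000 surrogates per cell, 50-seed replicates for
EA recovery and responsiveness, and 200-seed replicates for spectral
moment checks — sizes at which the binomial/Poisson standard errors are
several times smaller than the margins being asserted. Sampling-rate
inference tolerates 1e-6 relative jitter on the median step and fails
loudly beyond it; EDF round-trips are exact within 16-bit quantization of
the declared physical range; peak snapping uses `round()` (banker's
rounding at exact half-samples, deterministic); all seeds are plain R
integer seeds.

## Known limitations

- EA on/offsets from `suggest_ea_bounds()` are a proxy for visual scoring
  and inherit the first-discharge waiting-time bias described above.
- The phase-locking null draws triggers uniformly without excluding the
  vicinity of real peaks; with strongly coupled cells the null is thereby
  slightly inflated (conservative for detection, anticonservative for
  effect-size comparisons across episodes).
- No multiple-testing correction is applied across cells, matching the
  source convention; the per-EA locked percentage should be read
  accordingly.
- The Racine mapping of intermediate stage groupings ("stage 1-2/3-4") is
  passed through unmodified; the package does not reinterpret scores.
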