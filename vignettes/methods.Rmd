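---
title: "Measuring event-related high-gamma dynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring event-related high-gamma dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`erhg` quantifies task-related cortical activation and deactivation from
intracranial EEG as percent change of high-gamma (65–95 Hz) band amplitude,
time-locked to the phrase boundaries of spoken three-phrase questions. This
vignette is the package's account of the science: the signal model, the
statistics and their assumptions, what the synthetic cohort generator does
and does not emulate, and the numerical and design decisions that were
genuinely open.

## Signal model and time–frequency transform

The recorded field potential is modeled as broadband 1/f background plus
mains line noise plus a band-limited high-gamma component whose amplitude
envelope carries the neural signal of interest. The analysis readout is
amplitude (not phase): complex demodulation multiplies the signal by
$e^{-2\pi i f t}$ for each frequency center $f$ on a 5-Hz grid, low-pass
filters the product, and reports $2\,|\cdot|$ every 10 ms, so a unit
sinusoid at a bin center yields unit amplitude. High-gamma amplitude is the
unweighted mean over the seven bins with centers in the closed interval
[65, 95] Hz; endpoint inclusion is configurable because "65–95 Hz" is
ambiguous about endpoints, and the closed convention (7 bins) is the
default.

Numerical implementation: one forward FFT per channel; per frequency bin a
circular rotation of the spectrum (exact to within the FFT grid spacing,
< 0.01 Hz here); multiplication by the real, zero-phase frequency response
of a symmetric Hamming-window FIR kernel (order 660, normalized to unit DC
gain so amplitude calibration is exact); and a band-limited inverse FFT
straight onto the 10-ms output grid. This is algebraically the textbook
"modulate, low-pass, rectify" demodulator, with zero net phase shift by
construction. The filter's −6 dB point sits at half the 5-Hz bin spacing;
with a 661-tap kernel at 1,000 Hz the attenuation at the neighboring bin
(5 Hz) exceeds 20 dB while mains components 15+ Hz away are suppressed far
below 1% — which is why a 50/60-Hz line leaves the 65–95 Hz readout
essentially untouched (tested to < 1%). The first and last filter
half-lengths (330 ms) are marked `NA` rather than extrapolated; this also
covers the circular wrap of the FFT implementation. Padding is to 2-3-5
smooth lengths, so transform cost is near-linear in recording length.

Assumption to note: averaging sub-band envelopes is not the same estimator
as the wideband Hilbert envelope — for stochastic band content it sits lower
by roughly $\sqrt{K}$ for $K$ independent sub-bands, and fluctuates more
slowly. Percent change is invariant to that scale factor, which is the
point of the baseline normalization. On narrowband (single-bin) signals the
two agree within 5% RMS, and that equivalence is what the oracle tests
assert.

## Percent change and epoching

Per electrode, the baseline $B$ is the mean band amplitude over the
$[-600, -200)$ ms pre-stimulus windows of all correct trials, and every bin
becomes $100\,(A-B)/B$. The baseline is computed per electrode across
trials by default: a single 400-ms window estimates a Rayleigh-distributed
amplitude mean from ~40 bins and is high-variance at the single-trial
level; pooling across trials stabilizes it. The per-trial alternative is
implemented (`baseline_per = "trial"`) and tested, since the choice is not
dictated by the method. The baseline window is half-open on bin centers;
time stamps are bin centers; event alignment takes the nearest 10-ms bin
with ties toward earlier — all conventions that had to be fixed somewhere
and are documented here.

Trials without a correct overt answer are excluded before any statistic.
Trial-averaging happens within electrode first; the electrode is the
statistical unit everywhere downstream, matching the idea of pooling "all
available electrode sites" per ROI across patients. Bins without recorded
coverage are missing (`NA`), never zero-filled, and trial averages are
NA-aware so partial coverage near recording edges degrades gracefully
rather than biasing toward zero.

## Pointwise statistics

The permutation test flips the sign of whole electrode traces (one draw per
electrode per permutation, shared across bins). Exchangeability is at the
electrode level under the null of zero mean modulation; flipping whole
traces preserves each electrode's temporal autocorrelation, so the joint
null across bins is honest. P-values use the add-one convention
$p = (1 + \#\{|\bar x^*| \ge |\bar x|\})/(n_{perm}+1)$, so $p = 0$ is
unattainable with finite permutations. BH-FDR is applied across time bins
within one ROI × sentence type × anchor family (451 bins for the default
4,500-ms epoch); the family scope is configurable because the method fixes
the family size, not whether it spans ROIs.

The duration criterion keeps maximal significant runs whose extent — bin
count × 10 ms, so six consecutive bins span 60 ms — reaches 60 ms. The
common gloss "at least four 65-Hz cycles" would give 61.5 ms; the stated
60 ms is implemented and the discrepancy noted. Runs are split at sign
changes of the mean so each epoch is purely augmentation or suppression.

The slope of rise is the OLS slope of the ROI mean trace in a centered
600-ms sliding window, in %/s, computed as a convolution (exactly the
per-window OLS estimate); CIs come from a percentile bootstrap over
electrodes, and argmax ties break to the earliest center.

## Window contrasts and the mixed model

Sentence types are contrasted in eleven 100-ms windows. The default set
takes, for each phrase, the 100 ms before/after its onset and offset and
omits the window before the 1st phrase onset (it overlaps the baseline),
giving labels 1b–3d. The exact placement is configurable: the eleven
windows are referenced by label in the source analyses but never fully
enumerated, so the default is this package's explicit, documented choice
and should not be over-interpreted.

The studentized bootstrap resamples electrodes within group and bases both
the two-sided p (add-one) and the 95% CI on the bootstrap distribution of
the t-like pivot; 2,000 replicates by default (the replicate count is not
prescribed by the method; 2,000 makes the Monte-Carlo error on a 0.05-level
p about 0.005). FDR is applied across the 11 windows × ROIs family.

The mixed model is fit by REML with a patient random intercept and
Satterthwaite degrees of freedom for the sentence-type term (the estimator
is not prescribed; REML + Satterthwaite is the field default via lmerTest).
The observation unit is the electrode × sentence-type window mean —
"high-gamma amplitude at a given window at a given ROI" is unit-ambiguous,
and the electrode level matches the rest of the pipeline; patient-level
aggregation can be had by averaging before the fit. Covariates constant
across the (possibly small) patient sample are dropped from the fixed
effects as inestimable; singular fits are flagged and reported, never
silently discarded. The detectable-effect-size helper solves the
noncentral-t power equation for a one-sample two-sided t test; it is
provided as a generic power tool.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the statistical structure the analysis relies on:

* **Stimuli.** Phrase/gap durations drawn per sentence type from normals
  truncated at ±3 SD and > 0 (concrete-first: 546±80, 168±57, 538±83,
  155±49, 410±50 ms; wh-first: 436±56, 181±62, 487±100, 157±60, 554±75 ms);
  48 trials per type per patient in pseudorandom order with no two
  consecutive trials sharing a wh-word; correctness i.i.d. Bernoulli(0.979);
  response latency log-normal with median 1.5 s after sentence offset.
* **Cohort.** Patient covariates centered on a drug-resistant epilepsy
  surgical population (age 27.5±10.8 y, onset 13.8±11.2 y, 43.5% female,
  ~3.2 antiepileptic drugs, FIQ 81.7±14.2, 61% congenital lesions);
  hemisphere sampling 11:9:3 left:right:both; the default electrode layout
  places 626 left / 493 right analyzable sites over 8 ROIs per hemisphere
  plus a catch-all.
* **Signals.** 1/f^α background (α = 1 by default, configurable; the fitted
  periodogram slope is tested to ±10%), 50- or 60-Hz line noise, and a
  65–95 Hz narrowband Gaussian carrier amplitude-modulated by trial-locked
  ramped-boxcar effects. The carrier owns the high-gamma band — the
  background is notched out of 65–95 Hz — so the stored envelope is an
  *exact* oracle for the band-amplitude readout, which is the property the
  recovery tests exploit. The periodogram-slope check therefore fits around
  the notch. Effect ramps flank the stated interval on the outside, so a
  "300-ms, +10%" effect holds full amplitude for its whole 300 ms.
* **Unstated conditions, chosen once.** Inter-trial interval uniform 3–5 s
  between response onset and the next sentence onset (with a 2-s lead-in),
  keeping the 400-ms baseline clear of effects; a per-patient Gaussian
  shift on effect amplitude (`patient_effect_sd`, default 0) to exercise
  the mixed model's random intercept.

Not emulated: acoustic speech content (phrases are timing events), seizure
or spike artifacts beyond the exclusion-status flag, electrode geometry or
volume conduction, non-stationary background, and any spatial correlation
between electrodes. Passing recovery tests therefore demonstrates that the
pipeline's estimators and error control behave as designed under the
assumed signal model — not that real cortical high-gamma meets those
assumptions, and not that any particular empirical percent-change value
from patient data is reproduced.

## Problem sizes and numerical choices in the validation studies

The test and acceptance studies size their simulations to be decisive while
staying light: null calibrations use 200 replicates (25 electrodes for the
permutation test; 20 per group, 2,000 bootstrap replicates for the
contrast), checked against the binomial 95% band around 0.05. Parameter
recovery runs 100 full signal-level replicates of a 30-electrode ROI with
8 trials per sentence type and a −600..1500-ms epoch; an injected +10%,
300-ms augmentation must be detected as an overlapping ≥ 60-ms epoch in
≥ 95% of replicates, with the mean recovered peak within ±2 percentage
points and the slope argmax within ±50 ms of the same slope estimator
applied to the noiseless ground-truth profile (the low-pass envelope
smoothing biases the recovered peak slightly below the injected value —
about −1 point at these settings — which the tolerance absorbs). Mixed-model
coverage uses 200 replicates of 8 patients × 8 electrodes with a +5% effect,
3% patient-intercept SD and 5% residual SD, simulated at the window-value
level, where the model's assumptions hold exactly and coverage isolates the
inference machinery.

## Known limitations

* The demodulator's edge invalidation (330 ms per side at default order)
  means very short recordings lose a noticeable fraction of bins; the
  generator's 2-s lead-in makes this moot for simulated data.
* Percent change with an electrode-level baseline ties all trials to one
  normalization constant; slow drifts in baseline amplitude across a
  session would leak into every trial equally.
* The bootstrap and permutation tests treat electrodes as exchangeable and
  independent; spatially correlated electrodes (not simulated) would make
  both anticonservative.
* EDF output quantizes to 16 bits over a per-channel symmetric range; for
  signals with rare large excursions the quantization step grows
  accordingly.
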