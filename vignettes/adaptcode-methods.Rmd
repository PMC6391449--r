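---
title: "Models and methods behind adaptcode"
author: "adaptcode maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adaptcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptcode)
```

## The scientific problem

Neurons in early visual cortex must encode a rapidly changing stimulus
dimension (grating orientation, here a new random orientation every two
monitor frames, 2/120 s) while other dimensions — mean luminance and
contrast — also change, on a slower timescale (every 5 s).  Luminance and
contrast strongly drive firing rates, so from the point of view of
orientation coding they are nuisance variables; after each switch the
neuron adapts, and its ability to transmit orientation information changes
during that adaptation.  `adaptcode` implements the complete analysis chain
for this paradigm: stimulus-schedule generation, a generative spiking model
used as ground truth, orientation reverse correlation, mutual information
with bias correction, peri-switch rate and Fano-factor dynamics, linear
population decoding, gain/offset tuning-modulation analysis, and the
psychophysical counterpart (orientation discrimination thresholds early vs
late after a switch).

Because no recordings ship with the package, every estimator is validated
by parameter recovery against the built-in simulator: the simulator's
parameters are the ground truth, and the tests demand that each estimator
recovers the parameters it targets.

## The switching stimulus

`generate_schedule()` tiles a session into contiguous 5-s epochs, each
drawn i.i.d. from the four luminance-contrast conditions (70 or 140 cd/m2
crossed with 35% or 65% contrast), and fills each epoch with 16.67-ms
grating frames whose orientation (12 values, 0-165 deg), phase (8 values)
and spatial frequency are drawn i.i.d. per frame.  Conventions that matter
downstream:

* time is 0-based seconds, and every analysis window is half-open `[a, b)`;
* the frame duration is stored exactly as `2/120` s, not a rounded 16.7 ms;
* because epochs are i.i.d., all 16 ordered condition transitions occur,
  each with long-run probability 1/16; 12 of them change at least one
  parameter and 8 change exactly one.  Analyses that compare adaptation
  directions use those eight single-parameter switches, addressable either
  by type (`"contrast_inc"`) or by ordered pair (`"L70C35->L70C65"`);
* a 60-min session has 720 epochs, hence at most 720 switches;
* the default spatial frequency is a single value (0.25 cpd), configurable
  to the one-to-three values a real session would use.

The early and late adaptation phases are `[0, 1.6)` s and `[3.4, 5.0)` s
after a switch (`adaptation_phase_window()`), each containing 96 frames.

## The generative neuron model

`neuron_params()` describes a linear-nonlinear-renewal neuron:

```
rate(t) = offset[c(t)] + g(t) * drive(t)
drive(t) = mean over s in [t - latency - w/2, t - latency + w/2) of
           exp(kappa * (cos(2 * (theta(s) - theta_pref)) - 1))
```

Orientation has period 180 degrees, so tuning lives on doubled angles; the
tuning factor is normalised to peak at 1, making `steady_gain` the peak
drive in spikes/s.  The temporal kernel is deliberately simple — a boxcar
of width `kernel_width` centred `latency` seconds back — chosen so that the
reverse-correlation peak lag equals the latency and the half-maximum
temporal width equals `kernel_width`, which is exactly what the kernel
feature recovery tests check.  A biphasic impulse response would change the
constants, not the logic.

Within each epoch the gain relaxes exponentially towards the steady gain of
the current condition, `g(t) = g_ss + (g_start - g_ss) exp(-(t - t_s)/tau)`.
Two regimes are supported for `g_start`:

* **continuous** (the `neuron_params()` default): the post-switch gain
  starts at the pre-switch end gain;
* **transient multipliers** (`transient =`): the gain is reset to
  `transient[switch_type] * g_ss` at matching switches.  The population
  sampler `sample_neuron_params()` uses `default_transients()` —
  overshoot (1.8) after contrast increments, 1.7 after luminance
  decrements, undershoot (0.45/0.55) after luminance increments and
  contrast decrements — emulating the transient rate dynamics seen in this
  paradigm: a jump followed by exponential relaxation to an intermediate
  plateau, with the direction depending on the switch.

Default steady gains order the four conditions as the steady-state data
order them (strongest drive at high contrast/low luminance, weakest at low
contrast/high luminance), scaled per neuron by a lognormal factor
(sd 0.3).  Time constants are asymmetric: contrast decrements (1.2 s)
slower than increments (0.6 s), luminance increments (1.0 s) slower than
decrements (0.5 s).

Spiking: Poisson neurons (`dispersion = 1`) are sampled exactly by thinning
against the rate's upper bound.  For `dispersion != 1` the package
time-rescales a gamma-renewal process (ISI shape `1/dispersion`) through
the numerically integrated rate (1 ms grid).  Renewal-count Fano factors
converge to the ISI CV^2 only when counting windows hold many events, so
the Fano calibration uses 1-s windows at ~50 spikes/s, where a
dispersion-0.5 neuron measures 0.5 within a few percent; in 50-ms windows
at low rates any renewal process is pushed towards 1 by count
discretisation, which is a property of the statistic, not of the
simulator.

What the simulator does *not* emulate: correlated variability across
neurons (the decoder shuffles trials per neuron anyway), biphasic
post-luminance-switch responses, and spike-sorting artefacts.  Passing
recovery tests therefore demonstrate estimator correctness, not robustness
to those features of real recordings.

## Reverse correlation and selectivity

`reverse_correlate()` counts, for each spike and each lag on the exact
grid -6 to +250 ms in 0.5 ms steps (513 lags), the orientation on screen
`tau` earlier, ignoring phase and spatial frequency, and normalises each
lag column to the probability surface `p(theta, tau)`.  Only spikes whose
entire lag range lies inside the frame sequence are used, so each column of
raw counters sums exactly to the number of spikes used.  The optimized
per-lag counting path is tested for exact equality against a naive
per-spike loop.

Feature conventions (each one a decision the data cannot make for us):

* the acausal lags (`tau < 0`) define the baseline; their pooled mean is
  exactly 1/12 after normalisation and their SD estimates the counting
  noise;
* the peak lag maximises `max_theta p - min_theta p` over causal lags,
  ties broken toward the earliest lag;
* the temporal width is the half-maximum span of
  `p(theta_pref, tau) - baseline`, with linear interpolation between lag
  samples; baseline subtraction is configurable
  (`subtract_baseline = FALSE`) since either convention is defensible;
* tuning curves at the peak lag are fitted with a difference of two von
  Mises functions on doubled angles (multi-start over all 12 grid
  orientations, concentrations bounded in (0, 50], non-negative scale
  factors), and the preferred orientation is the argmax of the fitted
  curve.  The F test against a flat line uses the standard nested
  least-squares form with 6 extra parameters and 12 - 7 residual df.

A neuron is orientation selective when (1) the peak probability exceeds
baseline mean + 3 SD, (2) the fit beats the flat line at p < 0.05, and
(3) the fitted full-width-at-half-height bandwidth lies in 20-95 degrees.

## Mutual information

The plug-in estimator uses empirical `p(theta)`, `p(R | theta)` over raw
integer counts (counts above the 99.5th percentile merged into one bin),
with `0 log 0 = 0`.  The count window defaults to 50 ms placed over the
information-carrying lag (`offset_s = peak time - width/2`, 25 ms for the
default 50-ms-latency neuron).

Plug-in MI is positively biased at finite n.  The correction subtracts the
mean MI over 100 shuffles of the orientation labels — a null-information
estimate of the bias.  `mi_corrected` is floored at zero (an information
quantity); `mi_debiased` keeps the unfloored value, which is the right
object to average when testing that independent data recenter on zero.
The shuffle estimate measures bias under independence, so it slightly
overcorrects strongly informative channels at small n; the error shrinks
as 1/n and is negligible at the presentation counts this paradigm
provides (hundreds per orientation per window).  `mi_timecourse()` applies
the estimator in six 833-ms windows spanning the epoch and reports the
firing rate alongside for rate-MI correlation.

## Rate dynamics and variability

`switch_psth()` bins spikes in 50-ms bins from -5 to +5 s around every
repetition of a switch, ignoring all other stimulus dimensions.
`shuffle_normalize()` divides by the mean PSTH of 50 surrogate trains whose
spike times are redrawn uniformly over the session — the flat expectation
under no event locking — yielding a unitless modulation around 1.  Gaussian
smoothing (`smooth_psth()`) exists for display only; every statistic is
computed unsmoothed.  `fit_decay()` fits `a + b exp(-t/tau)` to the
normalised rate on `[0.05, 5)` s (the first bin is skipped as transient),
multi-start over tau in {0.1, 0.5, 1, 2} s, flagging non-convergent or
low-amplitude (|b| < 0.05) fits where tau is unidentifiable.

`fano_series()` slides a 50-ms window in 10-ms steps across +/-0.5 s around
the switch and reports the unbiased (n-1) variance over mean of
per-repetition counts; windows with zero mean are undefined rather than
zero.

## Population decoding

`build_response_matrix()` pools the presentations of each orientation
across all repetitions of a switch inside a phase window, counts spikes in
a 15-ms window per neuron (positioned, by default, to cover the typical
kernel peak at ~50 ms; the position is a parameter), permutes trials
independently per neuron (removing spike-count correlations), and truncates
to the minimum per-orientation count.  Decoding uses 15 runs of: random
neuron subsample (50 by default), stratified 70/30 split, z-scoring with
training-fold statistics only (the leakage-free choice), and a linear
classifier.  The default classifier is a linear discriminant with
diagonal-shrinkage pooled covariance (`lambda = 0.1` plus an absolute
floor), written in-package because the shrinkage is essential at 50
neurons by a few hundred trials; a linear SVM is available and agrees
within a few percentage points.  Shuffled-label controls must sit at the
1/12 chance level.

On default simulations the early/late comparison reproduces the
adaptation geometry: accuracy early > late after contrast increments
(overshoot decaying) and early < late after luminance increments
(undershoot recovering).

## Gain and offset modulation

`tuning_curves()` locates the peak response time from per-orientation
PSTHs (0-200 ms after frame onset, pooled across both phases so early and
late share one window) and averages rates in a 20-ms window centred there.
`gain_offset_regression()` regresses late on early: slope = multiplicative
gain change, intercept = additive change.  The late-on-early direction
makes "gain decreased during adaptation" read as slope < 1.  Note that
ordinary least squares on noisy early-phase curves attenuates the slope
(regression dilution); at the repetition counts of a full-length session
(several hundred presentations per orientation) the attenuation is a few
percent, which is why the recovery tests run at that scale.

`compare_models()` fits four single-peaked von Mises models to the stacked
early/late curves (shared curve; independent curves; shared gain/free
offsets; shared offset/free gains — the constrained pair shares preferred
orientation and concentration so that gain vs offset is the only
contrast).  Fitting profiles the linear parameters out, leaving a 2-D
search over (theta_pref, kappa) with multi-start and cross-seeding between
the models, which also guarantees the nesting inequalities
(RSS m2 <= m3, m4 <= m1) numerically.  Two departures from the naive
formulation proved necessary and are deliberate:

* **inverse-variance weighting.**  Spike-count curves have variance
  proportional to their mean, and under unweighted least squares the gain
  degree of freedom preferentially absorbs the high-variance peak points,
  inflating spurious "gain change" detections.  Weights `1/mu` (with `mu`
  the cross-phase mean rate, floored at a tenth of its average) restore the
  calibration; only relative weights matter, so no count scale is needed.
  `weighting = "none"` recovers plain least squares.
* **a two-stage decision.**  Information criteria alone have a structural
  false-selection rate for the one-extra-parameter models (~20% regardless
  of signal strength), so "modulated at all" is first gated by a nested F
  test of the independent-curves model against the shared model (df 4/16,
  p < 0.05); only gated neurons are classified among
  both/additive-only/gain-only by AICc.  AICc rather than plain AIC
  because with n = 24 points the 8-parameter model is otherwise
  over-selected.  Plain AIC values are still reported per model.

With these choices the classifier recovers the generating class in
94-100% of synthetic neurons per class at a full-length session's repetition scale.

## Psychophysics

`simulate_observer()` draws clockwise/counter-clockwise responses from a
cumulative Gaussian `P(CW) = Phi((dOri - mu)/sigma)` over 14 log-spaced
levels (seven per direction), with separate sigma for early and late
probes.  `fit_psychometric()` is the maximum-likelihood probit fit; the
JND is reported as `sigma * qnorm(0.75)` (the 75%-correct half-threshold),
a convention the object also exposes through `sigma` itself for users who
prefer the slope parameter.  No lapse rate is modelled by default (none is
needed for the simulated observer; real data with lapses would need one).
Degenerate patterns are flagged rather than fitted: all-one-response data
(`degenerate`), perfectly separated responses (`separation`, sigma pinned
at a lower bound), and near-flat curves (`flat`).  Confidence intervals
come from 1000 case-resampling bootstraps; `compare_thresholds()` uses the
bootstrap distribution of the JND difference with a two-sided exceedance
p-value.  Calibrated simulations put the 95% CI coverage of the true JND
in the mid-90s.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use the session lengths
each check needs rather than one global size: structural checks and
decoding use full 60-min schedules (the paradigm's own scale; decoding
geometry needs the full trial counts), kernel recovery uses 5-10-min
single-neuron sessions (3,000-10,000 spikes), the gain-slope recovery uses
60-min sessions because regression dilution would otherwise bias the slope
by more than the tolerance, and the model-recovery study uses synthetic
curves at 350 presentations per orientation.  All random draws flow
through explicit integer seeds; regenerating any object with the same seed
is byte-identical, which the pipeline (`run_pipeline()`) turns into a
reproducibility contract over its entire output directory.

Known limitations: the temporal kernel is monophasic by construction; the
MI bias correction is the shuffle-subtraction scheme, not a specific
published estimator; luminance/contrast information itself is out of scope
(they are treated as nuisance dimensions throughout); and the psychometric
observer has no lapse parameter by default.
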