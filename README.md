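# adaptcode

Analysis pipeline for **orientation coding under luminance and contrast
adaptation** in early visual cortex.

The experimental paradigm this package serves interleaves two timescales:
grating orientation changes every two monitor frames (2/120 s, 12
orientations x 8 phases), while the gratings' mean luminance and contrast
switch every 5 s among four combinations (70/140 cd/m2 x 35/65%).  Each
switch triggers firing-rate adaptation, and the scientific question is how
that adaptation reshapes the coding of orientation — a dimension that is
itself changing far faster than the adaptation.  `adaptcode` implements
the complete chain:

| stage | functions |
|---|---|
| stimulus schedules & switch classification | `generate_schedule()`, `classify_switches()`, `switch_windows()` |
| ground-truth spiking simulator (LN + gamma renewal, condition-dependent gain with exponential adaptation) | `neuron_params()`, `simulate_population()`, `instantaneous_rate()` |
| orientation reverse correlation, kernel features, difference-of-von-Mises fits, selectivity criteria | `reverse_correlate()`, `extract_features()`, `fit_diff_von_mises()`, `assess_selectivity()` |
| bias-corrected mutual information, six-window adaptation time course | `mutual_information()`, `bias_corrected_mi()`, `mi_timecourse()` |
| shuffle-normalised peri-switch PSTHs, exponential decay constants, sliding Fano factor | `switch_psth()`, `shuffle_normalize()`, `fit_decay()`, `fano_series()` |
| linear population decoding (shrinkage LDA / linear SVM), early-vs-late comparison | `build_response_matrix()`, `decode_orientation()`, `early_late_comparison()` |
| gain/offset tuning modulation, four-model von Mises comparison | `tuning_curves()`, `gain_offset_regression()`, `compare_models()` |
| psychometric thresholds (probit MLE, bootstrap JND comparison) | `simulate_observer()`, `fit_psychometric()`, `compare_thresholds()` |
| end-to-end reproducible pipeline with CSV/JSON outputs | `default_config()`, `run_pipeline()` |

The core single-neuron model is
`rate(t) = offset_c + g(t) * exp(kappa * (cos 2(theta(t - latency) - theta_pref) - 1))`,
where the gain `g(t)` relaxes exponentially toward the steady gain of the
current luminance-contrast condition with switch-type-specific time
constants; the reverse-correlation kernel `p(theta, tau)` is estimated on
the exact lag grid -6..250 ms (0.5 ms steps), and information is the
plug-in `MI = sum_theta p(theta) sum_R p(R|theta) log2 p(R|theta)/p(R)`
with a shuffle-based bias correction.  Because no public recordings exist
for this paradigm, every estimator is validated by parameter recovery
against the simulator.  The methods vignette
(`vignettes/adaptcode-methods.Rmd`) documents each model, convention and
tolerance.

## Worked example

Simulate one adapting neuron through the full 60-min paradigm, estimate
its kernel, information time course and gain modulation:

```r
library(adaptcode)

sch <- generate_schedule(3600, seed = 1)          # 720 x 5 s epochs
p <- neuron_params(60, 3, steady_gain = default_condition_gains(30),
                   offset = 2, tau_adapt = default_tau_adapt(),
                   transient = default_transients())
sp <- simulate_spike_train(p, sch, seed = 3)      # 25681 spikes

kern <- reverse_correlate(sp, sch)
extract_features(kern)
#> peak 50.5 ms | width 29.6 ms | modulation 0.139 | pref 60 deg
assess_selectivity(kern)$fit
#> <von_mises_fit> theta_pref 60.4 deg, bandwidth 40.1 deg, F-test p 1.2e-07

mi_timecourse(sp, sch, "contrast_inc", seed = 4)[, c("window", "mi_corrected", "rate_hz")]
#>  window mi_corrected rate_hz
#>       1       0.0354 11.3000
#>       2       0.0313  9.2318
#>       3       0.0216  8.9455
#>       4       0.0260  8.5045
#>       5       0.0319  9.1000
#>       6       0.0263  8.3000

tp <- tuning_curves(sp, sch, "contrast_inc")
gain_offset_regression(tp)
#> slope 0.78, intercept 0.54
compare_models(tp)$classification
#> "gain_only"   (p_modulation 0.0031)
```

Reading the numbers: the neuron was generated with a 50-ms latency, 30-ms
response kernel and preferred orientation 60 deg, and the kernel recovers
all three.  After a contrast increment its gain overshoots (x1.8) and
decays with tau = 0.6 s, so firing rate and mutual information are highest
in the first ~1.6 s window and settle lower; the late-vs-early tuning
regression slope of 0.78 matches the expected ratio of steady to
window-averaged gain (1/1.279 = 0.78), and the four-model comparison
correctly calls the change *gain-only*.

The whole pipeline can also be run in one call (or from the shell via
`inst/cli/adaptcode.R run --out dir --seed 1`):

```r
cfg <- default_config("out_dir", seed = 1, duration_s = 600, n_neurons = 12)
run_pipeline(cfg)   # schedule/, spikes.csv, features.csv, mi.csv, psth.csv,
                    # fano.csv, decode.csv, tuning_mod.csv, psycho.csv, ...
```

Re-running with the same config is byte-identical, and every CSV carries a
JSON sidecar with the package version, seed and config hash.

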