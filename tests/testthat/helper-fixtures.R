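# Shared fixtures and independent oracles, built in code at test time.

quick_schedule <- function(duration_s = 60, seed = 1, ...) {
  generate_schedule(duration_s, seed = seed, ...)
}

quick_neuron <- function(theta_pref = 45, kappa = 2.5, gain = 40,
                         offset = 2, ...) {
  neuron_params(theta_pref, kappa, steady_gain = gain, offset = offset,
                latency = 0.05, kernel_width = 0.03, ...)
}

# Condition-dependent neuron with the default adaptation scenario.
adapting_neuron <- function(theta_pref = 60, kappa = 2.5,
                            peak_rate = 30, ...) {
  neuron_params(theta_pref, kappa,
                steady_gain = default_condition_gains(peak_rate),
                offset = 2, tau_adapt = default_tau_adapt(),
                transient = default_transients(), ...)
}

# Independent reverse-correlation oracle: per-spike loop with arithmetic
# frame lookup (valid for gap-free uniform schedules), structurally
# different from the per-lag findInterval path in the package.
naive_revcorr_counts <- function(spikes, schedule, lags = default_lags()) {
  fr <- schedule$frames
  oris <- sort(unique(schedule$orientations))
  oi <- match(fr$orientation_deg, oris)
  fl <- schedule$frame_len_s
  t_end <- nrow(fr) * fl
  counts <- matrix(0L, length(oris), length(lags))
  for (s in spikes) {
    tt <- s - lags
    ok <- tt >= 0 & tt < t_end
    k <- floor(tt[ok] / fl + 1e-12) + 1
    idx <- cbind(oi[k], which(ok))
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# Homogeneous Poisson spike train on [0, T).
poisson_train <- function(rate, T_end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(stats::runif(stats::rpois(1, rate * T_end), 0, T_end))
}

# Synthetic early/late tuning curves at a full-length session's repetition scale
# (350 presentations per orientation, 20 ms count windows).
synth_tuning_pair <- function(kind, gain_early = 30, offset_early = 5,
                              n_rep = 350, win = 0.02,
                              orientations = seq(0, 165, by = 15)) {
  tp <- stats::runif(1, 0, 180)
  kap <- stats::runif(1, 1.5, 4)
  b <- adaptcode:::vm_tuning(orientations, tp, kap)
  g_l <- if (kind %in% c("gain_only", "both")) gain_early / 2 else gain_early
  o_l <- if (kind %in% c("additive_only", "both")) offset_early + 5
         else offset_early
  r_e <- offset_early + gain_early * b
  r_l <- o_l + g_l * b
  list(early = stats::rpois(12, r_e * win * n_rep) / (win * n_rep),
       late = stats::rpois(12, r_l * win * n_rep) / (win * n_rep),
       theta_pref = tp, kappa = kap)
}
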