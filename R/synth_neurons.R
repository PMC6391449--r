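#' Parameters of a model orientation-tuned neuron
#'
#' Generative model: the firing rate is
#' `rate(t) = offset[c(t)] + g(t) * drive(t)` where `drive(t)` is the mean of
#' the von Mises tuning factor `exp(kappa * (cos(2 * (theta - theta_pref)) - 1))`
#' over the grating frames inside a boxcar response window of width
#' `kernel_width` centred `latency` seconds before `t` (the neuron responds
#' to a frame over lags `latency +/- kernel_width / 2`, so the
#' reverse-correlation peak lag equals the latency and the half-maximum
#' temporal width equals `kernel_width`).  The
#' gain `g(t)` relaxes exponentially within each epoch towards the steady
#' gain of the current condition:
#' `g(t) = g_ss + (g_start - g_ss) * exp(-(t - t_switch) / tau)`.
#' By default `g_start` equals the gain at the end of the previous epoch
#' (continuous trajectory); `transient` multipliers instead reset
#' `g_start = transient[switch_type] * g_ss` at matching switches, emulating
#' the transient rate overshoot/undershoot observed after switches.
#'
#' @param theta_pref preferred orientation in degrees, `[0, 180)`
#' @param kappa tuning concentration on the doubled-angle scale (0 = untuned)
#' @param steady_gain spikes/s scale at the preferred orientation; scalar or
#'   vector named by condition label
#' @param offset spikes/s baseline; scalar or named by condition label
#' @param tau_adapt adaptation time constant(s) in seconds; scalar or named
#'   by switch type
#' @param latency response lag in seconds, in (0, 0.25)
#' @param kernel_width temporal width of the boxcar response in seconds
#' @param dispersion Fano-like dispersion of spiking (1 = Poisson; other
#'   values use a gamma-renewal process with ISI CV^2 = dispersion)
#' @param transient `NULL` for a continuous gain trajectory, or a numeric
#'   vector of multipliers named by switch type
#' @param label optional neuron id
#' @return object of class `neuron_params`
#' @export
neuron_params <- function(theta_pref, kappa, steady_gain, offset = 0,
                          tau_adapt = 0.8, latency = 0.05,
                          kernel_width = 0.03, dispersion = 1,
                          transient = NULL, label = NULL) {
  stopifnot(is.numeric(theta_pref), length(theta_pref) == 1,
            theta_pref >= 0, theta_pref < 180,
            is.numeric(kappa), kappa >= 0,
            all(steady_gain >= 0), all(offset >= 0),
            all(tau_adapt > 0),
            latency > 0, latency < 0.25,
            kernel_width > 0, dispersion > 0)
  if (!is.null(transient)) stopifnot(all(transient > 0),
                                     !is.null(names(transient)))
  structure(list(theta_pref = theta_pref, kappa = kappa,
                 steady_gain = steady_gain, offset = offset,
                 tau_adapt = tau_adapt, latency = latency,
                 kernel_width = kernel_width, dispersion = dispersion,
                 transient = transient, label = label),
            class = "neuron_params")
}

#' Default condition-dependent gains, time constants and transients
#'
#' The relative steady gains follow the ordering seen in steady state:
#' strongest drive at high contrast and low luminance, weakest at low
#' contrast and high luminance.  Time constants are asymmetric, longer for
#' contrast decrements than increments.  Transient multipliers emulate the
#' post-switch rate dynamics: overshoot (then decay) after contrast
#' increments and luminance decrements, undershoot (then recovery) after
#' contrast decrements and luminance increments.
#'
#' @param peak_rate steady peak drive (spikes/s) scaling the four conditions
#' @return named numeric vector
#' @export
default_condition_gains <- function(peak_rate = 30) {
  c(L70C35 = 0.60, L70C65 = 1.00, L140C35 = 0.45, L140C65 = 0.80) * peak_rate
}

#' @rdname default_condition_gains
#' @export
default_tau_adapt <- function() {
  c(contrast_inc = 0.6, contrast_dec = 1.2,
    luminance_inc = 1.0, luminance_dec = 0.5,
    both_changed = 0.8, no_change = 0.8)
}

#' @rdname default_condition_gains
#' @export
default_transients <- function() {
  c(contrast_inc = 1.8, contrast_dec = 0.55,
    luminance_inc = 0.45, luminance_dec = 1.7)
}

#' Sample a population of model neurons
#'
#' Preferred orientations are uniform on `[0, 180)`, concentrations uniform
#' on `kappa_range`, and each neuron's condition gains are the default
#' condition profile scaled by a lognormal factor (sd 0.3 on the log scale).
#'
#' @param n number of neurons
#' @param seed integer seed (`NULL` = use current RNG state)
#' @param conditions condition table the gains are named after
#' @param peak_rate population-average steady peak drive, spikes/s
#' @param kappa_range range of tuning concentrations
#' @param offset_rate untuned baseline, spikes/s
#' @param dispersion spiking dispersion (shared)
#' @param transient transient multipliers (see [neuron_params()]); the
#'   default emulates the observed post-switch rate dynamics
#' @return list of `neuron_params`
#' @export
sample_neuron_params <- function(n, seed = NULL,
                                 conditions = lc_conditions(),
                                 peak_rate = 30,
                                 kappa_range = c(1.5, 4),
                                 offset_rate = 2,
                                 dispersion = 1,
                                 transient = default_transients()) {
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  gains0 <- default_condition_gains(peak_rate)
  stopifnot(all(conditions$label %in% names(gains0)))
  lapply(seq_len(n), function(i) {
    scale <- stats::rlnorm(1, 0, 0.3)
    neuron_params(theta_pref = stats::runif(1, 0, 180),
                  kappa = stats::runif(1, kappa_range[1], kappa_range[2]),
                  steady_gain = gains0[conditions$label] * scale,
                  offset = stats::setNames(rep(offset_rate,
                                               nrow(conditions)),
                                           conditions$label),
                  tau_adapt = default_tau_adapt(),
                  dispersion = dispersion,
                  transient = transient,
                  label = sprintf("n%03d", i))
  })
}

# Resolve a scalar-or-named parameter map against a label vector.
resolve_map <- function(map, labels, what) {
  if (length(map) == 1 && is.null(names(map)))
    return(rep(unname(map), length(labels)))
  if (!all(labels %in% names(map)))
    stop(sprintf("%s must name every label: missing %s", what,
                 paste(setdiff(labels, names(map)), collapse = ", ")))
  unname(map[labels])
}

#' Epoch-wise gain trajectory of a model neuron
#'
#' @param params a `neuron_params`
#' @param schedule a `stimulus_schedule`
#' @return data.frame, one row per epoch: `start_s`, `g_start`, `g_ss`,
#'   `tau`, `offset`
#' @export
gain_trajectory <- function(params, schedule) {
  ep <- schedule$epochs
  n <- nrow(ep)
  g_ss <- resolve_map(params$steady_gain, ep$label, "steady_gain")
  offset <- resolve_map(params$offset, ep$label, "offset")
  ev <- classify_switches(schedule)
  tau_in <- c(1, resolve_map(params$tau_adapt, ev$switch_type, "tau_adapt"))
  g_start <- numeric(n)
  g_start[1] <- g_ss[1]
  if (n > 1) {
    for (e in 2:n) {
      ty <- ev$switch_type[e - 1]
      if (!is.null(params$transient) && ty %in% names(params$transient)) {
        g_start[e] <- params$transient[[ty]] * g_ss[e]
      } else {
        # continuity: start from the previous epoch's end gain
        g_start[e] <- g_ss[e - 1] + (g_start[e - 1] - g_ss[e - 1]) *
          exp(-ep$duration_s[e - 1] / tau_in[e - 1])
      }
    }
  }
  data.frame(start_s = ep$start_s, g_start = g_start, g_ss = g_ss,
             tau = tau_in, offset = offset)
}

# Closure evaluating the instantaneous rate at arbitrary times.
# Precomputes the cumulative integral of the per-frame tuning factor so the
# boxcar-averaged drive is an O(log n_frames) interpolation per query.
make_rate_fn <- function(params, schedule) {
  fr <- schedule$frames
  f <- vm_tuning(fr$orientation_deg, params$theta_pref, params$kappa)
  onsets <- fr$onset_s
  durs <- fr$duration_s
  Gcum <- c(0, cumsum(f * durs))
  first_on <- onsets[1]
  G <- function(s) {
    k <- findInterval(s, onsets)
    out <- numeric(length(s))
    pos <- k >= 1
    kk <- k[pos]
    out[pos] <- Gcum[kk] + f[kk] * pmin(pmax(s[pos] - onsets[kk], 0),
                                        durs[kk])
    out
  }
  traj <- gain_trajectory(params, schedule)
  lat <- params$latency
  w <- params$kernel_width
  if (lat - w / 2 <= 0)
    stop("kernel_width/2 must not exceed latency (causality)")
  dur_total <- schedule$duration_s
  function(t) {
    drive <- (G(t - lat + w / 2) - G(t - lat - w / 2)) / w
    e <- pmax(findInterval(t, traj$start_s), 1)
    g <- traj$g_ss[e] + (traj$g_start[e] - traj$g_ss[e]) *
      exp(-(t - traj$start_s[e]) / traj$tau[e])
    r <- traj$offset[e] + g * drive
    r[t - lat < first_on | t < 0 | t > dur_total] <- 0
    pmax(r, 0)
  }
}

#' Instantaneous firing rate of a model neuron
#'
#' @param params a `neuron_params`
#' @param schedule a `stimulus_schedule`
#' @param t vector of times in seconds
#' @return spikes/s at each `t` (0 before the first frame plus latency)
#' @export
instantaneous_rate <- function(params, schedule, t) {
  make_rate_fn(params, schedule)(t)
}

#' Simulate one spike train
#'
#' Poisson neurons (`dispersion == 1`) are sampled exactly by thinning an
#' upper-bound homogeneous process.  Non-Poisson neurons use a gamma-renewal
#' process (ISI shape `1/dispersion`) in operational time, obtained by
#' time-rescaling the integrated rate on a 1 ms grid; stationary spike-count
#' Fano factors approach `dispersion` in windows holding many spikes.
#'
#' @param params a `neuron_params`
#' @param schedule a `stimulus_schedule`
#' @param seed integer seed (`NULL` = current RNG state)
#' @return sorted numeric vector of spike times in seconds
#' @export
simulate_spike_train <- function(params, schedule, seed = NULL) {
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  rate_fn <- make_rate_fn(params, schedule)
  traj <- gain_trajectory(params, schedule)
  bound <- max(traj$offset) + max(pmax(traj$g_start, traj$g_ss))
  if (!is.finite(bound)) stop("rate is unbounded")
  T_end <- schedule$duration_s
  if (bound <= 0) return(numeric(0))
  if (params$dispersion == 1) {
    n_cand <- stats::rpois(1, bound * T_end)
    tc <- sort(stats::runif(n_cand, 0, T_end))
    keep <- stats::runif(n_cand) < rate_fn(tc) / bound
    return(tc[keep])
  }
  # time-rescaling for gamma-renewal spiking
  dt <- 1e-3
  edges <- seq(0, T_end, by = dt)
  mids <- edges[-1] - dt / 2
  lam <- rate_fn(mids)
  Lam <- c(0, cumsum(lam * dt))
  L_total <- Lam[length(Lam)]
  if (L_total <= 0) return(numeric(0))
  shape <- 1 / params$dispersion
  isi <- stats::rgamma(ceiling(L_total * 1.2) + 50, shape = shape,
                       rate = shape)
  s <- cumsum(isi)
  while (s[length(s)] < L_total) {
    isi <- stats::rgamma(ceiling(L_total * 0.3) + 50, shape = shape,
                         rate = shape)
    s <- c(s, s[length(s)] + cumsum(isi))
  }
  s <- s[s <= L_total]
  stats::approx(x = Lam, y = edges, xout = s, ties = "ordered")$y
}

#' Simulate a population recording
#'
#' Neurons are simulated sequentially from a single seeded stream, so the
#' whole recording is reproducible from `seed`.
#'
#' @param params_list list of `neuron_params`
#' @param schedule a `stimulus_schedule`
#' @param seed integer seed
#' @return object of class `population_recording`: `spikes` (named list of
#'   spike-time vectors), `params`, `schedule`, `seed`
#' @export
simulate_population <- function(params_list, schedule, seed = 1) {
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  ids <- vapply(seq_along(params_list), function(i) {
    params_list[[i]]$label %||% sprintf("n%03d", i)
  }, character(1))
  spikes <- lapply(params_list, simulate_spike_train, schedule = schedule,
                   seed = NULL)
  names(spikes) <- ids
  structure(list(spikes = spikes, params = params_list,
                 schedule = schedule, seed = seed),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  n_sp <- vapply(x$spikes, length, integer(1))
  cat(sprintf(paste0("<population_recording> %d neurons over %g s,",
                     " %.1f +/- %.1f spikes/s, seed %s\n"),
              length(x$spikes), x$schedule$duration_s,
              mean(n_sp) / x$schedule$duration_s,
              stats::sd(n_sp) / x$schedule$duration_s, format(x$seed)))
  invisible(x)
}

#' Write / read spike trains as CSV
#'
#' Long format `neuron_id, spike_time_s`; ground truth parameters can be
#' saved alongside as JSON with [write_ground_truth()].
#'
#' @param spikes named list of spike-time vectors or a
#'   `population_recording`
#' @param path CSV file path
#' @return `write_spikes()` the path, invisibly; `read_spikes()` a named
#'   list of sorted spike-time vectors
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "population_recording")) spikes <- spikes$spikes
  df <- data.frame(neuron_id = rep(names(spikes),
                                   vapply(spikes, length, integer(1))),
                   spike_time_s = unlist(spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df$spike_time_s, df$neuron_id), sort)
}

#' @rdname write_spikes
#' @param recording a `population_recording`
#' @export
write_ground_truth <- function(recording, path) {
  truth <- lapply(recording$params, function(p) {
    p <- unclass(p)
    p[!vapply(p, is.null, logical(1))]
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
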