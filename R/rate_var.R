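#' Peri-switch time histogram
#'
#' Firing rate in uniform bins around each switch event, averaged over
#' repetitions and ignoring all other stimulus dimensions (orientation,
#' phase, spatial frequency).  Events whose `+/- span_s` surround extends
#' beyond the session are dropped so every bin pools the same number of
#' repetitions.
#'
#' @param spikes sorted spike times (s)
#' @param switch_events event times (s), or rows of [classify_switches()]
#' @param bin_s bin width (default 0.05 s)
#' @param span_s half-span around each event (default 5 s)
#' @param session_len_s session duration used for edge trimming and later
#'   shuffle normalisation
#' @return object of class `switch_psth`: data.frame `bins` (`time_s`
#'   centres, `rate_hz`), `events`, `n_repetitions`, `bin_s`, `span_s`,
#'   `session_len_s`; `rate_norm` is added by [shuffle_normalize()]
#' @export
switch_psth <- function(spikes, switch_events, bin_s = 0.05, span_s = 5,
                        session_len_s) {
  times <- if (is.data.frame(switch_events)) switch_events$time_s
           else as.numeric(switch_events)
  times <- times[times - span_s >= 0 & times + span_s <= session_len_s]
  if (length(times) == 0) stop("no switch repetition with full coverage")
  edges <- seq(-span_s, span_s, by = bin_s)
  counts <- psth_counts(spikes, times, edges)
  rate <- counts / (length(times) * bin_s)
  structure(list(bins = data.frame(time_s = edges[-1] - bin_s / 2,
                                   rate_hz = rate),
                 events = times, n_repetitions = length(times),
                 bin_s = bin_s, span_s = span_s,
                 session_len_s = session_len_s),
            class = "switch_psth")
}

# Total spike counts per peri-event bin, summed over events.
psth_counts <- function(spikes, event_times, edges) {
  total <- numeric(length(edges) - 1)
  for (t0 in event_times) {
    total <- total + diff(findInterval(t0 + edges - 1e-12, spikes))
  }
  total
}

#' @export
print.switch_psth <- function(x, ...) {
  cat(sprintf("<switch_psth> %d reps, %g ms bins over +/- %g s%s\n",
              x$n_repetitions, 1000 * x$bin_s, x$span_s,
              if (!is.null(x$bins$rate_norm)) ", shuffle-normalised" else ""))
  invisible(x)
}

#' Shuffle-normalise a peri-switch PSTH
#'
#' Divides the raw PSTH by the mean PSTH of surrogate spike trains whose
#' spike times are redrawn uniformly over the whole session, repeated
#' `n_shuffles` times.  The result is a unitless rate relative to the
#' session average; 1 means no event-locked modulation.
#'
#' @param psth a `switch_psth`
#' @param spikes the session-long spike train the PSTH was computed from
#' @param n_shuffles number of uniform redraws (default 50)
#' @param seed integer seed
#' @return the `switch_psth` with columns `rate_shuffle` and `rate_norm`
#'   added to `bins`; a silent neuron yields `NA` and a `flagged_silent`
#'   attribute
#' @export
shuffle_normalize <- function(psth, spikes, n_shuffles = 50, seed = NULL) {
  stopifnot(inherits(psth, "switch_psth"))
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  n_sp <- length(spikes)
  edges <- seq(-psth$span_s, psth$span_s, by = psth$bin_s)
  if (n_sp == 0) {
    psth$bins$rate_shuffle <- NA_real_
    psth$bins$rate_norm <- NA_real_
    attr(psth, "flagged_silent") <- TRUE
    return(psth)
  }
  acc <- numeric(length(edges) - 1)
  for (s in seq_len(n_shuffles)) {
    sh <- sort(stats::runif(n_sp, 0, psth$session_len_s))
    acc <- acc + psth_counts(sh, psth$events, edges)
  }
  rate_sh <- acc / (n_shuffles * psth$n_repetitions * psth$bin_s)
  psth$bins$rate_shuffle <- rate_sh
  psth$bins$rate_norm <- ifelse(rate_sh > 0,
                                psth$bins$rate_hz / rate_sh, NA_real_)
  psth$n_shuffles <- n_shuffles
  psth
}

#' Gaussian smoothing for display
#'
#' Convolves the PSTH with a Gaussian window (sd `sigma_s`).  Display only:
#' all statistics in this package are computed on unsmoothed series.
#'
#' @param psth a `switch_psth`
#' @param sigma_s Gaussian sd in seconds (default 0.05)
#' @return the `switch_psth` with `rate_smooth` (and `rate_norm_smooth` if
#'   normalised) columns added
#' @export
smooth_psth <- function(psth, sigma_s = 0.05) {
  sm <- function(y) {
    half <- ceiling(3 * sigma_s / psth$bin_s)
    k <- stats::dnorm(seq(-half, half) * psth$bin_s, sd = sigma_s)
    k <- k / sum(k)
    as.numeric(stats::filter(c(rep(y[1], half), y, rep(y[length(y)], half)),
                             k, sides = 2))[half + seq_along(y)]
  }
  psth$bins$rate_smooth <- sm(psth$bins$rate_hz)
  if (!is.null(psth$bins$rate_norm))
    psth$bins$rate_norm_smooth <- sm(psth$bins$rate_norm)
  psth
}

#' Exponential decay fit to the post-switch PSTH
#'
#' Least-squares fit of `a + b * exp(-t / tau)` to the shuffle-normalised
#' rate inside `fit_window` (default `[0.05, 5)` s, skipping the first
#' transient bin), multi-start over `tau` in {0.1, 0.5, 1, 2} s.
#'
#' @param psth a shuffle-normalised `switch_psth` (falls back to the raw
#'   rate if not normalised)
#' @param fit_window post-switch window in seconds
#' @param min_amplitude |b| below which the transient is flagged
#'   `low_amplitude` (tau unidentifiable); default 0.05
#' @return object of class `decay_fit`: `tau_s`, `amplitude`, `asymptote`,
#'   `rss`, `fit_window`, `converged`, `flags`
#' @export
fit_decay <- function(psth, fit_window = c(0.05, 5), min_amplitude = 0.05) {
  stopifnot(inherits(psth, "switch_psth"),
            fit_window[1] >= 0, fit_window[2] <= psth$span_s)
  y_all <- psth$bins$rate_norm %||% psth$bins$rate_hz
  if (is.null(psth$bins$rate_norm)) y_all <- psth$bins$rate_hz
  sel <- psth$bins$time_s >= fit_window[1] &
    psth$bins$time_s < fit_window[2] & is.finite(y_all)
  t <- psth$bins$time_s[sel]
  y <- y_all[sel]
  if (length(y) < 5) stop("too few bins inside `fit_window`")
  best <- NULL
  for (tau0 in c(0.1, 0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                        start = list(a = mean(y[t > stats::median(t)]),
                                     b = y[1] - mean(y), tau = tau0),
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, flags = "no_convergence"),
                     class = "decay_fit"))
  cf <- stats::coef(best$fit)
  flags <- character(0)
  if (abs(cf[["b"]]) < min_amplitude) flags <- c(flags, "low_amplitude")
  structure(list(tau_s = cf[["tau"]], amplitude = cf[["b"]],
                 asymptote = cf[["a"]], rss = best$rss,
                 fit_window = fit_window, converged = TRUE, flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<decay_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<decay_fit> tau %.3f s, amplitude %.3f, asymptote %.3f%s\n",
              x$tau_s, x$amplitude, x$asymptote,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Sliding-window Fano factor around switches
#'
#' Spike counts are taken per repetition in a sliding window (`win_s` wide,
#' `step_s` step) around each event; the Fano factor at each window centre
#' is the unbiased (n-1) sample variance over repetitions divided by the
#' mean.  Centres with zero mean count are `NA`.
#'
#' @param spikes sorted spike times (s)
#' @param switch_events event times or [classify_switches()] rows
#' @param win_s window width (default 0.05 s)
#' @param step_s centre step (default 0.01 s)
#' @param span_s centres run from `-span_s` to `span_s` (default 0.5 s)
#' @param session_len_s session duration for edge trimming
#' @return data.frame (`centre_s`, `fano`, `mean_count`, `n_repetitions`)
#' @export
fano_series <- function(spikes, switch_events, win_s = 0.05, step_s = 0.01,
                        span_s = 0.5, session_len_s) {
  times <- if (is.data.frame(switch_events)) switch_events$time_s
           else as.numeric(switch_events)
  margin <- span_s + win_s
  times <- times[times - margin >= 0 & times + margin <= session_len_s]
  n_rep <- length(times)
  if (n_rep < 2) stop("need at least 2 fully covered repetitions")
  if (n_rep < 10)
    warning("fewer than 10 repetitions; Fano estimates will be noisy")
  centres <- seq(-span_s, span_s, by = step_s)
  lo <- centres - win_s / 2
  hi <- centres + win_s / 2
  counts <- vapply(times, function(t0) {
    count_in_windows(spikes, t0 + lo, t0 + hi)
  }, numeric(length(centres)))          # centres x reps
  counts <- matrix(counts, nrow = length(centres))
  m <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  data.frame(centre_s = centres,
             fano = ifelse(m > 0, v / m, NA_real_),
             mean_count = m, n_repetitions = n_rep)
}
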