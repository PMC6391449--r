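#' Per-presentation spike-count table
#'
#' One row per grating frame (presentation) inside the requested intervals:
#' the orientation shown and the spike count in a half-open window of width
#' `width_s` starting `offset_s` after frame onset.  A sensible default
#' places the window over the information-carrying lag: `offset_s` equal to
#' the kernel peak time minus half the width.
#'
#' @param spikes sorted spike times (s)
#' @param schedule a `stimulus_schedule`
#' @param intervals optional absolute intervals (see [switch_windows()]);
#'   `NULL` uses every frame
#' @param offset_s count-window start after frame onset (s), default 0.025
#' @param width_s count-window width (s), default 0.05
#' @return data.frame (`orientation_deg`, `count`, `onset_s`,
#'   `interval_index`) with attributes `offset_s`, `width_s`
#' @export
count_table <- function(spikes, schedule, intervals = NULL,
                        offset_s = 0.025, width_s = 0.05) {
  stopifnot(width_s > 0, !is.unsorted(spikes))
  fr <- if (is.null(intervals)) {
    cbind(schedule$frames, interval_index = NA_integer_)
  } else {
    frames_in_intervals(schedule$frames, intervals)
  }
  starts <- fr$onset_s + offset_s
  out <- data.frame(orientation_deg = fr$orientation_deg,
                    count = count_in_windows(spikes, starts,
                                             starts + width_s),
                    onset_s = fr$onset_s,
                    interval_index = fr$interval_index)
  attr(out, "offset_s") <- offset_s
  attr(out, "width_s") <- width_s
  out
}

# Raw integer counts with the sparse upper tail merged into one bin.
cap_counts <- function(counts, cap_quantile = 0.995) {
  cap <- stats::quantile(counts, cap_quantile, type = 1, names = FALSE)
  pmin(counts, cap)
}

#' Plug-in mutual information between orientation and spike count
#'
#' `MI = sum_theta p(theta) sum_R p(R|theta) log2( p(R|theta) / p(R) )` with
#' `p(R) = sum_theta p(theta) p(R|theta)`, all probabilities empirical and
#' `0 log 0 = 0`.  Counts are used as raw integers; counts above the
#' `cap_quantile` quantile are merged into a single bin to stabilise
#' `p(R|theta)`.
#'
#' @param counts integer spike counts, or a [count_table()] data.frame (in
#'   which case `stimulus` is taken from it)
#' @param stimulus stimulus labels (orientations), same length as `counts`
#' @param cap_quantile upper-tail merge quantile (default 0.995)
#' @return mutual information in bits
#' @export
#' @examples
#' mutual_information(rep(0:11, each = 10), rep(seq(0, 165, 15), each = 10))
mutual_information <- function(counts, stimulus = NULL,
                               cap_quantile = 0.995) {
  if (is.data.frame(counts)) {
    stimulus <- counts$orientation_deg
    counts <- counts$count
  }
  if (length(counts) == 0) stop("empty count table")
  stopifnot(length(counts) == length(stimulus))
  if (length(unique(stimulus)) < 2) {
    warning("single stimulus value; MI is 0 bits")
    return(0)
  }
  counts <- cap_counts(counts, cap_quantile)
  joint <- table(stimulus, counts) / length(counts)
  p_theta <- rowSums(joint)
  p_r <- colSums(joint)
  denom <- outer(p_theta, p_r)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / denom[nz]))
}

#' Bias-corrected mutual information
#'
#' The plug-in estimator is positively biased at finite sample size.  The
#' correction subtracts the mean plug-in MI obtained after shuffling the
#' orientation labels against the counts (a null-information estimate of the
#' bias), floored at zero.
#'
#' @param counts counts vector or [count_table()] data.frame
#' @param stimulus stimulus labels (ignored when `counts` is a data.frame)
#' @param n_bootstrap number of label shuffles (>= 20, default 100)
#' @param seed integer seed for the shuffles
#' @param cap_quantile see [mutual_information()]
#' @return object of class `mi_estimate`: `mi_raw`, `mi_corrected`
#'   (floored at 0), `mi_debiased` (same correction without the floor,
#'   useful when averaging near-zero estimates across neurons or seeds),
#'   `bits_per_spike` (corrected MI / mean count), `null_mean`, `null_se`,
#'   `n_bootstrap`, `n_presentations`, `mean_count`
#' @export
bias_corrected_mi <- function(counts, stimulus = NULL, n_bootstrap = 100,
                              seed = NULL, cap_quantile = 0.995) {
  if (is.data.frame(counts)) {
    stimulus <- counts$orientation_deg
    counts <- counts$count
  }
  stopifnot(n_bootstrap >= 20)
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  mi_raw <- mutual_information(counts, stimulus, cap_quantile)
  null <- vapply(seq_len(n_bootstrap), function(i) {
    mutual_information(counts, sample(stimulus), cap_quantile)
  }, numeric(1))
  null_mean <- mean(null)
  mean_count <- mean(counts)
  mi_corr <- max(0, mi_raw - null_mean)
  structure(list(mi_raw = mi_raw, mi_corrected = mi_corr,
                 mi_debiased = mi_raw - null_mean,
                 bits_per_spike = if (mean_count > 0) mi_corr / mean_count
                                  else NA_real_,
                 null_mean = null_mean,
                 null_se = stats::sd(null) / sqrt(n_bootstrap),
                 n_bootstrap = n_bootstrap,
                 n_presentations = length(counts),
                 mean_count = mean_count),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf(paste0("<mi_estimate> raw %.4f bits, corrected %.4f bits",
                     " (%.4f bits/spike), n = %d\n"),
              x$mi_raw, x$mi_corrected, x$bits_per_spike,
              x$n_presentations))
  invisible(x)
}

#' Mutual-information time course during adaptation
#'
#' Splits the epoch after each matching switch into `n_windows`
#' non-overlapping windows (default 6 x 833.33 ms) and estimates
#' bias-corrected MI per window, pooling presentations across all
#' repetitions of the switch.  The mean firing rate over each window's count
#' windows is returned alongside, to support rate-MI correlations.
#'
#' @param spikes sorted spike times (s)
#' @param schedule a `stimulus_schedule`
#' @param switch_types switch-type and/or pair labels (see
#'   [switch_windows()]); `NULL` pools all boundaries
#' @param n_windows number of windows dividing the epoch (default 6)
#' @param offset_s,width_s count window, see [count_table()]
#' @param n_bootstrap,seed bias-correction settings
#' @param min_presentations per-orientation presentation count below which
#'   the window is flagged `low_n`
#' @return data.frame, one row per window: `window`, `t_start_s`, `t_end_s`,
#'   `mi_raw`, `mi_corrected`, `bits_per_spike`, `rate_hz`,
#'   `n_presentations`, `low_n`
#' @export
mi_timecourse <- function(spikes, schedule, switch_types = NULL,
                          n_windows = 6, offset_s = 0.025, width_s = 0.05,
                          n_bootstrap = 100, seed = NULL,
                          min_presentations = 10) {
  wl <- schedule$epoch_len_s / n_windows
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  out <- lapply(seq_len(n_windows), function(w) {
    win <- c((w - 1) * wl, w * wl)
    iv <- switch_windows(schedule, switch_types, win)
    ct <- count_table(spikes, schedule, iv, offset_s, width_s)
    est <- bias_corrected_mi(ct, n_bootstrap = n_bootstrap, seed = NULL)
    per_ori <- table(ct$orientation_deg)
    data.frame(window = w, t_start_s = win[1], t_end_s = win[2],
               mi_raw = est$mi_raw, mi_corrected = est$mi_corrected,
               bits_per_spike = est$bits_per_spike,
               rate_hz = est$mean_count / width_s,
               n_presentations = est$n_presentations,
               low_n = length(per_ori) < length(schedule$orientations) ||
                 min(per_ori) < min_presentations)
  })
  do.call(rbind, out)
}
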