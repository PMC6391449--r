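#' Default lag grid for orientation reverse correlation
#'
#' Lags from -6 ms to +250 ms in 0.5 ms steps (513 lags); negative lags are
#' acausal and serve as the baseline.
#'
#' @return numeric vector of lags in seconds
#' @export
default_lags <- function() seq(-0.006, 0.250, by = 5e-4)

#' Orientation reverse correlation
#'
#' For every spike and every lag `tau`, looks `tau` earlier in time and
#' increments the counter of the orientation presented then, regardless of
#' grating phase and spatial frequency.  Counts at each lag are normalised to
#' the probability `p(theta, tau)` that a spike was preceded by each
#' orientation; every lag column then sums to 1.
#'
#' Only spikes for which every lag lands inside the frame sequence are used,
#' so before normalisation the counter sum at each lag equals the number of
#' spikes used (exactly, when the schedule has no inter-epoch gaps).
#'
#' @param spikes sorted numeric vector of spike times (s)
#' @param schedule a `stimulus_schedule`
#' @param intervals optional data.frame of absolute half-open intervals
#'   (`start_s`, `end_s`), e.g. from [switch_windows()]; only spikes inside
#'   them are used.  `NULL` uses the full session.
#' @param lags lag grid in seconds, default [default_lags()]
#' @param window_label free-text label stored with the kernel
#' @return object of class `orientation_kernel`: probability matrix `p`
#'   (orientations x lags), raw `counts`, `n_spikes`, `lags_s`,
#'   `orientations`, `window_label`, and `empty` flag
#' @export
reverse_correlate <- function(spikes, schedule, intervals = NULL,
                              lags = default_lags(),
                              window_label = "full") {
  stopifnot(is.numeric(spikes), !is.unsorted(spikes))
  fr <- schedule$frames
  orientations <- sort(unique(schedule$orientations))
  n_ori <- length(orientations)
  ori_idx <- match(fr$orientation_deg, orientations)
  if (!is.null(intervals) && nrow(intervals) > 0) {
    o <- order(intervals$start_s)
    k <- findInterval(spikes, intervals$start_s[o])
    spikes <- spikes[k >= 1 & spikes < intervals$end_s[o][pmax(k, 1)]]
  }
  # keep only spikes whose full lag range is covered by frames
  lo <- fr$onset_s[1] + max(lags)
  hi <- fr$onset_s[nrow(fr)] + fr$duration_s[nrow(fr)] + min(lags)
  spikes <- spikes[spikes >= lo & spikes < hi]
  n_sp <- length(spikes)
  counts <- matrix(0L, n_ori, length(lags),
                   dimnames = list(orientation = orientations,
                                   lag_ms = sprintf("%g", lags * 1000)))
  if (n_sp > 0) {
    onsets <- fr$onset_s
    ends <- fr$onset_s + fr$duration_s
    for (j in seq_along(lags)) {
      tt <- spikes - lags[j]
      k <- findInterval(tt, onsets)
      ok <- k >= 1 & tt < ends[pmax(k, 1)]
      counts[, j] <- tabulate(ori_idx[k[ok]], nbins = n_ori)
    }
  }
  cs <- colSums(counts)
  p <- sweep(counts, 2, pmax(cs, 1), "/")
  structure(list(p = p, counts = counts, n_spikes = n_sp,
                 lags_s = lags, orientations = orientations,
                 window_label = window_label, empty = n_sp == 0),
            class = "orientation_kernel")
}

#' @export
print.orientation_kernel <- function(x, ...) {
  cat(sprintf("<orientation_kernel> [%s] %d orientations x %d lags, %d spikes%s\n",
              x$window_label, nrow(x$p), ncol(x$p), x$n_spikes,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Temporal and tuning features of a kernel
#'
#' The peak time is the causal lag (`tau >= 0`) maximising the orientation
#' modulation `max_theta p - min_theta p`, ties broken toward the earliest
#' lag; the maximum modulation is that difference at the peak; the preferred
#' orientation is the row maximising `p` at the peak lag.  The temporal width
#' is the half-maximum span of `p(theta_pref, tau)` above the acausal
#' baseline, with linear interpolation between lag samples.  The baseline is
#' the mean and SD of all kernel entries at negative lags (acausal lags
#' carry no stimulus information; the mean is 1/12 by construction).
#'
#' @param kernel an `orientation_kernel`
#' @param subtract_baseline subtract the baseline mean before the
#'   half-maximum width computation (default `TRUE`)
#' @return object of class `kernel_features`: `theta_pref_deg`,
#'   `peak_time_ms`, `max_modulation`, `temporal_width_ms`, `peak_prob`,
#'   `baseline_mean`, `baseline_sd`
#' @export
extract_features <- function(kernel, subtract_baseline = TRUE) {
  if (kernel$empty) stop("kernel is empty; features undefined")
  lags_ms <- kernel$lags_s * 1000
  neg <- lags_ms < 0
  base <- kernel$p[, neg, drop = FALSE]
  baseline_mean <- mean(base)
  baseline_sd <- stats::sd(as.vector(base))
  causal <- which(lags_ms >= 0)
  mod <- apply(kernel$p[, causal, drop = FALSE], 2, function(col)
    max(col) - min(col))
  j_peak <- causal[which.max(mod)]   # which.max -> earliest on ties
  max_modulation <- max(kernel$p[, j_peak]) - min(kernel$p[, j_peak])
  i_pref <- which.max(kernel$p[, j_peak])
  theta_pref <- kernel$orientations[i_pref]

  y <- kernel$p[i_pref, ]
  if (subtract_baseline) y <- y - baseline_mean
  y_c <- y[causal]
  ymax <- max(y_c)
  width <- 0
  if (ymax > 0) {
    half <- ymax / 2
    jmax <- which.max(y_c)
    above <- y_c >= half
    # contiguous above-half region containing the peak, interpolated edges
    l <- jmax
    while (l > 1 && above[l - 1]) l <- l - 1
    r <- jmax
    while (r < length(y_c) && above[r + 1]) r <- r + 1
    t_c <- lags_ms[causal]
    t_lo <- if (l == 1) t_c[1] else {
      stats::approx(y_c[c(l - 1, l)], t_c[c(l - 1, l)], xout = half)$y
    }
    t_hi <- if (r == length(y_c)) t_c[length(t_c)] else {
      stats::approx(y_c[c(r + 1, r)], t_c[c(r + 1, r)], xout = half)$y
    }
    width <- t_hi - t_lo
  }
  structure(list(theta_pref_deg = theta_pref,
                 peak_time_ms = lags_ms[j_peak],
                 max_modulation = max_modulation,
                 temporal_width_ms = width,
                 peak_prob = kernel$p[i_pref, j_peak],
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd),
            class = "kernel_features")
}

# Difference-of-von-Mises curve on doubled angles (period 180 deg).
dvm_curve <- function(theta, par) {
  par[["a1"]] * vm_tuning(theta, par[["t1"]], par[["k1"]]) -
    par[["a2"]] * vm_tuning(theta, par[["t2"]], par[["k2"]]) + par[["b"]]
}

#' Fit a difference of two von Mises functions to a tuning curve
#'
#' Least squares on the doubled-angle scale (orientation has period 180
#' degrees), multi-start with the first preferred angle seeded at every grid
#' orientation; concentrations are bounded in (0, 50] and scale factors are
#' non-negative.  The reported preferred orientation is the argmax of the
#' fitted curve mapped to `[0, 180)`.  `f_test_p` compares the fit against a
#' constant (flat) curve with a standard nested-least-squares F test
#' (6 extra parameters, 12 - 7 residual df).
#'
#' @param tuning_curve numeric vector of responses (probabilities or rates),
#'   one per orientation
#' @param orientations orientation grid in degrees (default 12 values)
#' @param components 2 for the full difference model, 1 for a single von
#'   Mises (second component clamped to zero)
#' @return object of class `von_mises_fit`: `alpha1`, `k1`, `theta_pref1`,
#'   `alpha2`, `k2`, `theta_pref2`, `beta`, `theta_pref` (argmax of fit),
#'   `bandwidth_deg` (full width at half height above beta), `rss`,
#'   `rss_flat`, `f_test_p`, `converged`, and `predict(theta)`
#' @export
fit_diff_von_mises <- function(tuning_curve,
                               orientations = seq(0, 165, by = 15),
                               components = 2) {
  y <- as.numeric(tuning_curve)
  stopifnot(length(y) == length(orientations), all(is.finite(y)),
            components %in% c(1, 2))
  th <- orientations
  rss_flat <- sum((y - mean(y))^2)
  amp <- max(y) - min(y)
  two <- components == 2

  obj <- function(p) {
    pr <- list(a1 = p[1], k1 = p[2], t1 = p[3],
               a2 = if (two) p[4] else 0, k2 = if (two) p[5] else 1,
               t2 = if (two) p[6] else 0,
               b = p[length(p)])
    sum((y - dvm_curve(th, pr))^2)
  }
  lower <- if (two) c(0, 1e-3, -360, 0, 1e-3, -360, -Inf)
           else c(0, 1e-3, -360, -Inf)
  upper <- if (two) c(Inf, 50, 540, Inf, 50, 540, Inf)
           else c(Inf, 50, 540, Inf)

  best <- NULL
  for (t_seed in orientations) {
    init <- if (two) c(max(amp, 1e-6), 2, t_seed, amp / 10, 2,
                       (t_seed + 90) %% 180, min(y))
            else c(max(amp, 1e-6), 2, t_seed, min(y))
    fit <- tryCatch(
      stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 400)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(structure(list(converged = FALSE), class = "von_mises_fit"))

  p <- best$par
  par <- list(a1 = p[1], k1 = p[2], t1 = p[3] %% 180,
              a2 = if (two) p[4] else 0, k2 = if (two) p[5] else 1,
              t2 = if (two) p[6] %% 180 else 0, b = p[length(p)])
  rss <- best$value
  grid <- seq(0, 179.9, by = 0.1)
  curve <- dvm_curve(grid, par)
  theta_pref <- grid[which.max(curve)]

  # full width at half height above beta, circular in 180 deg
  pk <- max(curve)
  half <- par$b + (pk - par$b) / 2
  above <- curve >= half
  bandwidth <- if (all(above) || pk <= par$b) 180 else {
    shift <- which.max(curve)
    rot <- c(above[shift:length(above)], above[seq_len(shift - 1)])
    runs <- rle(rot)
    leading <- runs$lengths[1]          # rot[1] is the peak, always TRUE
    trailing <- if (length(runs$values) > 1 &&
                    runs$values[length(runs$values)])
      runs$lengths[length(runs$lengths)] else 0
    (leading + trailing) * 0.1
  }

  k_fit <- if (two) 7 else 4
  df1 <- k_fit - 1
  df2 <- length(y) - k_fit
  f_test_p <- if (rss <= 0 || df2 <= 0) 0 else {
    f <- ((rss_flat - rss) / df1) / (rss / df2)
    stats::pf(max(f, 0), df1, df2, lower.tail = FALSE)
  }
  structure(list(alpha1 = par$a1, k1 = par$k1, theta_pref1 = par$t1,
                 alpha2 = par$a2, k2 = par$k2, theta_pref2 = par$t2,
                 beta = par$b, theta_pref = theta_pref,
                 bandwidth_deg = bandwidth, rss = rss, rss_flat = rss_flat,
                 f_test_p = f_test_p, converged = TRUE,
                 predict = function(theta) dvm_curve(theta, par)),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<von_mises_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<von_mises_fit> theta_pref %.1f deg, bandwidth %.1f",
                     " deg, RSS %.3g, F-test p %.3g\n"),
              x$theta_pref, x$bandwidth_deg, x$rss, x$f_test_p))
  invisible(x)
}

#' Orientation-selectivity inclusion criteria
#'
#' A neuron counts as orientation selective if (1) the kernel's peak
#' probability exceeds the acausal baseline mean by more than 3 baseline
#' SDs, (2) the von Mises fit beats a flat line (F test, p < 0.05), and
#' (3) the fitted bandwidth lies within 20-95 degrees.
#'
#' @param kernel an `orientation_kernel`
#' @param fit optional `von_mises_fit` of the tuning curve at the peak lag
#'   (computed if missing)
#' @param features optional `kernel_features` (computed if missing)
#' @return list: `is_selective` (AND of the three), named logical
#'   `criteria`, `bandwidth_deg`, plus the features and fit used
#' @export
assess_selectivity <- function(kernel, fit = NULL, features = NULL) {
  if (kernel$empty)
    return(list(is_selective = FALSE,
                criteria = c(peak_above_baseline = FALSE,
                             beats_flat = FALSE, bandwidth_ok = FALSE),
                bandwidth_deg = NA_real_, features = NULL, fit = NULL))
  if (is.null(features)) features <- extract_features(kernel)
  if (is.null(fit)) {
    j <- which(abs(kernel$lags_s * 1000 - features$peak_time_ms) < 1e-9)
    fit <- fit_diff_von_mises(kernel$p[, j[1]], kernel$orientations)
  }
  c1 <- features$peak_prob >
    features$baseline_mean + 3 * features$baseline_sd
  c2 <- isTRUE(fit$converged) && fit$f_test_p < 0.05
  c3 <- isTRUE(fit$converged) && !is.na(fit$bandwidth_deg) &&
    fit$bandwidth_deg >= 20 && fit$bandwidth_deg <= 95
  crit <- c(peak_above_baseline = c1, beats_flat = c2, bandwidth_ok = c3)
  list(is_selective = all(crit), criteria = crit,
       bandwidth_deg = if (isTRUE(fit$converged)) fit$bandwidth_deg
                       else NA_real_,
       features = features, fit = fit)
}

#' Write a kernel as a CSV matrix with a JSON sidecar
#'
#' @param kernel an `orientation_kernel`
#' @param path CSV path; the sidecar is written next to it as `.json`
#' @return the path, invisibly
#' @export
write_kernel <- function(kernel, path) {
  utils::write.csv(as.data.frame(kernel$p), path, row.names = TRUE)
  meta <- list(lags_ms = kernel$lags_s * 1000,
               orientations_deg = kernel$orientations,
               n_spikes = kernel$n_spikes,
               window_label = kernel$window_label)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
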