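#' Early and late orientation tuning curves
#'
#' Computes per-orientation PSTHs over `response_window` (default 0-200 ms)
#' after each grating onset, pooling early- and late-phase presentations to
#' find the peak response time of the preferred orientation; tuning curves
#' are then the mean rate per orientation in a `peak_width_s` window
#' (default 20 ms) centred on that peak, computed separately for the early
#' and late phases.  Both phases share the same window.
#'
#' @param spikes sorted spike times (s)
#' @param schedule a `stimulus_schedule`
#' @param switch_types switch-type and/or pair labels (see
#'   [switch_windows()])
#' @param early,late phase windows relative to the switch
#' @param response_window PSTH window after grating onset (s)
#' @param peak_width_s width of the averaging window (default 0.02 s)
#' @param bin_s PSTH bin for locating the peak (default 0.002 s)
#' @return object of class `tuning_pair`: `early` and `late` numeric
#'   vectors of mean rates (spikes/s) per orientation, `orientations`,
#'   `peak_time_s`, `pref_orientation`, `n_presentations`
#' @export
tuning_curves <- function(spikes, schedule, switch_types = NULL,
                          early = adaptation_phase_window("early"),
                          late = adaptation_phase_window("late"),
                          response_window = c(0, 0.2),
                          peak_width_s = 0.02, bin_s = 0.002) {
  orientations <- sort(unique(schedule$orientations))
  iv_e <- switch_windows(schedule, switch_types, early)
  iv_l <- switch_windows(schedule, switch_types, late)
  fr_e <- frames_in_intervals(schedule$frames, iv_e)
  fr_l <- frames_in_intervals(schedule$frames, iv_l)
  fr_all <- rbind(fr_e, fr_l)
  if (nrow(fr_all) == 0) stop("no presentations in the requested windows")

  # pooled per-orientation PSTH to locate the peak of the preferred one
  edges <- seq(response_window[1], response_window[2], by = bin_s)
  centres <- edges[-1] - bin_s / 2
  ofac <- factor(fr_all$orientation_deg, levels = orientations)
  n_per_ori <- tabulate(ofac, length(orientations))
  psth <- t(vapply(seq_along(centres), function(j) {
    cnt <- count_in_windows(spikes, fr_all$onset_s + edges[j],
                            fr_all$onset_s + edges[j + 1])
    vapply(split(cnt, ofac), sum, numeric(1)) /
      (pmax(n_per_ori, 1) * bin_s)
  }, numeric(length(orientations))))    # bins x orientations
  if (all(psth == 0)) stop("flat response; no peak identifiable")
  pk <- arrayInd(which.max(psth), dim(psth))
  peak_time <- centres[pk[1]]
  pref <- orientations[pk[2]]

  win_lo <- peak_time - peak_width_s / 2
  curve_in <- function(fr) {
    starts <- fr$onset_s + win_lo
    cn <- count_in_windows(spikes, starts, starts + peak_width_s)
    vapply(orientations, function(o) {
      sel <- fr$orientation_deg == o
      if (!any(sel)) return(NA_real_)
      mean(cn[sel]) / peak_width_s
    }, numeric(1))
  }
  structure(list(early = curve_in(fr_e), late = curve_in(fr_l),
                 orientations = orientations, peak_time_s = peak_time,
                 pref_orientation = pref,
                 n_presentations = c(early = nrow(fr_e),
                                     late = nrow(fr_l))),
            class = "tuning_pair")
}

#' Gain and offset of tuning modulation
#'
#' Ordinary least squares of the late-phase mean responses on the
#' early-phase ones, orientation by orientation.  A purely multiplicative
#' (gain) modulation gives a line through the origin with slope equal to
#' the gain change; a purely additive modulation gives slope 1 with a
#' non-zero intercept.
#'
#' @param early,late numeric tuning curves (same length), or a
#'   `tuning_pair` passed as `early`
#' @return list of class `gain_offset`: `slope`, `intercept`, `r_squared`,
#'   `flagged` (`TRUE` when the early curve has no variance)
#' @export
gain_offset_regression <- function(early, late = NULL) {
  if (inherits(early, "tuning_pair")) {
    late <- early$late
    early <- early$early
  }
  stopifnot(length(early) == length(late), length(early) >= 3)
  if (stats::var(early) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, flagged = TRUE),
                     class = "gain_offset"))
  fit <- stats::lm(late ~ early)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 flagged = FALSE),
            class = "gain_offset")
}

# Profiled single-von-Mises fits: for fixed (theta_pref, kappa) every model
# below is linear in its gains/offsets, so the outer search is only 2-D.
# `design` maps the basis evaluated on the doubled-angle grid to the model's
# regression columns over the 24 stacked (early, late) points.
vm_model_rss <- function(theta, kappa, y, th, design, w) {
  b <- vm_tuning(th, theta, kappa)
  fit <- stats::lm.wfit(design(b), y, w)
  sum(w * fit$residuals^2)
}

fit_shared_vm <- function(y, th, design, starts, w = rep(1, length(y))) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(c(starts$theta[s], log(starts$kappa[s])),
                   function(p) vm_model_rss(p[1], exp(p[2]), y, th, design,
                                            w),
                   method = "Nelder-Mead",
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  theta <- best$par[1] %% 180
  kappa <- exp(best$par[2])
  b <- vm_tuning(th, theta, kappa)
  fit <- stats::lm.wfit(design(b), y, w)
  list(theta = theta, kappa = kappa, coef = fit$coefficients,
       rss = sum(w * fit$residuals^2))
}

# Re-evaluate a fitted model at candidate (theta, kappa) locations found by
# the other models; keeps each model at least as good as any nested-model
# optimum, so the RSS nesting inequalities hold by construction.
refine_vm <- function(fit, y, th, design, cands, w = rep(1, length(y))) {
  for (j in seq_len(nrow(cands))) {
    r <- vm_model_rss(cands$theta[j], cands$kappa[j], y, th, design, w)
    if (r < fit$rss - 1e-12) {
      b <- vm_tuning(th, cands$theta[j], cands$kappa[j])
      lf <- stats::lm.wfit(design(b), y, w)
      fit <- list(theta = cands$theta[j], kappa = cands$kappa[j],
                  coef = lf$coefficients, rss = sum(w * lf$residuals^2))
    }
  }
  fit
}

tk <- function(...) {
  fits <- list(...)
  data.frame(theta = vapply(fits, `[[`, numeric(1), "theta"),
             kappa = vapply(fits, `[[`, numeric(1), "kappa"))
}

#' Four-model comparison of tuning modulation
#'
#' Fits four single-peaked von Mises models to the stacked early and late
#' tuning curves (n = 24 points): (m1) one shared curve for both phases;
#' (m2) two fully independent curves; (m3) shared gain, free offsets;
#' (m4) shared offset, free gains.  m3 and m4 share the preferred
#' orientation and concentration across phases, isolating gain vs offset as
#' the only contrasts.  `AIC = n log(RSS/n) + 2k` is reported per model;
#' selection and classification use the small-sample corrected AICc
#' (n = 24 points), which guards against over-selecting the 8-parameter
#' model.  Classification is two-stage: a nested F test of m2 against m1
#' (`p_modulation`) gates significant tuning modulation at the 5% level;
#' ungated neurons are `no_change`, gated neurons take the AICc-best of
#' m2 (`both`), m3 (`additive_only`) and m4 (`gain_only`).  `m1_poorest`
#' additionally reports whether m1 was the worst model of the four.
#'
#' @param early,late numeric tuning curves, or a `tuning_pair` as `early`
#' @param orientations orientation grid in degrees
#' @param weighting `"poisson"` (default) weights each point by the inverse
#'   of its rate, matching the mean-proportional variance of spike counts;
#'   `"none"` gives ordinary unweighted least squares
#' @return object of class `tuning_model_comparison`: per-model `rss`,
#'   `n_params`, `aic`, `aicc`, plus `best_model`, `classification` and
#'   `m1_poorest`
#' @export
compare_models <- function(early, late = NULL,
                           orientations = seq(0, 165, by = 15),
                           weighting = c("poisson", "none")) {
  weighting <- match.arg(weighting)
  if (inherits(early, "tuning_pair")) {
    orientations <- early$orientations
    late <- early$late
    early <- early$early
  }
  stopifnot(length(early) == length(late),
            length(early) == length(orientations))
  th <- c(orientations, orientations)
  y <- c(early, late)
  n <- length(y)
  # spike-count curves have variance proportional to their mean; inverse-
  # variance weights keep the AIC comparison calibrated (only the relative
  # weights matter, so the count-to-rate scale need not be known).  The
  # mean rate is estimated from the cross-phase average so the weights do
  # not correlate with the individual residuals.
  mu <- rep((early + late) / 2, 2)
  w <- if (weighting == "poisson") 1 / pmax(mu, mean(mu) / 10, 1e-9)
       else rep(1, n)
  ph_l <- rep(c(0, 1), each = length(orientations))
  starts0 <- expand.grid(theta = orientations[seq(1, length(orientations),
                                                  by = 2)],
                         kappa = c(0.5, 2, 8))

  # m1: shared single von Mises (offset + gain * basis)
  d1 <- function(b) cbind(1, b)
  m1 <- fit_shared_vm(y, th, d1, starts0, w)
  starts1 <- rbind(starts0, data.frame(theta = m1$theta, kappa = m1$kappa))

  # m3: shared gain, per-phase offsets
  d3 <- function(b) cbind(1 - ph_l, ph_l, b)
  m3 <- fit_shared_vm(y, th, d3, starts1, w)
  # m4: shared offset, per-phase gains
  d4 <- function(b) cbind(1, b * (1 - ph_l), b * ph_l)
  m4 <- fit_shared_vm(y, th, d4, starts1, w)

  # m2: fully independent single von Mises per phase
  starts2 <- rbind(starts1,
                   data.frame(theta = c(m3$theta, m4$theta),
                              kappa = c(m3$kappa, m4$kappa)))
  w_e <- w[ph_l == 0]
  w_l <- w[ph_l == 1]
  fe <- fit_shared_vm(early, orientations, d1, starts2, w_e)
  fl <- fit_shared_vm(late, orientations, d1, starts2, w_l)

  # cross-seed refinement: each model also gets the optima the others
  # found, so no model is penalised by a locally stuck 2-D search and the
  # nesting inequalities (m2 <= m3, m4 <= m1) hold exactly
  m1 <- refine_vm(m1, y, th, d1, tk(m3, m4, fe, fl), w)
  m3 <- refine_vm(m3, y, th, d3, tk(m1, fe, fl), w)
  m4 <- refine_vm(m4, y, th, d4, tk(m1, fe, fl), w)
  fe <- refine_vm(fe, early, orientations, d1, tk(m1, m3, m4), w_e)
  fl <- refine_vm(fl, late, orientations, d1, tk(m1, m3, m4), w_l)
  m2_rss <- fe$rss + fl$rss

  rss <- c(m1 = m1$rss, m2 = m2_rss, m3 = m3$rss, m4 = m4$rss)
  k <- c(m1 = 4, m2 = 8, m3 = 5, m4 = 5)
  aic <- n * log(pmax(rss, 1e-12) / n) + 2 * k
  # small-sample correction; with n = 24 points the plain AIC over-selects
  # the 8-parameter model, so selection and classification use AICc
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  best <- names(which.min(aicc))
  # two-stage decision: a nested F test (m2 vs m1) gates "significant
  # modulation" at the nominal error rate; only gated neurons are then
  # classified among the modulated models by AICc
  f_stat <- ((rss[["m1"]] - rss[["m2"]]) / (k[["m2"]] - k[["m1"]])) /
    (rss[["m2"]] / (n - k[["m2"]]))
  p_modulation <- stats::pf(max(f_stat, 0), k[["m2"]] - k[["m1"]],
                            n - k[["m2"]], lower.tail = FALSE)
  classification <- if (p_modulation >= 0.05) "no_change" else {
    switch(names(which.min(aicc[c("m2", "m3", "m4")])),
           m2 = "both", m3 = "additive_only", m4 = "gain_only")
  }
  structure(list(rss = rss, n_params = k, aic = aic, aicc = aicc, n = n,
                 best_model = best, classification = classification,
                 p_modulation = p_modulation,
                 m1_poorest = which.max(aicc) == 1L,
                 fits = list(m1 = m1, m3 = m3, m4 = m4,
                             m2 = list(early = fe, late = fl))),
            class = "tuning_model_comparison")
}

#' @export
print.tuning_model_comparison <- function(x, ...) {
  cat(sprintf("<tuning_model_comparison> best %s (%s)\n  AIC: %s\n",
              x$best_model, x$classification,
              paste(sprintf("%s %.1f", names(x$aic), x$aic),
                    collapse = ", ")))
  invisible(x)
}
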