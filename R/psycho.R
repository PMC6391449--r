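#' Default orientation-difference levels
#'
#' Fourteen log-spaced levels of orientation difference, seven clockwise
#' (positive) and seven counter-clockwise (negative), symmetric about zero.
#'
#' @param min_deg,max_deg smallest and largest |delta| in degrees
#' @param n_per_side levels per direction (default 7)
#' @return sorted numeric vector of length `2 * n_per_side`
#' @export
default_delta_levels <- function(min_deg = 0.5, max_deg = 8,
                                 n_per_side = 7) {
  stopifnot(min_deg > 0, max_deg > min_deg)
  pos <- exp(seq(log(min_deg), log(max_deg), length.out = n_per_side))
  sort(c(-pos, pos))
}

#' Simulate a cumulative-Gaussian psychophysical observer
#'
#' The observer reports clockwise with probability
#' `Phi((delta - mu) / sigma_phase)`, with different noise in the early
#' (0.2-1.2 s) and late (5-6 s) probe phases after a switch.
#'
#' @param mu bias in degrees
#' @param sigma_early,sigma_late noise SD in degrees per probe phase (> 0)
#' @param levels orientation-difference levels (degrees)
#' @param n_per_level trials per level per phase (>= 15)
#' @param seed integer seed
#' @param condition label stored with the trials (e.g. a switch type)
#' @return data.frame of trials: `delta_ori_deg`, `response` ("CW"/"CCW"),
#'   `probe_phase` ("early"/"late"), `condition`
#' @export
simulate_observer <- function(mu = 0, sigma_early = 3, sigma_late = 3,
                              levels = default_delta_levels(),
                              n_per_level = 20, seed = NULL,
                              condition = "contrast_inc") {
  if (sigma_early <= 0 || sigma_late <= 0) stop("sigma must be positive")
  if (n_per_level < 15)
    warning("fewer than 15 trials per level per phase")
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  one_phase <- function(phase, sigma) {
    delta <- rep(levels, each = n_per_level)
    p_cw <- stats::pnorm((delta - mu) / sigma)
    data.frame(delta_ori_deg = delta,
               response = ifelse(stats::runif(length(delta)) < p_cw,
                                 "CW", "CCW"),
               probe_phase = phase,
               condition = condition,
               stringsAsFactors = FALSE)
  }
  rbind(one_phase("early", sigma_early), one_phase("late", sigma_late))
}

# Probit MLE of (mu, sigma) from trial-level data; glm is the cumulative-
# Gaussian maximum-likelihood fit. Returns NULL on numerical failure.
probit_fit <- function(delta, cw) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, delta), cw,
                                    family = stats::binomial("probit"),
                                    control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  b <- fit$coefficients
  if (!all(is.finite(b))) return(NULL)
  list(mu = -b[1] / b[2], sigma = 1 / b[2],
       loglik = sum(stats::dbinom(cw, 1,
                                  pmin(pmax(fit$fitted.values, 1e-12),
                                       1 - 1e-12), log = TRUE)))
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood probit fit of P(clockwise) against the orientation
#' difference.  The just-noticeable difference is reported as
#' `jnd = sigma * qnorm(0.75)` (the 75%-correct half-threshold); `sigma`
#' itself is returned alongside.  A bootstrap (resampling trials with
#' replacement) gives a percentile confidence interval for the JND.
#' Degenerate data are flagged: `flat` when the fitted slope is
#' non-positive or the curve never leaves 50%, `separation` when responses
#' split perfectly and sigma collapses to the lower bound.
#'
#' @param trials data.frame with `delta_ori_deg` and `response`
#'   ("CW"/"CCW"); typically one probe phase of [simulate_observer()]
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed integer seed for the bootstrap
#' @param conf confidence level (default 0.95)
#' @param sigma_min lower bound for sigma under separation (degrees)
#' @return object of class `psychometric_fit`: `mu`, `sigma`, `jnd`,
#'   `loglik`, `jnd_ci`, `boot_jnd`, `flags`, `n_trials`, `trials`
#' @export
fit_psychometric <- function(trials, n_boot = 1000, seed = NULL,
                             conf = 0.95, sigma_min = 1e-3) {
  stopifnot(all(c("delta_ori_deg", "response") %in% names(trials)))
  delta <- trials$delta_ori_deg
  cw <- as.integer(trials$response == "CW")
  if (length(unique(delta)) < 2)
    stop("need >= 2 orientation-difference levels")
  if (length(unique(cw)) < 2) {
    # observer always answered the same way: nothing to fit
    return(structure(list(mu = NA_real_, sigma = NA_real_, jnd = NA_real_,
                          loglik = NA_real_, jnd_ci = c(NA_real_, NA_real_),
                          boot_jnd = numeric(0), flags = "degenerate",
                          n_trials = length(delta), conf = conf,
                          trials = trials[, c("delta_ori_deg", "response")]),
                     class = "psychometric_fit"))
  }
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)

  flags <- character(0)
  separated <- min(delta[cw == 1]) > max(delta[cw == 0])
  fit <- probit_fit(delta, cw)
  if (is.null(fit) || separated) {
    # perfect separation: the ML slope diverges (any curve steep enough to
    # pass between the groups fits); report sigma at the lower bound
    mu_hat <- mean(c(max(delta[cw == 0]), min(delta[cw == 1])))
    fit <- list(mu = mu_hat, sigma = sigma_min, loglik = 0)
    flags <- c(flags, "separation")
  } else if (fit$sigma <= 0) {
    flags <- c(flags, "flat")
    fit$sigma <- abs(fit$sigma)
  } else if (fit$sigma > 10 * max(abs(delta))) {
    flags <- c(flags, "flat")
  }
  if (fit$sigma < sigma_min) {
    fit$sigma <- sigma_min
    flags <- unique(c(flags, "separation"))
  }
  q75 <- stats::qnorm(0.75)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    n <- length(delta)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- probit_fit(delta[idx], cw[idx])
      boot[b] <- if (is.null(bf) || bf$sigma <= 0) NA_real_
                 else bf$sigma * q75
    }
  }
  alpha <- (1 - conf) / 2
  ci <- if (all(is.na(boot))) c(NA_real_, NA_real_)
        else unname(stats::quantile(boot, c(alpha, 1 - alpha),
                                    na.rm = TRUE))
  structure(list(mu = unname(fit$mu), sigma = unname(fit$sigma),
                 jnd = unname(fit$sigma) * q75, loglik = fit$loglik,
                 jnd_ci = ci, boot_jnd = boot, flags = flags,
                 n_trials = length(delta), conf = conf,
                 trials = trials[, c("delta_ori_deg", "response")]),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_fit> mu %.2f deg, sigma %.2f deg,",
                     " JND %.2f deg [%.2f, %.2f]%s\n"),
              x$mu, x$sigma, x$jnd, x$jnd_ci[1], x$jnd_ci[2],
              if (length(x$flags)) paste0(" (",
                                          paste(x$flags, collapse = ","),
                                          ")") else ""))
  invisible(x)
}

#' Bootstrap comparison of early vs late discrimination thresholds
#'
#' Resamples each phase's trials with replacement `n_boot` times, refits,
#' and forms the bootstrap distribution of the JND difference
#' (late - early).  The p-value is the two-sided exceedance probability of
#' zero.
#'
#' @param fit_early,fit_late `psychometric_fit` objects (with stored
#'   trials)
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed integer seed
#' @return list: `delta_jnd` (point estimate, late - early), `p_boot`,
#'   `boot_delta`
#' @export
compare_thresholds <- function(fit_early, fit_late, n_boot = 1000,
                               seed = NULL) {
  stopifnot(inherits(fit_early, "psychometric_fit"),
            inherits(fit_late, "psychometric_fit"))
  if (length(fit_early$flags) > 0 || length(fit_late$flags) > 0)
    stop("refusing to compare degenerate fits: ",
         paste(unique(c(fit_early$flags, fit_late$flags)), collapse = ", "))
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  boot_one <- function(fit) {
    d <- fit$trials$delta_ori_deg
    cw <- as.integer(fit$trials$response == "CW")
    n <- length(d)
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- probit_fit(d[idx], cw[idx])
      if (is.null(bf) || bf$sigma <= 0) NA_real_
      else bf$sigma * stats::qnorm(0.75)
    }, numeric(1))
  }
  be <- boot_one(fit_early)
  bl <- boot_one(fit_late)
  delta <- bl - be
  delta <- delta[is.finite(delta)]
  if (length(delta) < 10) stop("too few valid bootstrap resamples")
  p_lo <- mean(delta <= 0)
  p_hi <- mean(delta >= 0)
  p <- max(2 * min(p_lo, p_hi), 1 / length(delta))
  list(delta_jnd = fit_late$jnd - fit_early$jnd, p_boot = min(p, 1),
       boot_delta = delta)
}
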