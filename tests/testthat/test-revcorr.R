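test_that("optimized kernel counting equals the naive per-spike oracle exactly", {
  sch <- quick_schedule(120, seed = 21)
  p <- quick_neuron(theta_pref = 75, kappa = 2, gain = 30)
  sp <- simulate_spike_train(p, sch, seed = 22)
  lags <- default_lags()
  sp_use <- sp[sp >= max(lags) & sp < 120 + min(lags)]
  k <- reverse_correlate(sp_use, sch, lags = lags)
  oracle <- naive_revcorr_counts(sp_use, sch, lags)
  expect_identical(unname(k$counts), oracle)
  # counter sums equal the number of spikes used, at every lag
  expect_true(all(colSums(k$counts) == k$n_spikes))
  # normalisation: every lag column of p sums to 1 at machine precision
  expect_equal(colSums(k$p), rep(1, length(lags)), ignore_attr = TRUE)
})

test_that("stimulus-independent spiking gives a flat kernel near 1/12", {
  sch <- quick_schedule(120, seed = 23)
  sp <- poisson_train(30, 120, seed = 24)
  k <- reverse_correlate(sp, sch)
  expect_true(all(abs(k$p - 1 / 12) < 0.03))
  fe <- extract_features(k)
  expect_lt(fe$max_modulation, 0.05)
  v <- assess_selectivity(k, features = fe)
  expect_false(v$is_selective)
  expect_false(v$criteria[["peak_above_baseline"]])
})

test_that("a single spike increments exactly one counter per lag", {
  sch <- quick_schedule(10, seed = 25)
  lags <- c(0.01, 0.05)
  t_spike <- 5.2
  k <- reverse_correlate(t_spike, sch, lags = lags)
  expect_equal(colSums(k$counts), c(1, 1), ignore_attr = TRUE)
  for (j in 1:2) {
    fr <- sch$frames
    active <- which(fr$onset_s <= t_spike - lags[j] &
                      t_spike - lags[j] < fr$onset_s + fr$duration_s)
    o <- as.character(fr$orientation_deg[active])
    expect_equal(unname(k$counts[o, j]), 1L)
    expect_equal(sum(k$counts[, j]), 1L)
  }
})

test_that("kernel features recover a constructed rectangular bump", {
  lags <- default_lags()
  n_ori <- 12
  p <- matrix(1 / n_ori, n_ori, length(lags))
  bump <- lags >= 0.040 & lags <= 0.060
  h <- 0.1
  p[5, bump] <- 1 / n_ori + h
  p[-5, bump] <- (1 - p[5, bump][1]) / (n_ori - 1)
  kern <- structure(list(p = p, counts = NULL, n_spikes = 1000,
                         lags_s = lags, orientations = seq(0, 165, 15),
                         window_label = "toy", empty = FALSE),
                    class = "orientation_kernel")
  fe <- extract_features(kern)
  expect_equal(fe$theta_pref_deg, 60)   # 5th orientation
  expect_gte(fe$peak_time_ms, 40)
  expect_lte(fe$peak_time_ms, 60)
  expect_equal(fe$temporal_width_ms, 20, tolerance = 0.05)
  expect_equal(fe$max_modulation, h * (1 + 1 / (n_ori - 1)),
               tolerance = 1e-9)
})

test_that("a uniform kernel has zero modulation and zero width", {
  lags <- default_lags()
  p <- matrix(1 / 12, 12, length(lags))
  kern <- structure(list(p = p, n_spikes = 500, lags_s = lags,
                         orientations = seq(0, 165, 15),
                         window_label = "flat", empty = FALSE),
                    class = "orientation_kernel")
  fe <- extract_features(kern)
  expect_equal(fe$max_modulation, 0)
  expect_equal(fe$temporal_width_ms, 0)
})

test_that("empty kernels are flagged and feature extraction refuses them", {
  sch <- quick_schedule(10, seed = 26)
  k <- reverse_correlate(numeric(0), sch)
  expect_true(k$empty)
  expect_error(extract_features(k), "empty")
  expect_false(assess_selectivity(k)$is_selective)
})

test_that("simulated neurons are recovered: preferred orientation, peak time, width", {
  sch <- generate_schedule(600, seed = 27)
  p <- quick_neuron(theta_pref = 45, kappa = 2.5, gain = 40)
  sp <- simulate_spike_train(p, sch, seed = 28)
  k <- reverse_correlate(sp, sch)
  fe <- extract_features(k)
  expect_equal(fe$theta_pref_deg, 45)   # grid argmax at the peak lag
  expect_lt(abs(fe$peak_time_ms - 50), 2)
  expect_lt(abs(fe$temporal_width_ms - 30), 3)
  v <- assess_selectivity(k, features = fe)
  expect_true(v$is_selective)
  expect_lt(abs(v$fit$theta_pref - 45), 7.5)
})

test_that("max modulation grows monotonically with tuning concentration", {
  kappas <- seq(0.4, 4, length.out = 10)
  mods <- vapply(seq_along(kappas), function(i) {
    sch <- generate_schedule(240, seed = 300 + i)
    p <- quick_neuron(theta_pref = 90, kappa = kappas[i], gain = 35)
    sp <- simulate_spike_train(p, sch, seed = 400 + i)
    extract_features(reverse_correlate(sp, sch))$max_modulation
  }, numeric(1))
  expect_gt(stats::cor(kappas, mods, method = "spearman"), 0.9)
})

test_that("early and late windows use disjoint spike sets", {
  sch <- quick_schedule(120, seed = 29)
  p <- quick_neuron()
  sp <- simulate_spike_train(p, sch, seed = 30)
  iv_e <- switch_windows(sch, NULL, adaptation_phase_window("early"))
  iv_l <- switch_windows(sch, NULL, adaptation_phase_window("late"))
  ke <- reverse_correlate(sp, sch, iv_e, window_label = "early")
  kl <- reverse_correlate(sp, sch, iv_l, window_label = "late")
  k_full <- reverse_correlate(sp, sch)
  expect_lte(ke$n_spikes + kl$n_spikes, k_full$n_spikes)
  # intervals themselves are disjoint
  expect_true(all(iv_e$end_s <= iv_l$start_s |
                    iv_e$start_s >= iv_l$end_s))
})

test_that("difference-of-von-Mises fitting recovers single-component curves", {
  set.seed(55)
  th <- seq(0, 165, 15)
  errs <- vapply(1:30, function(i) {
    tp <- stats::runif(1, 0, 180)
    y <- 0.08 + 0.15 * adaptcode:::vm_tuning(th, tp, 2.5) +
      stats::rnorm(12, 0, 0.004)
    fit <- fit_diff_von_mises(y, th)
    d <- abs(fit$theta_pref - tp)
    min(d, 180 - d)
  }, numeric(1))
  expect_lt(stats::median(errs), 7.5)
  expect_lt(mean(errs > 7.5), 0.2)
})

test_that("a flat tuning curve is not significantly better than a line", {
  set.seed(56)
  y <- rep(0.083, 12) + stats::rnorm(12, 0, 1e-4)
  fit <- fit_diff_von_mises(y)
  expect_gte(fit$f_test_p, 0.05)
})

test_that("two components beat one on asymmetric curves (nested RSS)", {
  th <- seq(0, 165, 15)
  y <- 0.2 * adaptcode:::vm_tuning(th, 40, 3) -
    0.08 * adaptcode:::vm_tuning(th, 120, 5) + 0.1
  f2 <- fit_diff_von_mises(y, th, components = 2)
  f1 <- fit_diff_von_mises(y, th, components = 1)
  expect_lt(f2$rss, f1$rss)
})

test_that("an ultra-narrow fitted curve fails the bandwidth criterion", {
  th <- seq(0, 165, 15)
  y <- 0.05 + 0.3 * adaptcode:::vm_tuning(th, 45, 40)
  fit <- fit_diff_von_mises(y, th)
  expect_lt(fit$bandwidth_deg, 20)
  lags <- default_lags()
  p <- matrix(1 / 12, 12, length(lags))
  p[, lags >= 0] <- y / sum(y)
  kern <- structure(list(p = p, n_spikes = 5000, lags_s = lags,
                         orientations = th, window_label = "narrow",
                         empty = FALSE),
                    class = "orientation_kernel")
  v <- assess_selectivity(kern, fit = fit)
  expect_false(v$criteria[["bandwidth_ok"]])
})
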