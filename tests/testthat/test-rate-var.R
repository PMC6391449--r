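test_that("a homogeneous Poisson train yields a flat PSTH that conserves spike mass", {
  set.seed(81)
  sp <- poisson_train(20, 600)
  events <- seq(10, 590, by = 10)
  ps <- switch_psth(sp, events, session_len_s = 600)
  expect_equal(ps$n_repetitions, length(events))
  # mass conservation: bins x width x rate x reps = spikes counted
  total <- sum(ps$bins$rate_hz * ps$bin_s * ps$n_repetitions)
  manual <- sum(vapply(events, function(t0)
    sum(sp >= t0 - 5 & sp < t0 + 5), numeric(1)))
  expect_equal(total, manual)
  bin_se <- sqrt(20 / (ps$bin_s * ps$n_repetitions))
  expect_lt(max(abs(ps$bins$rate_hz - 20)), 4.5 * bin_se)
  ps <- shuffle_normalize(ps, sp, n_shuffles = 50, seed = 82)
  expect_lt(abs(mean(ps$bins$rate_norm) - 1), 0.05)
})

test_that("a rate step at the switch appears as a PSTH step at t = 0", {
  set.seed(83)
  # 10 sp/s before each event, 30 sp/s for 5 s after
  events <- seq(10, 590, by = 20)
  lo <- poisson_train(10, 600)
  keep_hi <- function(t) {
    k <- findInterval(t, events)
    d <- t - events[pmax(k, 1)]
    k >= 1 & d < 5
  }
  hi <- poisson_train(20, 600)
  sp <- sort(c(lo, hi[keep_hi(hi)]))
  ps <- switch_psth(sp, events, session_len_s = 600)
  pre <- mean(ps$bins$rate_hz[ps$bins$time_s < 0 & ps$bins$time_s > -5])
  post <- mean(ps$bins$rate_hz[ps$bins$time_s > 0 & ps$bins$time_s < 5])
  expect_gt(post / pre, 2.4)
  expect_lt(post / pre, 3.6)
  # the step is aligned: the first post bin is already high
  first_post <- ps$bins$rate_hz[which(ps$bins$time_s > 0)[1]]
  expect_gt(first_post, 20)
})

test_that("doubling repetitions roughly halves PSTH variance per bin", {
  set.seed(84)
  var_at <- function(n_events) {
    mean(vapply(1:8, function(i) {
      sp <- poisson_train(15, 30 * n_events + 20)
      events <- seq(10, by = 30, length.out = n_events)
      ps <- switch_psth(sp, events, session_len_s = 30 * n_events + 20)
      stats::var(ps$bins$rate_hz)
    }, numeric(1)))
  }
  v1 <- var_at(20)
  v2 <- var_at(40)
  expect_gt(v1 / v2, 1.4)
  expect_lt(v1 / v2, 2.8)
})

test_that("shuffle normalisation handles silent neurons and flattens with many shuffles", {
  ps <- switch_psth(c(1, 2, 3), 50, session_len_s = 100)
  ps_silent <- shuffle_normalize(ps, numeric(0), seed = 1)
  expect_true(isTRUE(attr(ps_silent, "flagged_silent")))
  expect_true(all(is.na(ps_silent$bins$rate_norm)))
  # shuffled PSTH flattens as n_shuffles grows
  set.seed(85)
  sp <- poisson_train(20, 300)
  events <- seq(10, 290, by = 10)
  p1 <- shuffle_normalize(switch_psth(sp, events, session_len_s = 300),
                          sp, n_shuffles = 4, seed = 86)
  p2 <- shuffle_normalize(switch_psth(sp, events, session_len_s = 300),
                          sp, n_shuffles = 64, seed = 87)
  expect_lt(stats::var(p2$bins$rate_shuffle),
            stats::var(p1$bins$rate_shuffle))
})

test_that("rate doubling after the switch gives a ~2:1 normalised plateau", {
  set.seed(88)
  events <- seq(10, 590, by = 20)     # 5 s post window inside 20 s spacing
  lo <- poisson_train(10, 600)
  hi <- poisson_train(10, 600)
  d <- hi - events[pmax(findInterval(hi, events), 1)]
  sp <- sort(c(lo, hi[findInterval(hi, events) >= 1 & d >= 0 & d < 5]))
  ps <- switch_psth(sp, events, session_len_s = 600)
  ps <- shuffle_normalize(ps, sp, n_shuffles = 30, seed = 89)
  post <- mean(ps$bins$rate_norm[ps$bins$time_s > 0.5 &
                                   ps$bins$time_s < 4.5])
  pre <- mean(ps$bins$rate_norm[ps$bins$time_s < -0.5 &
                                  ps$bins$time_s > -4.5])
  expect_equal(post / pre, 2, tolerance = 0.15)
})

test_that("exponential decay fits recover tau within 15%", {
  set.seed(91)
  taus <- vapply(1:20, function(i) {
    t <- seq(-5, 5, by = 0.05)[-1] - 0.025
    y <- 1 + 0.8 * exp(-pmax(t, 0) / 0.7) + stats::rnorm(length(t), 0, 0.04)
    ps <- structure(list(bins = data.frame(time_s = t, rate_hz = y,
                                           rate_norm = y),
                         bin_s = 0.05, span_s = 5, n_repetitions = 50,
                         events = numeric(0), session_len_s = 0),
                    class = "switch_psth")
    fit_decay(ps)$tau_s
  }, numeric(1))
  expect_lt(abs(stats::median(taus) - 0.7) / 0.7, 0.15)
  expect_gt(mean(abs(taus - 0.7) / 0.7 < 0.15), 0.6)
})

test_that("a flat PSTH is flagged low-amplitude", {
  t <- seq(-5, 5, by = 0.05)[-1] - 0.025
  set.seed(92)
  y <- 1 + stats::rnorm(length(t), 0, 0.01)
  ps <- structure(list(bins = data.frame(time_s = t, rate_hz = y,
                                         rate_norm = y),
                       bin_s = 0.05, span_s = 5, n_repetitions = 50,
                       events = numeric(0), session_len_s = 0),
                  class = "switch_psth")
  fit <- fit_decay(ps)
  expect_true("low_amplitude" %in% fit$flags)
})

test_that("asymmetric adaptation time constants are recovered (dec ~ 2x inc)", {
  sch <- generate_schedule(3000, seed = 93)
  p <- adapting_neuron(theta_pref = 20, kappa = 2, peak_rate = 40)
  sp <- simulate_spike_train(p, sch, seed = 94)
  ev <- classify_switches(sch)
  tau_of <- function(type) {
    ps <- switch_psth(sp, ev$time_s[ev$switch_type == type],
                      session_len_s = 3000)
    ps <- shuffle_normalize(ps, sp, n_shuffles = 30, seed = 95)
    fit_decay(ps)$tau_s
  }
  ratio <- tau_of("contrast_dec") / tau_of("contrast_inc")
  expect_gt(ratio, 1.2)   # generative ratio 1.2/0.6 = 2
  expect_lt(ratio, 3.5)
})

test_that("Fano factor matches hand computation and degenerate cases", {
  # counts 1, 2, 3 across three repetitions -> FF = var/mean = 1/2
  events <- c(100, 200, 300)
  sp <- sort(c(100.001, 200.001, 200.002, 300.001, 300.002, 300.003))
  fs <- suppressWarnings(fano_series(sp, events, span_s = 0,
                                     session_len_s = 400))
  expect_equal(nrow(fs), 1)
  expect_equal(fs$fano, 0.5)
  expect_equal(fs$mean_count, 2)
  # identical counts every repetition -> FF = 0
  sp2 <- sort(c(events + 0.001, events + 0.002))
  fs2 <- suppressWarnings(fano_series(sp2, events, span_s = 0,
                                      session_len_s = 400))
  expect_equal(fs2$fano, 0)
  # zero-mean windows are NA
  fs3 <- suppressWarnings(fano_series(numeric(0), events, span_s = 0,
                                      session_len_s = 400))
  expect_true(is.na(fs3$fano))
})

test_that("Poisson spiking has Fano near 1 across the sliding series", {
  set.seed(96)
  sp <- poisson_train(30, 500)
  events <- seq(5, 495, by = 2.5)     # 197 stationary "switches"
  fs <- fano_series(sp, events, session_len_s = 500)
  expect_equal(nrow(fs), 101)
  expect_gt(mean(fs$fano), 0.9)
  expect_lt(mean(fs$fano), 1.1)
})
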