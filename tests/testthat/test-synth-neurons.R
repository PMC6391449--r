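test_that("parameter validation catches bad inputs", {
  expect_error(neuron_params(200, 2, 10), "theta_pref")
  expect_error(neuron_params(45, 2, -1), "steady_gain")
  expect_error(neuron_params(45, 2, 10, tau_adapt = 0), "tau_adapt")
  expect_error(neuron_params(45, 2, 10, dispersion = 0), "dispersion")
  expect_error(neuron_params(45, 2, 10, latency = 0.3), "latency")
})

test_that("an untuned neuron's rate is orientation independent", {
  sch <- quick_schedule(20, seed = 2)
  p <- quick_neuron(kappa = 0, gain = 20, offset = 5)
  # steady interior of epoch 1: gain constant, drive = 1 when kappa = 0
  t <- seq(1, 4.5, by = 0.01)
  r <- instantaneous_rate(p, sch, t)
  expect_true(all(abs(r - r[1]) < 1e-9))
  expect_equal(r[1], 25)   # offset + gain * 1
})

test_that("rate is zero before the first frame plus latency", {
  sch <- quick_schedule(20, seed = 2)
  p <- quick_neuron()
  expect_equal(instantaneous_rate(p, sch, c(0, 0.01, 0.03)), c(0, 0, 0))
  expect_gt(instantaneous_rate(p, sch, 0.5), 0)
})

test_that("the tuning factor peaks (at 1) for the preferred orientation", {
  f <- adaptcode:::vm_tuning(seq(0, 175, 5), 45, 3)
  expect_equal(max(f), 1)
  expect_equal(which.max(f), which(seq(0, 175, 5) == 45))
  # period 180: same value at theta and theta + 180
  expect_equal(adaptcode:::vm_tuning(10, 45, 3),
               adaptcode:::vm_tuning(190, 45, 3))
})

test_that("gain relaxes exponentially: continuity and 63.2% closure at tau", {
  sch <- generate_schedule(20, seed = 31)
  gains <- c(L70C35 = 10, L70C65 = 40, L140C35 = 15, L140C65 = 25)
  p <- neuron_params(0, 1, steady_gain = gains, offset = 0, tau_adapt = 1)
  traj <- gain_trajectory(p, sch)
  for (e in 2:nrow(traj)) {
    g_end_prev <- traj$g_ss[e - 1] +
      (traj$g_start[e - 1] - traj$g_ss[e - 1]) * exp(-5 / traj$tau[e - 1])
    expect_equal(traj$g_start[e], g_end_prev)   # continuous across switch
  }
  # at t = t_switch + tau the gap to g_ss has closed by 1 - exp(-1)
  e2 <- which(abs(traj$g_start - traj$g_ss) > 1e-9)[1]   # a real transition
  g_at_tau <- traj$g_ss[e2] + (traj$g_start[e2] - traj$g_ss[e2]) * exp(-1)
  closed <- (g_at_tau - traj$g_start[e2]) / (traj$g_ss[e2] - traj$g_start[e2])
  expect_equal(closed, 1 - exp(-1))
})

test_that("transient multipliers reset the post-switch gain", {
  sch <- generate_schedule(60, seed = 33)
  p <- adapting_neuron()
  traj <- gain_trajectory(p, sch)
  ev <- classify_switches(sch)
  i <- which(ev$switch_type == "contrast_inc")[1]
  expect_equal(traj$g_start[i + 1], 1.8 * traj$g_ss[i + 1])
  j <- which(ev$switch_type == "luminance_inc")[1]
  expect_equal(traj$g_start[j + 1], 0.45 * traj$g_ss[j + 1])
})

test_that("homogeneous limit: spike counts match Poisson expectation", {
  sch <- quick_schedule(60, seed = 4)
  p <- quick_neuron(kappa = 0, gain = 15, offset = 0)   # constant 15 sp/s
  n <- vapply(1:20, function(s)
    length(simulate_spike_train(p, sch, seed = 100 + s)), numeric(1))
  expected <- 15 * (60 - 0.05 - 0.015)   # latency + half kernel dead time
  se <- sqrt(expected / 20)
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("zero gain and offset produce an empty spike train", {
  sch <- quick_schedule(10, seed = 5)
  p <- quick_neuron(gain = 0, offset = 0)
  expect_length(simulate_spike_train(p, sch, seed = 1), 0)
})

test_that("rate integral matches the expected spike count (Monte Carlo)", {
  sch <- quick_schedule(60, seed = 6)
  p <- adapting_neuron(theta_pref = 30, kappa = 2)
  tg <- seq(0, 60, by = 0.002)
  lam <- instantaneous_rate(p, sch, tg[-1] - 0.001)
  expected <- sum(lam) * 0.002
  n <- vapply(1:15, function(s)
    length(simulate_spike_train(p, sch, seed = 200 + s)), numeric(1))
  expect_lt(abs(mean(n) - expected), 4 * sqrt(expected / 15))
})

test_that("time-rescaled Poisson ISIs are Exp(1) (KS test)", {
  sch <- quick_schedule(300, seed = 7)
  p <- quick_neuron(theta_pref = 120, kappa = 2, gain = 40)
  sp <- simulate_spike_train(p, sch, seed = 8)
  # numeric integrated rate evaluated at spike times
  tg <- seq(0, 300, by = 5e-4)
  lam <- instantaneous_rate(p, sch, tg[-1] - 2.5e-4)
  Lam <- c(0, cumsum(lam * 5e-4))
  resc <- stats::approx(tg, Lam, xout = sp)$y
  ks <- stats::ks.test(diff(resc), "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("spiking is reproducible from the seed, population-wide", {
  sch <- quick_schedule(30, seed = 9)
  pl <- sample_neuron_params(3, seed = 10)
  a <- simulate_population(pl, sch, seed = 11)
  b <- simulate_population(pl, sch, seed = 11)
  expect_identical(a$spikes, b$spikes)
  d <- simulate_population(pl, sch, seed = 12)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("spike trains round-trip through CSV, ground truth through JSON", {
  sch <- quick_schedule(30, seed = 13)
  pl <- sample_neuron_params(2, seed = 14)
  rec <- simulate_population(pl, sch, seed = 15)
  f <- tempfile(fileext = ".csv")
  write_spikes(rec, f)
  back <- read_spikes(f)
  expect_equal(back[[names(rec$spikes)[1]]], rec$spikes[[1]])
  g <- tempfile(fileext = ".json")
  write_ground_truth(rec, g)
  truth <- jsonlite::read_json(g, simplifyVector = FALSE)
  expect_equal(truth[[1]]$theta_pref, pl[[1]]$theta_pref)
  unlink(c(f, g))
})
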