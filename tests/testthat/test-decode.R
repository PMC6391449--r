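# One mid-size recording shared by the decoding tests.
dec_sch <- generate_schedule(1200, seed = 101)
dec_rec <- simulate_population(sample_neuron_params(20, seed = 102),
                               dec_sch, seed = 103)

test_that("response matrices have the right shape and disjoint phases", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 104)
  expect_s3_class(rm_e, "response_matrix")
  expect_equal(dim(rm_e$counts)[1], 12)
  expect_equal(dim(rm_e$counts)[2], 20)
  expect_gt(dim(rm_e$counts)[3], 50)
  expect_true(all(rm_e$counts >= 0))
  # early and late phase windows select disjoint presentation sets
  iv_e <- switch_windows(dec_sch, "contrast_inc",
                         adaptation_phase_window("early"))
  iv_l <- switch_windows(dec_sch, "contrast_inc",
                         adaptation_phase_window("late"))
  fe <- adaptcode:::frames_in_intervals(dec_sch$frames, iv_e)
  fl <- adaptcode:::frames_in_intervals(dec_sch$frames, iv_l)
  expect_length(intersect(fe$onset_s, fl$onset_s), 0)
})

test_that("z-scoring is idempotent and exact on the training block", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 105)
  z1 <- zscore_normalize(rm_e)
  mu <- apply(z1$counts, 2, mean)
  sdv <- apply(z1$counts, 2, sd)
  expect_true(all(abs(mu) < 1e-12))
  expect_true(all(abs(sdv - 1) < 1e-12))
  z2 <- zscore_normalize(z1)
  expect_equal(z2$counts, z1$counts, tolerance = 1e-10)
  # constant-count neurons are dropped with a warning
  bad <- rm_e
  bad$counts[, 3, ] <- 7
  expect_warning(zb <- zscore_normalize(bad), "constant")
  expect_equal(dim(zb$counts)[2], 19)
})

test_that("shuffled labels decode at chance (binomial CI)", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 106)
  d0 <- decode_orientation(rm_e, n_runs = 10, n_neurons = 20, seed = 107,
                           shuffle_labels = TRUE)
  n_test <- 12 * (dim(rm_e$counts)[3] -
                    floor(0.7 * dim(rm_e$counts)[3])) * 10
  ci <- 3 * sqrt((1 / 12) * (11 / 12) / n_test)
  expect_lt(abs(d0$accuracy_mean - 1 / 12), ci + 0.01)
})

test_that("decoding is deterministic given the seed and beats chance on signal", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 108)
  d1 <- decode_orientation(rm_e, n_runs = 5, seed = 109)
  d2 <- decode_orientation(rm_e, n_runs = 5, seed = 109)
  expect_identical(d1$accuracy_runs, d2$accuracy_runs)
  expect_gt(d1$accuracy_mean, 2 / 12)   # well above 1/12 chance
  # training accuracy is at least test accuracy on average
  expect_gte(mean(d1$train_accuracy_runs), mean(d1$accuracy_runs))
})

test_that("the two linear classifiers agree and z-scoring changes little", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 110)
  lda <- decode_orientation(rm_e, "lda", n_runs = 6, seed = 111)
  svm <- decode_orientation(rm_e, "svm", n_runs = 6, seed = 111)
  expect_lt(abs(lda$accuracy_mean - svm$accuracy_mean), 0.05)
  raw <- decode_orientation(rm_e, "lda", n_runs = 6, seed = 111,
                            zscore = FALSE)
  expect_lt(abs(lda$accuracy_mean - raw$accuracy_mean), 0.02)
})

test_that("the in-package shrinkage LDA matches MASS::lda where both apply", {
  skip_if_not_installed("MASS")
  set.seed(112)
  n <- 120; p <- 5
  mu <- matrix(stats::rnorm(3 * p, sd = 1.5), 3, p)
  y <- sample(1:3, n, replace = TRUE)
  X <- mu[y, ] + matrix(stats::rnorm(n * p), n, p)
  mdl <- adaptcode:::rlda_train(X, as.character(y), lambda = 1e-6)
  ours <- adaptcode:::rlda_predict(mdl, X)
  ref <- as.character(stats::predict(MASS::lda(X, grouping = y))$class)
  expect_gt(mean(ours == ref), 0.98)
})

test_that("accuracy is non-decreasing in population size on average", {
  rm_e <- build_response_matrix(dec_rec, "contrast_inc",
                                adaptation_phase_window("early"),
                                seed = 113)
  sizes <- c(4, 8, 12, 16, 20)
  acc <- vapply(sizes, function(k)
    decode_orientation(rm_e, n_runs = 6, n_neurons = k,
                       seed = 114)$accuracy_mean, numeric(1))
  expect_gt(stats::cor(sizes, acc, method = "spearman"), 0.8)
})

test_that("early/late comparison flips sign between contrast and luminance increments", {
  el <- early_late_comparison(dec_rec,
                              switch_types = c("contrast_inc",
                                               "luminance_inc"),
                              seed = 115, n_runs = 8, n_neurons = 20)
  expect_equal(nrow(el), 2)
  ci <- el[el$switch == "contrast_inc", ]
  li <- el[el$switch == "luminance_inc", ]
  expect_gt(ci$acc_early, ci$acc_late)   # gain overshoot decays
  expect_lt(li$acc_early, li$acc_late)   # gain undershoot recovers
  # a missing switch type is skipped with a warning, not an error
  expect_warning(
    el2 <- early_late_comparison(dec_rec,
                                 switch_types = c("contrast_inc",
                                                  "L1C1->L9C9"),
                                 seed = 116, n_runs = 4, n_neurons = 10),
    "skipped")
  expect_equal(nrow(el2), 1)
})

test_that("a stationary population decodes early and late equally", {
  pl <- lapply(1:12, function(i)
    neuron_params(15 * (i - 1), 2.5, steady_gain = 30, offset = 2))
  rec0 <- simulate_population(pl, dec_sch, seed = 117)
  el <- early_late_comparison(rec0, switch_types = "contrast_inc",
                              seed = 118, n_runs = 8, n_neurons = 12)
  expect_lt(abs(el$acc_early - el$acc_late),
            3 * sqrt(el$sd_early^2 + el$sd_late^2) + 0.02)
})
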