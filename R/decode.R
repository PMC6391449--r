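#' Build an orientation response matrix
#'
#' Spike counts per (orientation, neuron, trial) for presentations falling
#' in `phase_window` after every matching switch.  Presentations of each
#' orientation are pooled across repetitions of the switch; trials are
#' independently permuted per neuron (destroying trial-by-trial spike-count
#' correlations between neurons, as a correlation-blind decoder requires)
#' and the trial dimension is truncated to the minimum per-orientation
#' presentation count.
#'
#' @param recording a `population_recording` (or a named list of spike
#'   trains plus `schedule`)
#' @param switch_types switch-type and/or pair labels; `NULL` = all
#' @param phase_window window relative to the switch, e.g.
#'   `adaptation_phase_window("early")`
#' @param count_offset_s count-window start after frame onset (s); default
#'   0.0425 centres a 15 ms window on a typical 50 ms kernel peak
#' @param count_width_s count-window width (s), default 0.015
#' @param schedule required when `recording` is a plain list
#' @param seed seed for the per-neuron trial permutation
#' @return object of class `response_matrix`: `counts` array S x N x T,
#'   `orientations`, `count_window`, `phase_window`, `switch_types`
#' @export
build_response_matrix <- function(recording, switch_types = NULL,
                                  phase_window,
                                  count_offset_s = 0.0425,
                                  count_width_s = 0.015,
                                  schedule = NULL, seed = NULL) {
  if (inherits(recording, "population_recording")) {
    schedule <- recording$schedule
    spikes <- recording$spikes
  } else {
    stopifnot(!is.null(schedule))
    spikes <- recording
  }
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  iv <- switch_windows(schedule, switch_types, phase_window)
  if (nrow(iv) == 0) stop("no switch matches `switch_types`")
  fr <- frames_in_intervals(schedule$frames, iv)
  orientations <- sort(unique(schedule$orientations))
  per_ori <- table(factor(fr$orientation_deg, levels = orientations))
  if (any(per_ori == 0))
    stop("at least one orientation has zero presentations in the window")
  T_n <- min(per_ori)
  S <- length(orientations)
  N <- length(spikes)
  starts <- fr$onset_s + count_offset_s
  by_ori <- split(seq_len(nrow(fr)), factor(fr$orientation_deg,
                                            levels = orientations))
  counts <- array(0, dim = c(S, N, T_n),
                  dimnames = list(orientation = orientations,
                                  neuron = names(spikes), trial = NULL))
  for (n in seq_len(N)) {
    cn <- count_in_windows(spikes[[n]], starts, starts + count_width_s)
    for (s in seq_len(S)) {
      idx <- by_ori[[s]]
      counts[s, n, ] <- cn[idx[sample.int(length(idx), T_n)]]
    }
  }
  structure(list(counts = counts, orientations = orientations,
                 count_window = c(offset_s = count_offset_s,
                                  width_s = count_width_s),
                 phase_window = phase_window,
                 switch_types = switch_types),
            class = "response_matrix")
}

#' z-score a response matrix per neuron
#'
#' Centres and scales each neuron's counts.  When `stats` (from a training
#' block) is supplied, the transform uses those statistics; neurons with
#' zero training SD are dropped with a warning.
#'
#' @param matrix a `response_matrix` or a plain S x N x T array
#' @param stats optional list(`mean`, `sd`) per neuron from the training
#'   data
#' @return the input with normalised counts, a `zscored` flag, the `stats`
#'   used, and `dropped` neuron indices
#' @export
zscore_normalize <- function(matrix, stats = NULL) {
  rm_obj <- inherits(matrix, "response_matrix")
  arr <- if (rm_obj) matrix$counts else matrix
  N <- dim(arr)[2]
  if (is.null(stats)) {
    mu <- apply(arr, 2, mean)
    sdv <- apply(arr, 2, stats::sd)
    stats <- list(mean = mu, sd = sdv)
  }
  dropped <- which(!is.finite(stats$sd) | stats$sd == 0)
  if (length(dropped) > 0)
    warning(sprintf("dropping %d constant-count neuron(s)",
                    length(dropped)))
  keep <- setdiff(seq_len(N), dropped)
  out <- arr[, keep, , drop = FALSE]
  for (n in seq_along(keep)) {
    out[, n, ] <- (out[, n, ] - stats$mean[keep[n]]) / stats$sd[keep[n]]
  }
  if (rm_obj) {
    matrix$counts <- out
    matrix$zscored <- TRUE
    matrix$zscore_stats <- stats
    matrix$dropped <- dropped
    matrix
  } else {
    attr(out, "zscore_stats") <- stats
    attr(out, "dropped") <- dropped
    out
  }
}

# Linear discriminant classifier with diagonal-shrinkage pooled covariance.
# lambda blends the pooled covariance with a scaled identity so the solve is
# well posed even when N approaches the trial count.
rlda_train <- function(X, y, lambda = 0.1) {
  classes <- sort(unique(y))
  p <- ncol(X)
  M <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                numeric(p)))
  R <- X - M[match(y, classes), , drop = FALSE]
  S <- crossprod(R) / max(nrow(X) - length(classes), 1)
  # absolute floor keeps the solve well posed even for silent neurons
  S <- (1 - lambda) * S + lambda * max(mean(diag(S)), 1e-8) * diag(p)
  W <- solve(S, t(M))                     # p x K
  b <- -0.5 * colSums(t(M) * W)           # K
  list(classes = classes, W = W, b = b)
}

rlda_predict <- function(model, X) {
  scores <- X %*% model$W + matrix(model$b, nrow(X), length(model$b),
                                   byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}

# Flatten S x N x T array into (S*T) x N design plus labels.
flatten_trials <- function(arr, orientations, trials) {
  S <- dim(arr)[1]
  N <- dim(arr)[2]
  X <- do.call(rbind, lapply(seq_len(S), function(s)
    t(matrix(arr[s, , trials], nrow = N))))
  y <- rep(orientations, each = length(trials))
  list(X = X, y = factor(y, levels = orientations))
}

#' Decode orientation from a response matrix
#'
#' Per run: a random neuron subsample, a stratified random 70/30 train/test
#' split of trials per orientation, z-scoring with training statistics, and
#' a linear classifier (shrinkage LDA, or a linear SVM).  Accuracy is the
#' fraction of correctly classified test presentations, reported as mean
#' and SD over runs.
#'
#' @param matrix a `response_matrix`
#' @param classifier `"lda"` (regularised linear discriminant) or `"svm"`
#'   (linear support vector machine)
#' @param n_runs number of random runs (default 15)
#' @param n_neurons neurons per subsample (default `min(50, N)`)
#' @param train_fraction fraction of trials for training (default 0.7)
#' @param seed integer seed
#' @param zscore z-score with training statistics (default `TRUE`)
#' @param lambda LDA shrinkage intensity (default 0.1)
#' @param shuffle_labels permute orientation labels across all trials (null
#'   control; accuracy should sit at chance 1/S)
#' @return object of class `decoding_result`: `accuracy_mean`,
#'   `accuracy_sd`, `accuracy_runs`, `train_accuracy_runs`, `chance`,
#'   `n_runs`, `n_neurons`, `classifier`
#' @export
decode_orientation <- function(matrix, classifier = c("lda", "svm"),
                               n_runs = 15, n_neurons = NULL,
                               train_fraction = 0.7, seed = NULL,
                               zscore = TRUE, lambda = 0.1,
                               shuffle_labels = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(matrix, "response_matrix"))
  arr <- matrix$counts
  S <- dim(arr)[1]; N <- dim(arr)[2]; T_n <- dim(arr)[3]
  n_neurons <- n_neurons %||% min(50L, N)
  stopifnot(n_neurons <= N, train_fraction > 0, train_fraction < 1)
  n_train <- max(1L, floor(train_fraction * T_n))
  if (n_train >= T_n) stop("not enough trials for a test set")
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)

  acc <- train_acc <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    neurons <- sample.int(N, n_neurons)
    tr <- sample.int(T_n, n_train)
    te <- setdiff(seq_len(T_n), tr)
    sub <- arr[, neurons, , drop = FALSE]
    train <- flatten_trials(sub, matrix$orientations, tr)
    test <- flatten_trials(sub, matrix$orientations, te)
    if (shuffle_labels) {
      train$y <- sample(train$y)
      test$y <- sample(test$y)
    }
    if (zscore) {
      mu <- colMeans(train$X)
      sdv <- apply(train$X, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      train$X <- sweep(sweep(train$X, 2, mu), 2, sdv, "/")
      test$X <- sweep(sweep(test$X, 2, mu), 2, sdv, "/")
    }
    if (classifier == "lda") {
      mdl <- rlda_train(train$X, as.character(train$y), lambda)
      pred_te <- rlda_predict(mdl, test$X)
      pred_tr <- rlda_predict(mdl, train$X)
    } else {
      mdl <- e1071::svm(train$X, train$y, kernel = "linear", scale = FALSE)
      pred_te <- as.character(stats::predict(mdl, test$X))
      pred_tr <- as.character(stats::predict(mdl, train$X))
    }
    acc[r] <- mean(pred_te == as.character(test$y))
    train_acc[r] <- mean(pred_tr == as.character(train$y))
  }
  structure(list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 accuracy_runs = acc, train_accuracy_runs = train_acc,
                 chance = 1 / S, n_runs = n_runs, n_neurons = n_neurons,
                 train_fraction = train_fraction, classifier = classifier),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(paste0("<decoding_result> %s: %.3f +/- %.3f over %d runs",
                     " (%d neurons, chance %.3f)\n"),
              x$classifier, x$accuracy_mean, x$accuracy_sd, x$n_runs,
              x$n_neurons, x$chance))
  invisible(x)
}

#' Early vs late decoding accuracy per switch
#'
#' Decodes orientation separately in the early and late adaptation phases
#' for each requested switch (by default the eight single-parameter ordered
#' condition pairs) and reports both accuracies with a sign test across
#' runs.
#'
#' @param recording a `population_recording`
#' @param switch_types pair and/or type labels; default
#'   `single_param_pairs()$pair`
#' @param early,late phase windows relative to the switch
#' @param seed integer seed
#' @param ... passed to [build_response_matrix()] and
#'   [decode_orientation()] (e.g. `n_runs`, `n_neurons`, `classifier`,
#'   `count_offset_s`)
#' @return data.frame, one row per switch: `switch`, `acc_early`,
#'   `sd_early`, `acc_late`, `sd_late`, `p_sign` (sign test on run-wise
#'   early > late)
#' @export
early_late_comparison <- function(recording, switch_types = NULL,
                                  early = adaptation_phase_window("early"),
                                  late = adaptation_phase_window("late"),
                                  seed = NULL, ...) {
  switch_types <- switch_types %||%
    single_param_pairs(recording$schedule$conditions)$pair
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  dots <- list(...)
  bargs <- dots[names(dots) %in% names(formals(build_response_matrix))]
  dargs <- dots[names(dots) %in% names(formals(decode_orientation))]
  rows <- lapply(switch_types, function(st) {
    res <- tryCatch({
      rm_e <- do.call(build_response_matrix,
                      c(list(recording, st, early), bargs))
      rm_l <- do.call(build_response_matrix,
                      c(list(recording, st, late), bargs))
      de <- do.call(decode_orientation, c(list(rm_e), dargs))
      dl <- do.call(decode_orientation, c(list(rm_l), dargs))
      gt <- sum(de$accuracy_runs > dl$accuracy_runs)
      n_inf <- sum(de$accuracy_runs != dl$accuracy_runs)
      data.frame(switch = st,
                 acc_early = de$accuracy_mean, sd_early = de$accuracy_sd,
                 acc_late = dl$accuracy_mean, sd_late = dl$accuracy_sd,
                 p_sign = if (n_inf > 0)
                   stats::binom.test(gt, n_inf)$p.value else 1,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("switch %s skipped: %s", st, conditionMessage(e)))
      NULL
    })
    res
  })
  do.call(rbind, rows)
}
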