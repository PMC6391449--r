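#' Default pipeline configuration
#'
#' A nested list describing an end-to-end run: simulate a switching session,
#' estimate reverse-correlation kernels and selectivity, mutual information,
#' peri-switch rate and Fano dynamics, population decoding, tuning
#' modulation, and a simulated psychophysical observer.  Every stochastic
#' stage derives its seed from the top-level `seed`, so a run is
#' reproducible (and re-running into the same directory is byte-identical).
#'
#' @param out_dir output directory
#' @param seed master integer seed
#' @param duration_s session length in seconds (default 600)
#' @param n_neurons number of simulated neurons
#' @param stages character vector of stage names to run; any of
#'   `"stimgen"`, `"simulate"`, `"revcorr"`, `"mi"`, `"psth"`, `"fano"`,
#'   `"decode"`, `"tuning"`, `"psycho"`
#' @return list of class `pipeline_config`
#' @export
default_config <- function(out_dir, seed = 1, duration_s = 600,
                           n_neurons = 12,
                           stages = c("stimgen", "simulate", "revcorr",
                                      "mi", "psth", "fano", "decode",
                                      "tuning", "psycho")) {
  structure(list(
    out_dir = out_dir,
    seed = seed,
    stages = stages,
    stimgen = list(duration_s = duration_s, epoch_len_s = 5,
                   frame_len_s = 2 / 120),
    simulate = list(n_neurons = n_neurons, peak_rate = 30,
                    offset_rate = 2, dispersion = 1),
    revcorr = list(switch_types = NULL, phases = c("early", "late")),
    mi = list(switch_types = c("contrast_inc", "contrast_dec",
                               "luminance_inc", "luminance_dec"),
              n_windows = 6, n_bootstrap = 100,
              offset_s = 0.025, width_s = 0.05),
    psth = list(bin_s = 0.05, span_s = 5, n_shuffles = 50,
                fit_window = c(0.05, 5)),
    fano = list(win_s = 0.05, step_s = 0.01, span_s = 0.5),
    decode = list(classifier = "lda", n_runs = 15, n_neurons = NULL,
                  switch_types = NULL,
                  count_offset_s = 0.0425, count_width_s = 0.015),
    tuning = list(switch_types = NULL),
    psycho = list(mu = 0, sigma_early = 2, sigma_late = 3,
                  n_per_level = 20, n_boot = 1000)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges and stage names, aggregating every violation into
#' one readable error.
#'
#' @param config a `pipeline_config` (or plain list)
#' @return the config, invisibly; stops with the aggregated message on
#'   failure
#' @export
validate_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.character(config$out_dir %||% NULL) &&
         length(config$out_dir) == 1, "out_dir: single path required")
  need(is.numeric(config$seed %||% NULL) && length(config$seed) == 1 &&
         config$seed == round(config$seed), "seed: single integer required")
  known <- c("stimgen", "simulate", "revcorr", "mi", "psth", "fano",
             "decode", "tuning", "psycho")
  bad <- setdiff(config$stages %||% character(0), known)
  need(length(bad) == 0,
       sprintf("stages: unknown stage(s) %s", paste(bad, collapse = ", ")))
  sg <- config$stimgen %||% list()
  need(isTRUE(sg$duration_s > 0), "stimgen.duration_s: must be positive")
  need(isTRUE(sg$epoch_len_s > 0), "stimgen.epoch_len_s: must be positive")
  need(isTRUE(sg$frame_len_s > 0) && isTRUE(sg$frame_len_s < sg$epoch_len_s),
       "stimgen.frame_len_s: must be positive and below epoch_len_s")
  if (isTRUE(sg$duration_s > 0) && isTRUE(sg$epoch_len_s > 0))
    need(abs(sg$duration_s / sg$epoch_len_s -
               round(sg$duration_s / sg$epoch_len_s)) < 1e-9,
         "stimgen.duration_s: must be a multiple of epoch_len_s")
  need(isTRUE((config$simulate$n_neurons %||% 0) >= 1),
       "simulate.n_neurons: need at least one neuron")
  need(isTRUE((config$simulate$dispersion %||% 1) > 0),
       "simulate.dispersion: must be positive")
  need(isTRUE((config$mi$n_bootstrap %||% 100) >= 20),
       "mi.n_bootstrap: at least 20 shuffles")
  need(isTRUE((config$psycho$sigma_early %||% 1) > 0) &&
         isTRUE((config$psycho$sigma_late %||% 1) > 0),
       "psycho.sigma: must be positive")
  if (length(errs) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file
#' @param config a `pipeline_config`
#' @return `read_pipeline_config()` the config (validated);
#'   `write_pipeline_config()` the path, invisibly
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "pipeline_config"
  if (!is.null(cfg$psth$fit_window))
    cfg$psth$fit_window <- as.numeric(cfg$psth$fit_window)
  validate_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# Hash of the analysis configuration; the destination directory is not part
# of the analysis, so runs into different directories hash identically.
analysis_hash <- function(config) {
  cfg <- unclass(config)
  config_hash(cfg[setdiff(names(cfg), "out_dir")])
}

# CSV plus a JSON provenance sidecar (package version, seed, config hash).
write_stage_csv <- function(df, path, config, extra = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(package = "adaptcode",
                 version = as.character(utils::packageVersion("adaptcode")),
                 seed = config$seed,
                 config_hash = analysis_hash(config)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

pipeline_log <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[adaptcode] %-8s %6.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates a switching session and runs every enabled analysis stage,
#' writing each stage's CSV outputs (with JSON provenance sidecars) into
#' `config$out_dir` plus a `summary.json`.  Stages reuse the in-memory
#' objects of earlier stages; disabling a stage omits exactly its outputs.
#' Idempotent: the same config and seed produce byte-identical outputs.
#'
#' @param config a `pipeline_config` (validated on entry)
#' @param quiet suppress per-stage progress messages
#' @return list with the in-memory stage results, invisibly
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  validate_config(config)
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(st) st %in% config$stages
  res <- list()
  warn <- list()

  schedule <- generate_schedule(
    duration_s = config$stimgen$duration_s,
    epoch_len_s = config$stimgen$epoch_len_s,
    frame_len_s = config$stimgen$frame_len_s,
    seed = config$seed)
  events <- classify_switches(schedule)
  if (on("stimgen")) {
    write_schedule(schedule, file.path(config$out_dir, "schedule"))
    write_stage_csv(events, file.path(config$out_dir, "switches.csv"),
                    config)
    pipeline_log(quiet, "stimgen", t0)
  }
  res$schedule <- schedule

  params <- sample_neuron_params(config$simulate$n_neurons,
                                 seed = config$seed + 1,
                                 peak_rate = config$simulate$peak_rate,
                                 offset_rate = config$simulate$offset_rate,
                                 dispersion = config$simulate$dispersion)
  recording <- simulate_population(params, schedule,
                                   seed = config$seed + 2)
  if (on("simulate")) {
    write_spikes(recording, file.path(config$out_dir, "spikes.csv"))
    write_ground_truth(recording,
                       file.path(config$out_dir, "ground_truth.json"))
    pipeline_log(quiet, "simulate", t0)
  }
  res$recording <- recording
  ids <- names(recording$spikes)

  if (on("revcorr")) {
    rows <- list()
    kern_dir <- file.path(config$out_dir, "kernels")
    dir.create(kern_dir, showWarnings = FALSE)
    for (i in seq_along(ids)) {
      for (ph in config$revcorr$phases) {
        iv <- switch_windows(schedule, config$revcorr$switch_types,
                             adaptation_phase_window(ph,
                                                     schedule$epoch_len_s))
        kern <- reverse_correlate(recording$spikes[[i]], schedule, iv,
                                  window_label = ph)
        if (kern$empty) next
        fe <- extract_features(kern)
        verdict <- assess_selectivity(kern, features = fe)
        write_kernel(kern, file.path(kern_dir,
                                     sprintf("%s_%s.csv", ids[i], ph)))
        rows[[length(rows) + 1]] <- data.frame(
          neuron = ids[i], phase = ph,
          theta_pref_deg = fe$theta_pref_deg,
          peak_time_ms = fe$peak_time_ms,
          max_modulation = fe$max_modulation,
          temporal_width_ms = fe$temporal_width_ms,
          bandwidth_deg = verdict$bandwidth_deg,
          is_selective = verdict$is_selective,
          stringsAsFactors = FALSE)
      }
    }
    res$features <- do.call(rbind, rows)
    write_stage_csv(res$features,
                    file.path(config$out_dir, "features.csv"), config)
    pipeline_log(quiet, "revcorr", t0)
  }

  if (on("mi")) {
    rows <- list()
    for (i in seq_along(ids)) {
      for (st in config$mi$switch_types) {
        tc <- mi_timecourse(recording$spikes[[i]], schedule, st,
                            n_windows = config$mi$n_windows,
                            offset_s = config$mi$offset_s,
                            width_s = config$mi$width_s,
                            n_bootstrap = config$mi$n_bootstrap,
                            seed = config$seed + 3)
        tc$neuron <- ids[i]
        tc$switch_type <- st
        rows[[length(rows) + 1]] <- tc
      }
    }
    res$mi <- do.call(rbind, rows)
    write_stage_csv(res$mi, file.path(config$out_dir, "mi.csv"), config)
    pipeline_log(quiet, "mi", t0)
  }

  types4 <- c("contrast_inc", "contrast_dec",
              "luminance_inc", "luminance_dec")
  if (on("psth")) {
    psth_rows <- decay_rows <- list()
    for (st in types4) {
      ev_t <- events$time_s[events$switch_type == st]
      pooled <- sort(unlist(recording$spikes, use.names = FALSE))
      ps <- switch_psth(pooled, ev_t, bin_s = config$psth$bin_s,
                        span_s = config$psth$span_s,
                        session_len_s = schedule$duration_s)
      ps <- shuffle_normalize(ps, pooled,
                              n_shuffles = config$psth$n_shuffles,
                              seed = config$seed + 4)
      df <- ps$bins
      df$switch_type <- st
      psth_rows[[st]] <- df
      dec <- tryCatch(fit_decay(ps, config$psth$fit_window),
                      error = function(e) NULL)
      if (!is.null(dec) && isTRUE(dec$converged))
        decay_rows[[st]] <- data.frame(switch_type = st,
                                       tau_s = dec$tau_s,
                                       amplitude = dec$amplitude,
                                       asymptote = dec$asymptote,
                                       rss = dec$rss,
                                       flags = paste(dec$flags,
                                                     collapse = ";"))
    }
    res$psth <- do.call(rbind, psth_rows)
    write_stage_csv(res$psth, file.path(config$out_dir, "psth.csv"),
                    config)
    res$decay <- do.call(rbind, decay_rows)
    if (!is.null(res$decay))
      write_stage_csv(res$decay,
                      file.path(config$out_dir, "decay_fits.csv"), config)
    pipeline_log(quiet, "psth", t0)
  }

  if (on("fano")) {
    rows <- list()
    for (st in types4) {
      ev_t <- events$time_s[events$switch_type == st]
      pooled <- sort(unlist(recording$spikes, use.names = FALSE))
      fs <- suppressWarnings(
        fano_series(pooled, ev_t, win_s = config$fano$win_s,
                    step_s = config$fano$step_s,
                    span_s = config$fano$span_s,
                    session_len_s = schedule$duration_s))
      fs$switch_type <- st
      rows[[st]] <- fs
    }
    res$fano <- do.call(rbind, rows)
    write_stage_csv(res$fano, file.path(config$out_dir, "fano.csv"),
                    config)
    pipeline_log(quiet, "fano", t0)
  }

  if (on("decode")) {
    res$decode <- early_late_comparison(
      recording, switch_types = config$decode$switch_types,
      seed = config$seed + 5,
      classifier = config$decode$classifier,
      n_runs = config$decode$n_runs,
      n_neurons = config$decode$n_neurons %||%
        min(50L, length(ids)),
      count_offset_s = config$decode$count_offset_s,
      count_width_s = config$decode$count_width_s)
    write_stage_csv(res$decode, file.path(config$out_dir, "decode.csv"),
                    config)
    pipeline_log(quiet, "decode", t0)
  }

  if (on("tuning")) {
    rows <- list()
    for (i in seq_along(ids)) {
      for (st in types4) {
        row <- tryCatch({
          tp <- tuning_curves(recording$spikes[[i]], schedule, st)
          go <- gain_offset_regression(tp)
          cm <- compare_models(tp)
          data.frame(neuron = ids[i], switch_type = st,
                     slope = go$slope, intercept = go$intercept,
                     r_squared = go$r_squared,
                     best_model = cm$best_model,
                     classification = cm$classification,
                     aic_m1 = cm$aic[["m1"]], aic_m2 = cm$aic[["m2"]],
                     aic_m3 = cm$aic[["m3"]], aic_m4 = cm$aic[["m4"]],
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (!is.null(row)) rows[[length(rows) + 1]] <- row
      }
    }
    res$tuning <- do.call(rbind, rows)
    write_stage_csv(res$tuning,
                    file.path(config$out_dir, "tuning_mod.csv"), config)
    pipeline_log(quiet, "tuning", t0)
  }

  if (on("psycho")) {
    trials <- simulate_observer(mu = config$psycho$mu,
                                sigma_early = config$psycho$sigma_early,
                                sigma_late = config$psycho$sigma_late,
                                n_per_level = config$psycho$n_per_level,
                                seed = config$seed + 6)
    fe <- fit_psychometric(trials[trials$probe_phase == "early", ],
                           n_boot = config$psycho$n_boot,
                           seed = config$seed + 7)
    fl <- fit_psychometric(trials[trials$probe_phase == "late", ],
                           n_boot = config$psycho$n_boot,
                           seed = config$seed + 8)
    cmp <- tryCatch(compare_thresholds(fe, fl,
                                       n_boot = config$psycho$n_boot,
                                       seed = config$seed + 9),
                    error = function(e) NULL)
    res$psycho <- data.frame(
      probe_phase = c("early", "late"),
      mu = c(fe$mu, fl$mu), sigma = c(fe$sigma, fl$sigma),
      jnd = c(fe$jnd, fl$jnd),
      jnd_ci_lo = c(fe$jnd_ci[1], fl$jnd_ci[1]),
      jnd_ci_hi = c(fe$jnd_ci[2], fl$jnd_ci[2]))
    write_stage_csv(res$psycho, file.path(config$out_dir, "psycho.csv"),
                    config,
                    extra = list(delta_jnd = cmp$delta_jnd %||% NA,
                                 p_boot = cmp$p_boot %||% NA))
    write_stage_csv(trials, file.path(config$out_dir, "trials.csv"),
                    config)
    pipeline_log(quiet, "psycho", t0)
  }

  summary <- list(
    package = "adaptcode",
    version = as.character(utils::packageVersion("adaptcode")),
    seed = config$seed,
    config_hash = analysis_hash(config),
    stages_run = intersect(config$stages,
                           c("stimgen", "simulate", "revcorr", "mi",
                             "psth", "fano", "decode", "tuning",
                             "psycho")),
    n_epochs = nrow(schedule$epochs),
    n_neurons = length(ids))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
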