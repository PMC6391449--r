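#' Luminance-contrast condition set
#'
#' The default switching paradigm draws each 5-s epoch from the four
#' combinations of two mean luminances (70, 140 cd/m2) and two contrasts
#' (35, 65%).
#'
#' @param luminance mean luminances in cd/m2 (positive)
#' @param contrast Michelson contrasts in percent, in (0, 100]
#' @return data.frame with columns `label`, `luminance_cdm2`, `contrast_pct`,
#'   one row per luminance x contrast combination
#' @export
#' @examples
#' lc_conditions()
lc_conditions <- function(luminance = c(70, 140), contrast = c(35, 65)) {
  stopifnot(length(luminance) >= 1, length(contrast) >= 1,
            all(luminance > 0), all(contrast > 0), all(contrast <= 100))
  g <- expand.grid(luminance_cdm2 = sort(unique(luminance)),
                   contrast_pct = sort(unique(contrast)),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(label = sprintf("L%gC%g", g$luminance_cdm2, g$contrast_pct),
             g, stringsAsFactors = FALSE)
}

#' Generate a luminance-contrast switching stimulus schedule
#'
#' Builds the nested paradigm: grating frames of duration `frame_len_s`
#' (default two frames of a 120 Hz monitor, 2/120 s) with orientation, phase
#' and spatial frequency drawn independently and uniformly per frame, tiled
#' inside contiguous epochs of `epoch_len_s` whose luminance-contrast
#' condition is drawn independently and uniformly per epoch.  Time is 0-based
#' seconds and all windows downstream are half-open `[a, b)`.
#'
#' If `epoch_len_s` is not an integer multiple of `frame_len_s` the final
#' partial frame of each epoch is dropped, leaving a gap before the next
#' epoch.
#'
#' @param duration_s total session length in seconds; must be a positive
#'   multiple of `epoch_len_s`
#' @param epoch_len_s epoch length in seconds (default 5)
#' @param frame_len_s grating-frame duration in seconds (default 2/120)
#' @param conditions data.frame as returned by [lc_conditions()]
#' @param orientations orientation grid in degrees (default 12 values, 0-165)
#' @param phases phase grid in degrees (default 8 values, 0-315)
#' @param spatial_frequencies one to a few spatial frequencies in cycles/deg
#' @param seed integer seed; the schedule is reproducible from it
#' @return object of class `stimulus_schedule` with elements `frames`
#'   (onset_s, duration_s, orientation_deg, phase_deg, sf_cpd, epoch_index)
#'   and `epochs` (start_s, duration_s, luminance_cdm2, contrast_pct, label)
#' @export
#' @examples
#' sch <- generate_schedule(60, seed = 1)
#' nrow(sch$epochs)  # 12 epochs
generate_schedule <- function(duration_s,
                              epoch_len_s = 5,
                              frame_len_s = 2 / 120,
                              conditions = lc_conditions(),
                              orientations = seq(0, 165, by = 15),
                              phases = seq(0, 315, by = 45),
                              spatial_frequencies = 0.25,
                              seed = 1) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop("`duration_s` must be a positive scalar")
  if (epoch_len_s <= 0 || frame_len_s <= 0)
    stop("`epoch_len_s` and `frame_len_s` must be positive")
  n_epochs <- duration_s / epoch_len_s
  if (abs(n_epochs - round(n_epochs)) > 1e-9)
    stop("`duration_s` must be a positive multiple of `epoch_len_s`")
  n_epochs <- as.integer(round(n_epochs))
  stopifnot(nrow(conditions) >= 1, length(orientations) >= 1,
            length(phases) >= 1, length(spatial_frequencies) >= 1)

  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)

  cond_idx <- sample.int(nrow(conditions), n_epochs, replace = TRUE)
  epoch_start <- (seq_len(n_epochs) - 1) * epoch_len_s
  epochs <- data.frame(start_s = epoch_start,
                       duration_s = epoch_len_s,
                       luminance_cdm2 = conditions$luminance_cdm2[cond_idx],
                       contrast_pct = conditions$contrast_pct[cond_idx],
                       label = conditions$label[cond_idx],
                       stringsAsFactors = FALSE)

  frames_per_epoch <- floor(epoch_len_s / frame_len_s + 1e-9)
  n_frames <- n_epochs * frames_per_epoch
  onset <- rep(epoch_start, each = frames_per_epoch) +
    rep((seq_len(frames_per_epoch) - 1) * frame_len_s, times = n_epochs)
  frames <- data.frame(onset_s = onset,
                       duration_s = frame_len_s,
                       orientation_deg = draw_from(orientations, n_frames),
                       phase_deg = draw_from(phases, n_frames),
                       sf_cpd = draw_from(spatial_frequencies, n_frames),
                       epoch_index = rep(seq_len(n_epochs),
                                         each = frames_per_epoch))

  structure(list(frames = frames,
                 epochs = epochs,
                 conditions = conditions,
                 orientations = orientations,
                 phases = phases,
                 spatial_frequencies = spatial_frequencies,
                 duration_s = duration_s,
                 epoch_len_s = epoch_len_s,
                 frame_len_s = frame_len_s,
                 seed = seed),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(paste0("<stimulus_schedule> %g s: %d epochs x %g s, %d frames",
                     " (%g ms), %d conditions, seed %s\n"),
              x$duration_s, nrow(x$epochs), x$epoch_len_s, nrow(x$frames),
              1000 * x$frame_len_s, nrow(x$conditions),
              format(x$seed)))
  invisible(x)
}

#' Classify a luminance-contrast transition
#'
#' Pure function of the ordered condition pair.  With the default four
#' conditions there are 16 ordered pairs: 12 change at least one parameter
#' and 8 change exactly one.
#'
#' @param from_luminance,from_contrast,to_luminance,to_contrast vectors of
#'   condition parameters (recycled)
#' @return character vector in `{luminance_inc, luminance_dec, contrast_inc,
#'   contrast_dec, both_changed, no_change}`
#' @export
classify_switch_pair <- function(from_luminance, from_contrast,
                                 to_luminance, to_contrast) {
  dl <- to_luminance - from_luminance
  dc <- to_contrast - from_contrast
  out <- rep("no_change", length(dl))
  out[dl != 0 & dc != 0] <- "both_changed"
  out[dl > 0 & dc == 0] <- "luminance_inc"
  out[dl < 0 & dc == 0] <- "luminance_dec"
  out[dl == 0 & dc > 0] <- "contrast_inc"
  out[dl == 0 & dc < 0] <- "contrast_dec"
  out
}

#' Switch events of a schedule
#'
#' One event per epoch boundary.  A 60-min session of 5-s epochs has 720
#' epochs and therefore at most 719 internal boundaries plus the initial
#' onset; following the convention of counting one potential switch per
#' epoch boundary, at most `n_epochs` switches can occur in a session.
#'
#' @param schedule a `stimulus_schedule`
#' @return data.frame with one row per boundary: `time_s`, `epoch_from`,
#'   `epoch_to`, `from_label`, `to_label`, the four condition parameters, a
#'   `pair` label (`"from->to"`) and `switch_type`; zero rows for a
#'   single-epoch schedule
#' @export
classify_switches <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  ep <- schedule$epochs
  n <- nrow(ep)
  if (n < 2) {
    return(data.frame(time_s = numeric(0), epoch_from = integer(0),
                      epoch_to = integer(0), from_label = character(0),
                      to_label = character(0), from_luminance = numeric(0),
                      from_contrast = numeric(0), to_luminance = numeric(0),
                      to_contrast = numeric(0), pair = character(0),
                      switch_type = character(0), stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 1)
  data.frame(time_s = ep$start_s[i + 1],
             epoch_from = i,
             epoch_to = i + 1L,
             from_label = ep$label[i],
             to_label = ep$label[i + 1],
             from_luminance = ep$luminance_cdm2[i],
             from_contrast = ep$contrast_pct[i],
             to_luminance = ep$luminance_cdm2[i + 1],
             to_contrast = ep$contrast_pct[i + 1],
             pair = paste0(ep$label[i], "->", ep$label[i + 1]),
             switch_type = classify_switch_pair(ep$luminance_cdm2[i],
                                                ep$contrast_pct[i],
                                                ep$luminance_cdm2[i + 1],
                                                ep$contrast_pct[i + 1]),
             stringsAsFactors = FALSE)
}

#' The eight single-parameter ordered condition pairs
#'
#' @param conditions condition table, default [lc_conditions()]
#' @return data.frame (`pair`, `from_label`, `to_label`, `switch_type`) of all
#'   ordered pairs changing exactly one of luminance or contrast
#' @export
single_param_pairs <- function(conditions = lc_conditions()) {
  n <- nrow(conditions)
  g <- expand.grid(from = seq_len(n), to = seq_len(n))
  ty <- classify_switch_pair(conditions$luminance_cdm2[g$from],
                             conditions$contrast_pct[g$from],
                             conditions$luminance_cdm2[g$to],
                             conditions$contrast_pct[g$to])
  keep <- ty %in% c("luminance_inc", "luminance_dec",
                    "contrast_inc", "contrast_dec")
  data.frame(pair = paste0(conditions$label[g$from[keep]], "->",
                           conditions$label[g$to[keep]]),
             from_label = conditions$label[g$from[keep]],
             to_label = conditions$label[g$to[keep]],
             switch_type = ty[keep],
             stringsAsFactors = FALSE)
}

#' Standard early/late adaptation windows
#'
#' Early is the first 1.6 s of an epoch, late the last 1.6 s; both are
#' half-open `[a, b)` relative to the switch time.
#'
#' @param phase `"early"`, `"late"` or `"full"`
#' @param epoch_len_s epoch length (default 5 s)
#' @return numeric length-2 window in seconds relative to the switch
#' @export
adaptation_phase_window <- function(phase = c("early", "late", "full"),
                                    epoch_len_s = 5) {
  switch(match.arg(phase),
         early = c(0, 1.6),
         late = c(epoch_len_s - 1.6, epoch_len_s),
         full = c(0, epoch_len_s))
}

# Match switch events against a filter that may mix switch_type labels
# ("contrast_inc") and ordered-pair labels ("L70C35->L70C65").
match_switches <- function(events, switch_types) {
  if (is.null(switch_types)) return(rep(TRUE, nrow(events)))
  events$switch_type %in% switch_types | events$pair %in% switch_types
}

#' Absolute analysis intervals around selected switches
#'
#' Maps a window relative to the switch time onto every matching switch
#' event, yielding disjoint absolute intervals usable for spike or frame
#' selection.
#'
#' @param schedule a `stimulus_schedule`
#' @param switch_types `NULL` (all boundaries) or a character vector of
#'   switch types and/or ordered-pair labels to keep
#' @param window half-open window `c(a, b)` in seconds relative to the switch
#'   time, with `0 <= a <= b <= epoch_len_s`
#' @return data.frame (`start_s`, `end_s`, `switch_type`, `pair`,
#'   `epoch_to`), one row per matching switch
#' @export
switch_windows <- function(schedule, switch_types = NULL, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] < 0 || window[2] > schedule$epoch_len_s)
    stop("`window` must lie within the epoch, [0, epoch_len_s]")
  ev <- classify_switches(schedule)
  ev <- ev[match_switches(ev, switch_types), , drop = FALSE]
  data.frame(start_s = ev$time_s + window[1],
             end_s = ev$time_s + window[2],
             switch_type = ev$switch_type,
             pair = ev$pair,
             epoch_to = ev$epoch_to,
             stringsAsFactors = FALSE)
}

#' Frames whose onset falls inside a window after one switch
#'
#' @param schedule a `stimulus_schedule`
#' @param switch_event one row of [classify_switches()] output, or a scalar
#'   switch time in seconds
#' @param window half-open `c(a, b)` relative to the switch, within the epoch
#' @return the matching rows of `schedule$frames`
#' @export
#' @examples
#' sch <- generate_schedule(30, seed = 2)
#' ev <- classify_switches(sch)
#' nrow(frames_in_window(sch, ev[1, ], c(0, 1.6)))  # 96 frames
frames_in_window <- function(schedule, switch_event, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] < 0 || window[2] > schedule$epoch_len_s)
    stop("`window` must lie within the epoch, [0, epoch_len_s]")
  t0 <- if (is.numeric(switch_event)) switch_event[1] else switch_event$time_s
  fr <- schedule$frames
  fr[fr$onset_s >= t0 + window[1] & fr$onset_s < t0 + window[2], ,
     drop = FALSE]
}

# Rows of `frames` whose onset lies in any of the (sorted, disjoint)
# half-open intervals; also reports which interval each row fell into.
frames_in_intervals <- function(frames, intervals) {
  o <- order(intervals$start_s)
  intervals <- intervals[o, , drop = FALSE]
  k <- findInterval(frames$onset_s, intervals$start_s)
  ok <- k >= 1 & frames$onset_s < intervals$end_s[pmax(k, 1)]
  out <- frames[ok, , drop = FALSE]
  out$interval_index <- o[k[ok]]
  out
}

#' Write / read a schedule as plain-text tables
#'
#' `frames.csv` and `epochs.csv` plus a `schedule.json` sidecar carrying the
#' grids, seed and timing constants; `read_schedule()` restores an identical
#' `stimulus_schedule`.
#'
#' @param schedule a `stimulus_schedule`
#' @param dir output directory (created if missing)
#' @return `write_schedule()` the directory, invisibly; `read_schedule()` the
#'   restored schedule
#' @export
write_schedule <- function(schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(schedule$frames, file.path(dir, "frames.csv"),
                   row.names = FALSE)
  utils::write.csv(schedule$epochs, file.path(dir, "epochs.csv"),
                   row.names = FALSE)
  meta <- schedule[c("conditions", "orientations", "phases",
                     "spatial_frequencies", "duration_s", "epoch_len_s",
                     "frame_len_s", "seed")]
  jsonlite::write_json(meta, file.path(dir, "schedule.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "schedule.json"),
                              simplifyVector = TRUE)
  frames <- utils::read.csv(file.path(dir, "frames.csv"))
  epochs <- utils::read.csv(file.path(dir, "epochs.csv"))
  structure(list(frames = frames, epochs = epochs,
                 conditions = as.data.frame(meta$conditions),
                 orientations = meta$orientations,
                 phases = meta$phases,
                 spatial_frequencies = meta$spatial_frequencies,
                 duration_s = meta$duration_s,
                 epoch_len_s = meta$epoch_len_s,
                 frame_len_s = meta$frame_len_s,
                 seed = meta$seed),
            class = "stimulus_schedule")
}
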