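#' Default segmentation and cleaning parameters
#'
#' All thresholds used by the event-detection and cleaning stages, bundled in
#' one list so they can be serialized, logged and overridden together.
#'
#' @param saccade_threshold_deg_s peak-velocity threshold above which a run of
#'   samples is a saccade candidate (deg/s).
#' @param min_fixation_ms fixations shorter than this are rejected (ms).
#' @param sp_dispersion_px fixation-like holds with a dispersion larger than
#'   this are reclassified as smooth pursuits (px).
#' @param min_saccade_samples minimum number of supra-threshold velocity
#'   intervals for a saccade candidate; shorter runs are treated as flicker.
#' @param merge_gap_samples supra-threshold runs separated by at most this many
#'   sub-threshold samples are merged into one saccade.
#' @param gap_min_samples runs of at least this many consecutive invalid
#'   samples become blink/tracking-loss gaps (25 samples = 100 ms at 250 Hz).
#' @param tracking_ratio_min trials with a lower fraction of valid samples are
#'   discarded.
#' @param max_velocity_deg_s physiological bound on saccade peak velocity.
#' @param max_accel_deg_s2 physiological bound on the magnitude of peak
#'   saccade acceleration and deceleration.
#' @param frame width and height of the equirectangular frame in px.
#' @param rate_hz sampling rate of the eye tracker.
#'
#' @return a named list of class `gaze_params`.
#' @export
gaze_params <- function(saccade_threshold_deg_s = 40,
                        min_fixation_ms = 50,
                        sp_dispersion_px = 100,
                        min_saccade_samples = 3,
                        merge_gap_samples = 1,
                        gap_min_samples = 25,
                        tracking_ratio_min = 0.75,
                        max_velocity_deg_s = 1000,
                        max_accel_deg_s2 = 1e5,
                        frame = c(3840, 1920),
                        rate_hz = 250) {
  stopifnot(saccade_threshold_deg_s > 0, min_fixation_ms > 0,
            sp_dispersion_px > 0, rate_hz > 0, all(frame > 0))
  structure(list(
    saccade_threshold_deg_s = saccade_threshold_deg_s,
    min_fixation_ms = min_fixation_ms,
    sp_dispersion_px = sp_dispersion_px,
    min_saccade_samples = min_saccade_samples,
    merge_gap_samples = merge_gap_samples,
    gap_min_samples = gap_min_samples,
    tracking_ratio_min = tracking_ratio_min,
    max_velocity_deg_s = max_velocity_deg_s,
    max_accel_deg_s2 = max_accel_deg_s2,
    frame = frame,
    rate_hz = rate_hz
  ), class = "gaze_params")
}

#' Convert pixel displacements to degrees on the equirectangular frame
#'
#' The full frame width maps to a 360 degree horizontal turn and — following
#' the arithmetic convention of the source recordings — the full frame height
#' also maps to 360 degrees. On the default 3840x1920 frame this gives
#' 0.09375 deg/px horizontally and 0.1875 deg/px vertically, so a 2400 px
#' horizontal displacement corresponds to 225 degrees and a 1000 px vertical
#' displacement to 187.5 degrees. The mapping is linear and exactly invertible
#' (see [deg_to_px()]).
#'
#' @param dx,dy displacements in px (vectorized).
#' @param frame `c(width, height)` in px.
#' @return a list with numeric components `x` and `y` in degrees.
#' @export
#' @examples
#' px_to_deg(2400, 0)            # x = 225
#' px_to_deg(0, 1000)$y          # 187.5
px_to_deg <- function(dx, dy, frame = c(3840, 1920)) {
  stopifnot(length(frame) == 2, all(frame > 0))
  list(x = dx * 360 / frame[1], y = dy * 360 / frame[2])
}

#' Inverse of [px_to_deg()]
#' @param deg_x,deg_y displacements in degrees.
#' @inheritParams px_to_deg
#' @return a list with components `x` and `y` in px.
#' @export
deg_to_px <- function(deg_x, deg_y, frame = c(3840, 1920)) {
  stopifnot(length(frame) == 2, all(frame > 0))
  list(x = deg_x * frame[1] / 360, y = deg_y * frame[2] / 360)
}

#' Angular distance between consecutive gaze samples
#'
#' Sample-to-sample angular displacement with horizontal wrap-around at the
#' equirectangular seam: the x displacement is `min(|dx|, width - |dx|)`,
#' because the 360-degree footage is continuous there.
#'
#' @param x,y sample coordinates in px.
#' @param frame `c(width, height)` in px.
#' @return numeric vector of length `length(x) - 1`, degrees.
#' @keywords internal
angular_step_deg <- function(x, y, frame = c(3840, 1920)) {
  dx <- abs(diff(x))
  dx <- pmin(dx, frame[1] - dx)
  dy <- diff(y)
  d <- px_to_deg(dx, dy, frame)
  sqrt(d$x^2 + d$y^2)
}

#' Per-sample angular speed of a gaze trial
#'
#' Two-point forward difference at the native sampling step: the speed of
#' interval `i` is the angular distance between samples `i` and `i + 1`
#' divided by the inter-sample interval (4 ms at 250 Hz). Speeds are computed
#' from the recorded coordinates as-is — including the `(0;0)` device-error
#' encoding, which produces the physiologically impossible jumps the cleaning
#' stage screens for — and intervals touching an invalid sample are
#' additionally flagged in `valid_pair`.
#'
#' @param trial a `gaze_trial` (see [gaze_trial()]).
#' @param frame optional frame override; defaults to the trial's frame.
#' @return a data.frame with one row per inter-sample interval:
#'   `speed_deg_s` and `valid_pair`.
#' @export
sample_velocity <- function(trial, frame = NULL) {
  stopifnot(inherits(trial, "gaze_trial"))
  if (length(trial$x) < 2) stop("trial must contain at least 2 samples")
  if (is.null(frame)) frame <- trial$frame
  dt_s <- 1 / trial$rate_hz
  step <- angular_step_deg(trial$x, trial$y, frame)
  data.frame(
    speed_deg_s = step / dt_s,
    valid_pair = trial$valid[-length(trial$valid)] & trial$valid[-1]
  )
}

#' Detect saccade candidate intervals from a speed series
#'
#' Maximal runs of intervals with speed above the peak threshold become
#' candidates. Runs separated by at most `merge_gap` sub-threshold samples are
#' merged (robustness to single-sample flicker), and merged runs spanning
#' fewer than `min_samples` intervals are discarded.
#'
#' @param speed numeric vector of per-interval speeds (deg/s).
#' @param threshold peak-velocity threshold (deg/s).
#' @param min_samples minimum run length in intervals.
#' @param merge_gap maximum sub-threshold separation merged over.
#' @return integer matrix with columns `start`, `end`: indices into the
#'   *sample* vector such that intervals `start..(end-1)` are saccadic; zero
#'   rows when nothing is found. Candidates never overlap.
#' @export
detect_saccades <- function(speed, threshold = 40, min_samples = 3,
                            merge_gap = 1) {
  supra <- !is.na(speed) & speed > threshold
  runs <- rle_runs(supra)
  if (nrow(runs) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  # merge runs separated by short sub-threshold stretches
  if (merge_gap > 0 && nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in seq_len(nrow(runs))[-1]) {
      last <- keep[[length(keep)]]
      if (runs[i, "start"] - last["end"] - 1 <= merge_gap) {
        last["end"] <- runs[i, "end"]
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }
  len <- runs[, "end"] - runs[, "start"] + 1
  runs <- runs[len >= min_samples, , drop = FALSE]
  # interval i sits between samples i and i+1: a run start..end of intervals
  # spans samples start..end+1
  cbind(start = runs[, "start"], end = runs[, "end"] + 1L)
}

# maximal runs of TRUE in a logical vector -> matrix(start, end)
rle_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- cbind(start = starts[r$values], end = ends[r$values])
  m[!is.na(m[, 1]), , drop = FALSE]
}

#' Detect blink / tracking-loss gaps
#'
#' Runs of at least `min_run` consecutive invalid samples become gaps; shorter
#' invalid runs stay embedded in the surrounding events (the cleaning stage
#' deals with those).
#'
#' @param trial a `gaze_trial`.
#' @param min_run minimum run length in samples (default 25, i.e. 100 ms at
#'   250 Hz).
#' @return integer matrix with columns `start`, `end` (sample indices).
#' @export
detect_gaps <- function(trial, min_run = 25) {
  stopifnot(inherits(trial, "gaze_trial"))
  runs <- rle_runs(!trial$valid)
  len <- runs[, "end"] - runs[, "start"] + 1
  runs[len >= min_run, , drop = FALSE]
}

#' Bounding-box dispersion of a set of gaze samples
#'
#' `(max x - min x) + (max y - min y)` over the valid samples — the I-DT
#' convention. Adding an interior point never changes the value.
#'
#' @param x,y coordinates in px.
#' @param valid logical validity flags (defaults to all valid).
#' @return dispersion in px.
#' @export
dispersion <- function(x, y, valid = rep(TRUE, length(x))) {
  x <- x[valid]; y <- y[valid]
  if (length(x) == 0) stop("dispersion needs at least one valid sample")
  (max(x) - min(x)) + (max(y) - min(y))
}

#' Assemble raw fixation intervals between saccades and gaps
#'
#' The complement intervals between saccade candidates and gaps become
#' fixation candidates; candidates shorter than the minimum fixation duration
#' are rejected outright.
#'
#' @param n_samples number of samples in the trial.
#' @param saccades,gaps integer matrices with `start`/`end` sample columns.
#' @param rate_hz sampling rate.
#' @param min_fixation_ms minimum fixation duration (ms).
#' @return integer matrix with columns `start`, `end` (sample indices).
#' @export
assemble_fixations <- function(n_samples, saccades, gaps, rate_hz = 250,
                               min_fixation_ms = 50) {
  occupied <- rep(FALSE, n_samples)
  mark <- function(m) {
    for (i in seq_len(nrow(m))) occupied[m[i, "start"]:m[i, "end"]] <<- TRUE
  }
  if (!is.null(saccades) && nrow(saccades)) mark(saccades)
  if (!is.null(gaps) && nrow(gaps)) mark(gaps)
  free <- rle_runs(!occupied)
  if (nrow(free) == 0) return(free)
  dur_ms <- (free[, "end"] - free[, "start"]) * 1000 / rate_hz
  free[dur_ms >= min_fixation_ms, , drop = FALSE]
}

#' Split fixation-like holds into fixations and smooth pursuits
#'
#' Holds with a dispersion above the threshold are smooth pursuits; the
#' partition is exhaustive and exclusive.
#'
#' @param events data.frame of hold events carrying a `dispersion_px` column.
#' @param threshold_px dispersion split threshold (default 100 px).
#' @return the same data.frame with `type` set to `"fixation"` or
#'   `"smooth_pursuit"`.
#' @export
split_smooth_pursuits <- function(events, threshold_px = 100) {
  if (nrow(events) == 0) {
    events$type <- character(0)
    return(events)
  }
  events$type <- ifelse(events$dispersion_px > threshold_px,
                        "smooth_pursuit", "fixation")
  events
}

#' Segment a gaze trial into saccades, fixations, smooth pursuits and gaps
#'
#' Composition of the detection primitives: per-interval angular speeds,
#' supra-threshold saccade runs, blink gaps, complement fixations with the
#' 50 ms minimum, and the 100 px dispersion split. Saccade kinematics (mean
#' and peak velocity, peak acceleration/deceleration, Eq.-style path-length
#' amplitude) are computed from the speed series; hold dispersions use valid
#' samples only. Invalid samples inside a saccade are retained in the record —
#' interpolation is deliberately not attempted — and are handled by
#' [validate_saccade()].
#'
#' @param trial a `gaze_trial`.
#' @param params a [gaze_params()] list.
#' @return a data.frame of class `event_stream`, one row per event, columns:
#'   `trial_id`, `participant_id`, `class_label`, `type`, `start_idx`,
#'   `end_idx`, `start_ms`, `end_ms`, `duration_ms`, `n_samples`,
#'   `centroid_x`, `centroid_y`, `dispersion_px`, `amplitude_deg`,
#'   `mean_vel`, `peak_vel`, `mean_acc`, `peak_acc`, `peak_dec`,
#'   `first_valid`, `all_valid`.
#' @export
segment_trial <- function(trial, params = gaze_params()) {
  stopifnot(inherits(trial, "gaze_trial"))
  n <- length(trial$x)
  dt_ms <- 1000 / trial$rate_hz
  vel <- sample_velocity(trial, params$frame)
  sacc <- detect_saccades(vel$speed_deg_s, params$saccade_threshold_deg_s,
                          params$min_saccade_samples, params$merge_gap_samples)
  gaps <- detect_gaps(trial, params$gap_min_samples)
  # drop saccade candidates swallowed by gaps
  if (nrow(sacc) && nrow(gaps)) {
    inside_gap <- vapply(seq_len(nrow(sacc)), function(i) {
      any(sacc[i, "start"] >= gaps[, "start"] & sacc[i, "end"] <= gaps[, "end"])
    }, logical(1))
    sacc <- sacc[!inside_gap, , drop = FALSE]
  }
  holds <- assemble_fixations(n, sacc, gaps, trial$rate_hz,
                              params$min_fixation_ms)

  mk_row <- function(type, s, e) {
    idx <- s:e
    v <- trial$valid[idx]
    row <- data.frame(
      trial_id = trial$trial_id, participant_id = trial$participant_id,
      class_label = trial$class_label, type = type,
      start_idx = s, end_idx = e,
      start_ms = trial$t_ms[s], end_ms = trial$t_ms[e],
      duration_ms = trial$t_ms[e] - trial$t_ms[s],
      n_samples = length(idx),
      centroid_x = NA_real_, centroid_y = NA_real_,
      dispersion_px = NA_real_, amplitude_deg = NA_real_,
      mean_vel = NA_real_, peak_vel = NA_real_,
      mean_acc = NA_real_, peak_acc = NA_real_, peak_dec = NA_real_,
      first_valid = v[1], all_valid = all(v),
      stringsAsFactors = FALSE
    )
    if (type == "hold") {
      if (any(v)) {
        row$centroid_x <- mean(trial$x[idx][v])
        row$centroid_y <- mean(trial$y[idx][v])
        row$dispersion_px <- dispersion(trial$x[idx], trial$y[idx], v)
      }
    } else if (type == "saccade") {
      sp <- vel$speed_deg_s[s:(e - 1)]
      row$mean_vel <- mean(sp)
      row$peak_vel <- max(sp)
      row$amplitude_deg <- mean(sp) * row$duration_ms / 1000
      if (length(sp) >= 2) {
        acc <- diff(sp) / (dt_ms / 1000)
        row$mean_acc <- if (any(acc > 0)) mean(acc[acc > 0]) else 0
        row$peak_acc <- max(acc)
        row$peak_dec <- min(acc)
      }
    }
    row
  }

  rows <- list()
  for (i in seq_len(nrow(sacc))) {
    rows[[length(rows) + 1]] <- mk_row("saccade", sacc[i, "start"], sacc[i, "end"])
  }
  for (i in seq_len(nrow(holds))) {
    rows[[length(rows) + 1]] <- mk_row("hold", holds[i, "start"], holds[i, "end"])
  }
  for (i in seq_len(nrow(gaps))) {
    rows[[length(rows) + 1]] <- mk_row("gap", gaps[i, "start"], gaps[i, "end"])
  }
  if (length(rows) == 0) {
    ev <- mk_row("hold", 1, 1)[0, ]
  } else {
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$start_idx), ]
  }
  is_hold <- ev$type == "hold"
  # holds with no valid sample at all cannot be typed; drop them
  drop <- is_hold & is.na(ev$dispersion_px)
  ev <- ev[!drop, ]
  is_hold <- ev$type == "hold"
  if (any(is_hold)) {
    split <- split_smooth_pursuits(ev[is_hold, ], params$sp_dispersion_px)
    ev$type[is_hold] <- split$type
  }
  rownames(ev) <- NULL
  class(ev) <- c("event_stream", class(ev))
  attr(ev, "trial_duration_s") <- n / trial$rate_hz
  ev
}

#' Segment every trial of a dataset
#'
#' @param dataset a `gaze_dataset` (list of `gaze_trial`s).
#' @param params a [gaze_params()] list.
#' @return a single `event_stream` data.frame covering all trials, with a
#'   `trial_durations` attribute (named vector of seconds per trial).
#' @export
segment_dataset <- function(dataset, params = gaze_params()) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  parts <- lapply(dataset, segment_trial, params = params)
  durs <- vapply(parts, function(p) attr(p, "trial_duration_s"), numeric(1))
  names(durs) <- vapply(dataset, function(tr) tr$trial_id, character(1))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("event_stream", "data.frame")
  attr(out, "trial_durations") <- durs
  out
}
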