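#' Tracking ratio of a trial
#'
#' Fraction of samples the device tracked validly (vendor-standard meaning).
#'
#' @param trial a `gaze_trial`.
#' @return fraction in `[0, 1]`.
#' @export
tracking_ratio <- function(trial) {
  stopifnot(inherits(trial, "gaze_trial"))
  if (length(trial$valid) == 0) stop("empty trial")
  mean(trial$valid)
}

#' Remove trials with a low tracking ratio
#'
#' Trials with less than `threshold` valid samples are discarded; the ledger
#' reports the invalid-trial count per participant and the total fraction
#' lost.
#'
#' @param dataset a `gaze_dataset`.
#' @param threshold minimum tracking ratio (default 0.75).
#' @return a list with `dataset` (the kept trials), `ledger` (per-participant
#'   data.frame with `n_trials`, `n_invalid`), `n_kept`, `n_total` and
#'   `fraction_lost`.
#' @export
filter_trials <- function(dataset, threshold = 0.75) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  ratios <- vapply(dataset, tracking_ratio, numeric(1))
  keep <- ratios >= threshold
  idx <- dataset_index(dataset)
  ledger <- do.call(rbind, lapply(split(seq_along(keep), idx$participant_id),
    function(rows) {
      data.frame(participant_id = idx$participant_id[rows[1]],
                 n_trials = length(rows),
                 n_invalid = sum(!keep[rows]),
                 stringsAsFactors = FALSE)
    }))
  rownames(ledger) <- NULL
  list(
    dataset = dataset[keep],
    ledger = ledger,
    n_kept = sum(keep),
    n_total = length(keep),
    fraction_lost = mean(!keep)
  )
}

#' Path-length saccade amplitude
#'
#' Amplitude as the total angular distance traveled along the (potentially
#' curved) trajectory: the mean sample-to-sample angular speed multiplied by
#' the event duration, which telescopes to the summed step lengths. This is
#' the second of the two textbook amplitude definitions (path length, not the
#' start-to-end chord).
#'
#' @param x,y saccade sample coordinates in px.
#' @param rate_hz sampling rate.
#' @param frame `c(width, height)` in px.
#' @return amplitude in degrees.
#' @export
saccade_amplitude <- function(x, y, rate_hz = 250, frame = c(3840, 1920)) {
  if (length(x) < 2) stop("saccade amplitude needs at least 2 samples")
  step <- angular_step_deg(x, y, frame)
  duration_s <- (length(x) - 1) / rate_hz
  mean(step / (1 / rate_hz)) * duration_s
}

#' Validate a saccade record against the physiological quality rules
#'
#' Reasons (any subset may co-occur):
#' * `invalid_start` — the first sample is `(0;0)`/device-invalid;
#' * `invalid_intra` — any interior sample is invalid;
#' * `velocity_bound` — peak velocity exceeds 1000 deg/s;
#' * `accel_bound` — the magnitude of peak acceleration or peak deceleration
#'   exceeds 100,000 deg/s^2.
#'
#' An empty reason set means the saccade is kept.
#'
#' @param record one saccade row of an `event_stream` (needs `first_valid`,
#'   `all_valid`, `peak_vel`, `peak_acc`, `peak_dec`).
#' @param max_velocity,max_accel physiological bounds.
#' @return character vector of reasons (possibly empty).
#' @export
validate_saccade <- function(record, max_velocity = 1000, max_accel = 1e5) {
  reasons <- character(0)
  if (!isTRUE(record$first_valid)) reasons <- c(reasons, "invalid_start")
  if (!isTRUE(record$all_valid)) reasons <- c(reasons, "invalid_intra")
  if (isTRUE(record$peak_vel > max_velocity)) {
    reasons <- c(reasons, "velocity_bound")
  }
  if (isTRUE(abs(record$peak_acc) > max_accel) ||
      isTRUE(abs(record$peak_dec) > max_accel)) {
    reasons <- c(reasons, "accel_bound")
  }
  reasons
}

#' Apply saccade-level quality control to an event stream
#'
#' Removes every saccade that violates any of the quality rules (fixations
#' and smooth pursuits are untouched) and reports counts per reason. A
#' saccade violating several rules counts once in the total — most invalid
#' saccades have more than one error source.
#'
#' @param events an `event_stream` data.frame from [segment_dataset()].
#' @param max_velocity,max_accel physiological bounds.
#' @return list with `events` (cleaned stream, reason columns attached) and
#'   `report` (a `cleaning_report`): counts and fractions per reason, total
#'   saccades removed, and the fraction of samples removed.
#' @export
clean_dataset <- function(events, max_velocity = 1000, max_accel = 1e5) {
  is_sacc <- events$type == "saccade"
  reasons <- c("invalid_start", "invalid_intra", "velocity_bound", "accel_bound")
  flag <- matrix(FALSE, nrow(events), length(reasons),
                 dimnames = list(NULL, reasons))
  if (any(is_sacc)) {
    sacc <- events[is_sacc, ]
    flag[is_sacc, "invalid_start"] <- !sacc$first_valid
    flag[is_sacc, "invalid_intra"] <- !sacc$all_valid
    flag[is_sacc, "velocity_bound"] <- !is.na(sacc$peak_vel) &
      sacc$peak_vel > max_velocity
    flag[is_sacc, "accel_bound"] <-
      (!is.na(sacc$peak_acc) & abs(sacc$peak_acc) > max_accel) |
      (!is.na(sacc$peak_dec) & abs(sacc$peak_dec) > max_accel)
  }
  removed <- rowSums(flag) > 0
  n_sacc <- sum(is_sacc)
  n_samples <- sum(events$n_samples[events$type != "gap"])
  report <- structure(list(
    n_saccades = n_sacc,
    n_removed = sum(removed),
    per_reason = colSums(flag),
    fraction_saccades_removed = if (n_sacc) sum(removed) / n_sacc else 0,
    fraction_samples_removed = if (n_samples)
      sum(events$n_samples[removed]) / n_samples else 0
  ), class = "cleaning_report")
  out <- events[!removed, ]
  rownames(out) <- NULL
  class(out) <- c("event_stream", "data.frame")
  attr(out, "trial_durations") <- attr(events, "trial_durations")
  list(events = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d/%d saccades removed (%.1f%%; %.1f%% of samples)\n",
              x$n_removed, x$n_saccades, 100 * x$fraction_saccades_removed,
              100 * x$fraction_samples_removed))
  for (r in names(x$per_reason)) {
    cat(sprintf("  %-15s %d\n", r, x$per_reason[[r]]))
  }
  invisible(x)
}
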