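# canonical 46-feature layout: 2 event frequencies plus avg/sd/min/max of
# eleven kinematic measures
feature_measures <- list(
  fix_dur = c("fixation", "duration_ms"),
  fix_disp = c("fixation", "dispersion_px"),
  sacc_dur = c("saccade", "duration_ms"),
  sacc_amp = c("saccade", "amplitude_deg"),
  sacc_acc_mean = c("saccade", "mean_acc"),
  sacc_acc_peak = c("saccade", "peak_acc"),
  sacc_dec_peak = c("saccade", "peak_dec"),
  sacc_vel_mean = c("saccade", "mean_vel"),
  sacc_vel_peak = c("saccade", "peak_vel"),
  sp_dur = c("smooth_pursuit", "duration_ms"),
  sp_disp = c("smooth_pursuit", "dispersion_px")
)

#' Canonical feature names
#'
#' The stable, ordered names of the 46 trial-level features: `fix_freq`,
#' `sacc_freq`, and `<measure>_<avg|sd|min|max>` for the eleven kinematic
#' measures.
#'
#' @return character vector of length 46.
#' @export
feature_names <- function() {
  c("fix_freq", "sacc_freq",
    as.vector(t(outer(names(feature_measures),
                      c("avg", "sd", "min", "max"), paste, sep = "_"))))
}

#' Aggregate one trial's events into the 46-feature vector
#'
#' Frequencies are event counts divided by the trial duration in seconds
#' (the literal definition). For each measure the average, standard deviation
#' (n-1 denominator), minimum and maximum over the trial's events of the
#' corresponding type are computed. Trials lacking an event type yield `NA`
#' for that type's features; the downstream policy (drop or keep) is applied
#' by [feature_matrix()].
#'
#' @param events `event_stream` rows of a single trial (cleaned).
#' @param trial_duration_s duration of the trial in seconds.
#' @return named numeric vector of length 46.
#' @export
trial_features <- function(events, trial_duration_s) {
  stopifnot(trial_duration_s > 0)
  out <- rep(NA_real_, 46)
  names(out) <- feature_names()
  out["fix_freq"] <- sum(events$type == "fixation") / trial_duration_s
  out["sacc_freq"] <- sum(events$type == "saccade") / trial_duration_s
  for (m in names(feature_measures)) {
    type <- feature_measures[[m]][1]
    col <- feature_measures[[m]][2]
    v <- events[events$type == type, col]
    v <- v[!is.na(v)]
    if (length(v)) {
      out[paste0(m, "_avg")] <- mean(v)
      out[paste0(m, "_sd")] <- if (length(v) > 1) sd(v) else 0
      out[paste0(m, "_min")] <- min(v)
      out[paste0(m, "_max")] <- max(v)
    }
  }
  out
}

#' Build the trial x feature matrix for a dataset
#'
#' One row per trial with participant id and class label retained for the
#' participant-wise split logic. Row order is deterministic (sorted by
#' trial id). Trials missing an event type (no saccade, no fixation, or no
#' smooth pursuit after cleaning) are dropped by default and counted in the
#' `dropped` attribute; with `na_policy = "keep"` they are retained with NA
#' features.
#'
#' @param events a cleaned `event_stream` covering the dataset (must carry
#'   the `trial_durations` attribute from [segment_dataset()], or supply
#'   `trial_durations`).
#' @param trial_durations named vector of per-trial durations in seconds.
#' @param na_policy `"drop"` (default) or `"keep"`.
#' @return data.frame with `trial_id`, `participant_id`, `class_label` and
#'   the 46 feature columns; attribute `dropped` lists removed trial ids.
#' @export
feature_matrix <- function(events, trial_durations = NULL,
                           na_policy = c("drop", "keep")) {
  na_policy <- match.arg(na_policy)
  if (is.null(trial_durations)) {
    trial_durations <- attr(events, "trial_durations")
  }
  if (is.null(trial_durations)) {
    stop("trial durations are required (segment_dataset() attaches them)")
  }
  if (nrow(events) == 0) stop("empty event stream")
  by_trial <- split(seq_len(nrow(events)), events$trial_id)
  by_trial <- by_trial[order(names(by_trial))]
  rows <- lapply(names(by_trial), function(tid) {
    ev <- events[by_trial[[tid]], ]
    fv <- trial_features(ev, trial_durations[[tid]])
    cbind(data.frame(trial_id = tid,
                     participant_id = ev$participant_id[1],
                     class_label = ev$class_label[1],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  dropped <- character(0)
  if (na_policy == "drop") {
    bad <- !stats::complete.cases(out[, feature_names()])
    dropped <- out$trial_id[bad]
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Per-class feature summary
#'
#' Mean and standard deviation of every feature by class — the layout used
#' for population-level reporting of the 46 features.
#'
#' @param features a [feature_matrix()] data.frame.
#' @return data.frame with `feature`, one `<class>_mean` and `<class>_sd`
#'   column pair per class.
#' @export
class_feature_summary <- function(features) {
  cls <- sort(unique(features$class_label))
  fn <- feature_names()
  out <- data.frame(feature = fn, stringsAsFactors = FALSE)
  for (cl in cls) {
    sub <- features[features$class_label == cl, fn, drop = FALSE]
    out[[paste0(cl, "_mean")]] <- vapply(sub, mean, numeric(1), na.rm = TRUE)
    out[[paste0(cl, "_sd")]] <- vapply(sub, sd, numeric(1))
  }
  out
}
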