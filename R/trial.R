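#' Construct a gaze trial
#'
#' One participant x stimulus recording: a time-ordered 250 Hz trace of gaze
#' positions on the equirectangular frame, with validity flags. The device
#' encodes tracking errors as position `(0;0)`; such samples are forced
#' invalid on construction.
#'
#' @param t_ms sample timestamps in ms, strictly increasing.
#' @param x,y gaze position in px.
#' @param valid logical validity flags.
#' @param trial_id,participant_id,class_label,block trial metadata.
#' @param rate_hz sampling rate in Hz.
#' @param frame `c(width, height)` of the frame in px.
#' @return an object of class `gaze_trial`.
#' @export
gaze_trial <- function(t_ms, x, y, valid = rep(TRUE, length(x)),
                       trial_id = "trial", participant_id = "p",
                       class_label = NA_character_, block = 1L,
                       rate_hz = 250, frame = c(3840, 1920)) {
  n <- length(x)
  stopifnot(n > 0, length(y) == n, length(t_ms) == n, length(valid) == n,
            rate_hz > 0, all(frame > 0))
  if (is.unsorted(t_ms, strictly = TRUE)) {
    stop("trial timestamps must be strictly increasing")
  }
  valid <- valid & !(x == 0 & y == 0)
  structure(list(
    trial_id = as.character(trial_id),
    participant_id = as.character(participant_id),
    class_label = as.character(class_label),
    block = as.integer(block),
    t_ms = as.numeric(t_ms), x = as.numeric(x), y = as.numeric(y),
    valid = as.logical(valid),
    rate_hz = rate_hz, frame = frame
  ), class = "gaze_trial")
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf("<gaze_trial %s> participant %s (%s), %d samples @ %g Hz, %.1f s, tracking ratio %.3f\n",
              x$trial_id, x$participant_id, x$class_label, length(x$x),
              x$rate_hz, length(x$x) / x$rate_hz, mean(x$valid)))
  invisible(x)
}

#' Bundle trials into a dataset
#'
#' @param trials list of `gaze_trial` objects.
#' @return an object of class `gaze_dataset` (a list of trials).
#' @export
gaze_dataset <- function(trials) {
  stopifnot(all(vapply(trials, inherits, logical(1), "gaze_trial")))
  ids <- vapply(trials, function(tr) tr$trial_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate trial ids in dataset")
  structure(trials, class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  pid <- vapply(x, function(tr) tr$participant_id, character(1))
  cls <- vapply(x, function(tr) tr$class_label, character(1))
  cat(sprintf("<gaze_dataset> %d trials, %d participants, classes: %s\n",
              length(x), length(unique(pid)),
              paste(sprintf("%s (%d)", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
`[.gaze_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "gaze_dataset")
}

#' Per-trial metadata of a dataset
#' @param dataset a `gaze_dataset`.
#' @return data.frame with `trial_id`, `participant_id`, `class_label`,
#'   `block`, `n_samples`.
#' @export
dataset_index <- function(dataset) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  data.frame(
    trial_id = vapply(dataset, function(tr) tr$trial_id, character(1)),
    participant_id = vapply(dataset, function(tr) tr$participant_id, character(1)),
    class_label = vapply(dataset, function(tr) tr$class_label, character(1)),
    block = vapply(dataset, function(tr) tr$block, integer(1)),
    n_samples = vapply(dataset, function(tr) length(tr$x), integer(1)),
    stringsAsFactors = FALSE
  )
}
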