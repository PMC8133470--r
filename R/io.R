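#' Write a gaze dataset to the trial CSV dialect
#'
#' One row per sample with columns `trial_id, participant_id, class_label,
#' block, t_ms, x_px, y_px, valid` (header mandatory, UTF-8). Rows are grouped
#' by trial and time-sorted within trial; `(0;0)` with `valid = 0` encodes a
#' device error, matching the tracker's export convention.
#'
#' @param dataset a `gaze_dataset`.
#' @param path output file path.
#' @param rate_hz,frame recording metadata written to a `#`-comment header
#'   line so the file round-trips.
#' @return `path`, invisibly.
#' @export
write_trials <- function(path, dataset,
                         rate_hz = dataset[[1]]$rate_hz,
                         frame = dataset[[1]]$frame) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  tabs <- lapply(dataset, function(tr) {
    data.table::data.table(
      trial_id = tr$trial_id, participant_id = tr$participant_id,
      class_label = tr$class_label, block = tr$block,
      t_ms = tr$t_ms, x_px = tr$x, y_px = tr$y,
      valid = as.integer(tr$valid)
    )
  })
  out <- data.table::rbindlist(tabs)
  header <- sprintf("# gazeclass trials v1 rate_hz=%g frame=%gx%g",
                    rate_hz, frame[1], frame[2])
  writeLines(header, path)
  data.table::fwrite(out, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a gaze dataset from the trial CSV dialect
#'
#' Malformed input is rejected with the first offending line where possible:
#' missing columns, non-increasing timestamps within a trial, and duplicate
#' `(trial, t)` pairs are errors.
#'
#' @param path CSV file written by [write_trials()] or any conforming export.
#' @param rate_hz,frame metadata overrides; when `NULL` they are taken from
#'   the file's comment header, falling back to 250 Hz and 3840x1920.
#' @return a `gaze_dataset`.
#' @export
read_trials <- function(path, rate_hz = NULL, frame = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("rate_hz=([0-9.]+) frame=([0-9.]+)x([0-9.]+)", first))[[1]]
    if (length(m) == 4) {
      if (is.null(rate_hz)) rate_hz <- as.numeric(m[2])
      if (is.null(frame)) frame <- as.numeric(m[3:4])
    }
  }
  if (is.null(rate_hz)) rate_hz <- 250
  if (is.null(frame)) frame <- c(3840, 1920)
  tab <- as.data.frame(data.table::fread(path,
    skip = if (startsWith(first, "#")) 1 else 0,
    colClasses = list(character = c("trial_id", "participant_id", "class_label"))))
  needed <- c("trial_id", "participant_id", "class_label", "block",
              "t_ms", "x_px", "y_px", "valid")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("trial CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  # header + comment offset for line numbers in messages
  offset <- if (startsWith(first, "#")) 2L else 1L
  split_rows <- split(seq_len(nrow(tab)), tab$trial_id)
  # preserve file order of trials
  first_row <- vapply(split_rows, min, numeric(1))
  split_rows <- split_rows[order(first_row)]
  trials <- lapply(split_rows, function(rows) {
    tt <- tab[rows, ]
    bad <- which(diff(tt$t_ms) <= 0)
    if (length(bad)) {
      stop(sprintf("trial %s: timestamps not strictly increasing at line %d",
                   tt$trial_id[1], rows[bad[1] + 1] + offset))
    }
    gaze_trial(tt$t_ms, tt$x_px, tt$y_px, tt$valid == 1,
               trial_id = tt$trial_id[1], participant_id = tt$participant_id[1],
               class_label = tt$class_label[1], block = tt$block[1],
               rate_hz = rate_hz, frame = frame)
  })
  gaze_dataset(unname(trials))
}

#' Write an event table to CSV
#' @param events an `event_stream` data.frame.
#' @param path output path.
#' @export
write_events <- function(path, events) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' Write a feature matrix to CSV
#' @param features a feature data.frame from [feature_matrix()].
#' @param path output path.
#' @export
write_features <- function(path, features) {
  data.table::fwrite(as.data.frame(features), path)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV path.
#' @return data.frame with metadata columns and the 46 features.
#' @export
read_features <- function(path) {
  as.data.frame(data.table::fread(path,
    colClasses = list(character = c("trial_id", "participant_id", "class_label"))))
}

#' Assemble the full pipeline configuration
#'
#' Gathers every tunable the pipeline uses — detection thresholds, cleaning
#' bounds, simulation settings and modeling hyperparameters — into one list
#' that serializes losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param params a [gaze_params()] list.
#' @param sim a [sim_config()] list.
#' @param k folds in the ensemble.
#' @param n_runs resampling runs.
#' @param alpha significance-screen threshold.
#' @param top_m size of the most-frequent-feature subset.
#' @param cost SVM regularization constant.
#' @param seed master seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = gaze_params(), sim = sim_config(),
                            k = 50, n_runs = 1000, alpha = 0.011, top_m = 7,
                            cost = 1, seed = 1L) {
  structure(list(params = unclass(params), sim = unclass(sim), k = k,
                 n_runs = n_runs, alpha = alpha, top_m = top_m, cost = cost,
                 seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(path, config) {
  raw <- unclass(config)
  # named vectors serialize as JSON objects so names survive the round trip
  raw$sim$participants <- as.list(raw$sim$participants)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$params <- do.call(gaze_params, raw$params)
  raw$sim <- do.call(sim_config, raw$sim)
  structure(raw, class = "pipeline_config")
}
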