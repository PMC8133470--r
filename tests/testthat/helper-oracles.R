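# Independent brute-force oracles, deliberately written without reusing any
# package internals.

oracle_speed <- function(x, y, frame = c(3840, 1920), rate = 250) {
  n <- length(x)
  out <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    dx <- abs(x[i + 1] - x[i])
    dx <- min(dx, frame[1] - dx)
    ddx <- dx * 360 / frame[1]
    ddy <- (y[i + 1] - y[i]) * 360 / frame[2]
    out[i] <- sqrt(ddx^2 + ddy^2) * rate
  }
  out
}

oracle_dispersion <- function(x, y) {
  (max(x) - min(x)) + (max(y) - min(y))
}

oracle_path_amplitude <- function(x, y, frame = c(3840, 1920), rate = 250) {
  sum(oracle_speed(x, y, frame, rate)) / rate
}

oracle_stats <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else 0
  c(avg = m, sd = s, min = min(v), max = max(v))
}

oracle_confusion <- function(truth, pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  cm
}

oracle_box <- function(v) {
  v <- sort(v)
  n <- length(v)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
  inside <- v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
  list(median = qt(0.5), q1 = q1, q3 = q3,
       lower = min(inside), upper = max(inside))
}

# a trial straight from a coordinate matrix
make_trace <- function(x, y, valid = rep(TRUE, length(x)), rate = 250,
                       frame = c(3840, 1920), ...) {
  gaze_trial(t_ms = (seq_along(x) - 1) * 1000 / rate, x = x, y = y,
             valid = valid, rate_hz = rate, frame = frame, ...)
}

# a trace alternating stationary holds with fast linear jumps; jump speed is
# far above threshold, hold samples are identical points
make_hold_jump_trace <- function(holds_px, hold_samples = 60,
                                 jump_samples = 10, ...) {
  xs <- c(); ys <- c()
  for (i in seq_along(holds_px)) {
    p <- holds_px[[i]]
    xs <- c(xs, rep(p[1], hold_samples))
    ys <- c(ys, rep(p[2], hold_samples))
    if (i < length(holds_px)) {
      q <- holds_px[[i + 1]]
      f <- seq_len(jump_samples) / (jump_samples + 1)
      xs <- c(xs, p[1] + f * (q[1] - p[1]))
      ys <- c(ys, p[2] + f * (q[2] - p[2]))
    }
  }
  make_trace(xs, ys, ...)
}

# lazily built shared fixtures (kept small; reused across test files)
.fixtures <- new.env(parent = emptyenv())

clean_small_features <- function() {
  if (is.null(.fixtures$fm)) {
    cfg <- sim_config(trials_per_participant = 6, trial_duration_s = 5,
                      dropout_rate = 0.005, low_tracking_fraction = 0,
                      idiosyncrasy = 0.1, seed = 101)
    ds <- generate_dataset(cfg)
    ev <- segment_dataset(ds)
    cl <- clean_dataset(ev)
    .fixtures$ds <- ds
    .fixtures$ev <- ev
    .fixtures$fm <- feature_matrix(cl$events)
  }
  .fixtures$fm
}

clean_small_events <- function() {
  invisible(clean_small_features())
  .fixtures$ev
}

clean_small_dataset <- function() {
  invisible(clean_small_features())
  .fixtures$ds
}
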