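#' Simulation configuration
#'
#' Study-level settings for the synthetic gaze generator. The defaults mirror
#' the study conditions the pipeline was designed around: 12/10/13
#' participants in the novice/intermediate/expert classes, 52 trials per
#' participant, 250 Hz sampling on a 3840x1920 equirectangular frame. Trial
#' duration is not a published quantity; 20 s is the package's convention.
#'
#' @param participants named integer vector of participants per class.
#' @param trials_per_participant trials recorded per participant.
#' @param trial_duration_s length of each trial in seconds.
#' @param rate_hz sampling rate.
#' @param frame `c(width, height)` in px.
#' @param dropout_rate expected fraction of samples lost to short
#'   device-error bursts (`(0;0)` encoding).
#' @param low_tracking_fraction fraction of trials degraded below the 75%
#'   tracking-ratio threshold.
#' @param idiosyncrasy relative spread of participant-level offsets
#'   (see [sample_participant()]).
#' @param seed master seed; the full dataset is reproducible from it.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(participants = c(novice = 12, intermediate = 10, expert = 13),
                       trials_per_participant = 52,
                       trial_duration_s = 20,
                       rate_hz = 250,
                       frame = c(3840, 1920),
                       dropout_rate = 0.003,
                       low_tracking_fraction = 0.03,
                       idiosyncrasy = 0.1,
                       seed = 1L) {
  stopifnot(rate_hz > 0, all(frame > 0), trial_duration_s > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            low_tracking_fraction >= 0, low_tracking_fraction <= 1,
            idiosyncrasy >= 0)
  participants <- unlist(participants)
  structure(list(
    participants = participants,
    trials_per_participant = trials_per_participant,
    trial_duration_s = trial_duration_s,
    rate_hz = rate_hz, frame = frame,
    dropout_rate = dropout_rate,
    low_tracking_fraction = low_tracking_fraction,
    idiosyncrasy = idiosyncrasy,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# anisotropic px geometry helpers: the deg/px scale differs between axes
.eta <- function(th, sx, sy) sqrt((cos(th) * sx)^2 + (sin(th) * sy)^2)
.kappa <- function(th) abs(cos(th)) + abs(sin(th))

# Build a hold (fixation or pursuit) path: a smooth, sub-threshold linear
# drift plus a slow perpendicular wobble, rescaled about its centroid so the
# bounding-box dispersion equals D exactly, then anchored at `pos`. All speed
# budgeting happens in degree space because the deg/px scale differs between
# axes; the wobble is temporally smooth (a sinusoid, not white noise) so it
# never creates spurious threshold crossings.
build_hold <- function(pos, m, D, sx, sy, dt_s, cap_deg, frame, margin,
                       theta = NULL, wobble_speed = 4) {
  if (m == 1) return(matrix(pos, 1, 2))
  if (D < 1) {
    tt <- seq(0, 1, length.out = m)
    p <- cbind(pos[1] + 0.3 * sin(2 * pi * tt + runif(1, 0, 6)),
               pos[2] + 0.3 * sin(2 * pi * tt + runif(1, 0, 6)))
    p[1, ] <- pos
    return(p)
  }
  max_step <- function(th) cap_deg * dt_s / .eta(th, sx, sy)
  d_max <- function(th) (m - 1) * max_step(th) * .kappa(th)
  if (is.null(theta)) theta <- runif(1, 0, 2 * pi)
  if (D > 0.95 * d_max(theta)) {
    grid <- seq(0, 2 * pi, length.out = 145)
    theta <- grid[which.max(vapply(grid, d_max, numeric(1)))]
    if (D > 0.95 * d_max(theta)) D <- 0.95 * d_max(theta)
  }
  L <- D / .kappa(theta)
  endp <- pos + L * c(cos(theta), sin(theta))
  inside <- function(p) p[1] > margin[1] && p[1] < frame[1] - margin[1] &&
    p[2] > margin[2] && p[2] < frame[2] - margin[2]
  if (!inside(endp)) {
    theta <- theta + pi
    endp <- pos + L * c(cos(theta), sin(theta))
    if (!inside(endp)) {
      theta <- atan2(frame[2] / 2 - pos[2], frame[1] / 2 - pos[1]) +
        runif(1, -0.3, 0.3)
      L <- min(L, D / .kappa(theta))
    }
  }
  s <- seq(0, L, length.out = m)
  base <- cbind(pos[1] + s * cos(theta), pos[2] + s * sin(theta))
  # slow perpendicular wobble, peak speed `wobble_speed` deg/s
  t_span <- (m - 1) * dt_s
  cyc <- runif(1, 1, 3)
  a_deg <- min(wobble_speed * t_span / (2 * pi * cyc), 0.08)
  tt <- seq(0, 1, length.out = m)
  w <- a_deg * sin(2 * pi * cyc * tt + runif(1, 0, 2 * pi))
  eta <- .eta(theta, sx, sy)
  perp_px <- c(-sin(theta) * sy / sx, cos(theta) * sx / sy) / eta
  p <- base + outer(w, perp_px)
  cen <- colMeans(p)
  r <- (max(p[, 1]) - min(p[, 1])) + (max(p[, 2]) - min(p[, 2]))
  if (r > 0) {
    p <- (p - rep(cen, each = m)) * (D / r) + rep(cen, each = m)
  }
  sweep(p, 2, pos - p[1, ], "+")
}

# Draw one saccade from the participant profile: (duration, mean velocity)
# from the Gaussian copula, amplitude = v * d by the path-length definition.
# The supra-threshold interval speeds are constructed directly — v_j = thr +
# (vbar - thr) * s_j / mean(s_j) over n = round(d / dt) intervals — so the
# detected run reproduces the drawn duration, mean velocity and path-length
# amplitude exactly; one sub-threshold entry and exit ramp interval smooths
# the junction with the adjacent holds.
sample_saccade <- function(pp, dt_ms, thr) {
  sh <- pp$shape
  for (try in 1:10) {
    z1 <- rnorm(1)
    z2 <- pp$rho * z1 + sqrt(1 - pp$rho^2) * rnorm(1)
    d_ms <- qtlnorm(pnorm(z1), pp$sampling$sacc_dur)
    v <- qtlnorm(pnorm(z2), pp$sampling$sacc_vel)
    n <- max(2L, as.integer(round(d_ms / dt_ms)))
    s_j <- approx(sh$tau, sh$s, xout = (seq_len(n) - 0.5) / n)$y
    v_j <- thr + (v - thr) * s_j / mean(s_j)
    # duration/velocity draws whose discretized profile would breach the
    # physiological acceleration bound are unphysiological; redraw them
    if (n == 2L || max(abs(diff(v_j))) / (dt_ms / 1000) < 0.95e5) break
  }
  ramp <- 0.5 * thr
  speeds <- c(ramp, v_j, ramp)          # n + 2 intervals, n + 3 samples
  list(d_ms = d_ms, v = v, A = v * n * dt_ms / 1000, n = n,
       speeds = speeds, n_block = n + 3L)
}

#' Generate one synthetic gaze trial
#'
#' Builds a 250 Hz trace alternating fixation-like holds (slow sub-threshold
#' drift with jitter, bounded dispersion), smooth-pursuit holds (dispersion
#' above the split threshold, duration emergent from a sub-threshold drift
#' speed) and saccadic jumps whose supra-threshold portion reproduces the
#' drawn duration, path-length amplitude and mean velocity. Sample spacing is
#' exactly `1/rate_hz`.
#'
#' The generated ground truth (event type, allocated sample range, drawn
#' measure values, partial flag for events truncated by the trial boundary)
#' is attached as the `"truth"` attribute.
#'
#' @param participant a [sample_participant()] profile.
#' @param config a [sim_config()].
#' @param trial_id,block trial metadata.
#' @return a `gaze_trial`.
#' @export
generate_trial <- function(participant, config, trial_id = "t01", block = 1L) {
  stopifnot(inherits(participant, "participant_profile"),
            inherits(config, "sim_config"))
  rate <- config$rate_hz
  n_total <- as.integer(round(config$trial_duration_s * rate))
  if (n_total < 2 * ceiling(0.05 * rate)) {
    stop("trial duration too short to hold a single event")
  }
  dt_ms <- 1000 / rate; dt_s <- 1 / rate
  frame <- config$frame
  sx <- 360 / frame[1]; sy <- 360 / frame[2]
  thr <- participant$threshold_deg_s
  cap_deg <- 0.9 * thr
  # best achievable bounding-box gain per interval over drift orientations
  grid <- seq(0, 2 * pi, length.out = 145)
  step_opt <- max(.kappa(grid) / .eta(grid, sx, sy)) * cap_deg * dt_s
  margin <- c(680, 360)
  x <- numeric(n_total); y <- numeric(n_total)
  pos <- c(frame[1] / 2, frame[2] / 2) + runif(2, -100, 100)
  truth <- list()
  add_truth <- function(type, s, e, partial = FALSE, dur = NA, disp = NA,
                        amp = NA, vel = NA) {
    truth[[length(truth) + 1]] <<- data.frame(
      type = type, start_idx = s, end_idx = e, partial = partial,
      target_dur_ms = dur, target_disp_px = disp, target_amp_deg = amp,
      target_vel = vel, stringsAsFactors = FALSE)
  }
  fill <- function(idx, mat) { x[idx] <<- mat[, 1]; y[idx] <<- mat[, 2] }

  if (participant$saccade_rate == 0) {
    D <- rtlnorm(1, participant$sampling$fix_disp)
    h <- build_hold(pos, n_total, D, sx, sy, dt_s, cap_deg, frame, margin)
    fill(1:n_total, h)
    add_truth("fixation", 1L, n_total, dur = n_total * dt_ms, disp = D)
  } else {
    i <- 1L
    repeat {
      remaining <- n_total - i + 1L
      if (remaining <= 0L) break
      sc <- sample_saccade(participant, dt_ms, thr)
      is_sp <- runif(1) < participant$p_sp
      if (is_sp) {
        D <- max(rtlnorm(1, participant$sampling$sp_disp), 104)
        v_sp <- runif(1, 0.45, 0.7) * thr
        th0 <- runif(1, 0, 2 * pi)
        step_px <- v_sp * dt_s / .eta(th0, sx, sy)
        m <- max(13L, as.integer(ceiling(D / (.kappa(th0) * step_px))) + 1L)
        dur_t <- NA_real_
      } else {
        # duration and dispersion are positively coupled (longer fixations
        # wander more), which also keeps the dispersion target reachable
        # within the sub-threshold drift-speed budget
        z1 <- rnorm(1)
        z2 <- 0.6 * z1 + 0.8 * rnorm(1)
        dur_t <- qtlnorm(pnorm(z1), participant$sampling$fix_dur)
        D <- qtlnorm(pnorm(z2), participant$sampling$fix_disp)
        # the detected fixation spans this hold plus the two adjacent ramp
        # samples; m is sized so the detected duration matches the draw
        m <- max(as.integer(round(dur_t / dt_ms)) + 1L, 13L)
        m_needed <- as.integer(ceiling(D / (0.95 * step_opt))) + 1L
        m <- max(m, m_needed)
      }
      partial <- FALSE
      # not enough room left for this hold plus another saccade/hold cycle:
      # let the hold absorb the remainder of the trial
      if (m >= remaining - (sc$n_block + 13L)) {
        m <- remaining
        partial <- TRUE
      }
      # the two adjacent ramp steps add a small footprint to the detected
      # bounding box of a fixation; shave it off the drift target
      D_build <- if (is_sp) D else max(D - 1.4, 3)
      h <- build_hold(pos, m, D_build, sx, sy, dt_s, cap_deg, frame, margin,
                      theta = if (is_sp) th0 else NULL)
      fill(i:(i + m - 1L), h)
      add_truth(if (is_sp) "smooth_pursuit" else "fixation",
                i, i + m - 1L, partial = partial, dur = dur_t, disp = D)
      pos <- h[m, ]
      i <- i + m
      if (partial) break
      # saccade block: sample 0 is the hold's last sample (index i - 1); the
      # entry ramp, the n supra-threshold intervals and the exit ramp place
      # interior samples at i .. i + n, and the landing sample at i + n + 1
      # becomes the next hold's first sample
      chord <- sum(sc$speeds) * dt_s    # degrees
      gamma <- NA
      for (try in 1:30) {
        g0 <- runif(1, 0, 2 * pi)
        land <- pos + c(chord * cos(g0) / sx, chord * sin(g0) / sy)
        if (land[1] > margin[1] && land[1] < frame[1] - margin[1] &&
            land[2] > margin[2] && land[2] < frame[2] - margin[2]) {
          gamma <- g0; break
        }
      }
      if (is.na(gamma)) {
        gamma <- atan2((frame[2] / 2 - pos[2]) * sy, (frame[1] / 2 - pos[1]) * sx)
      }
      u_px <- c(cos(gamma) / sx, sin(gamma) / sy)
      path <- cumsum(sc$speeds) * dt_s  # degrees traveled after each interval
      interior <- sc$n + 1L
      fill(i:(i + interior - 1L),
           outer(path[seq_len(interior)], u_px) + rep(pos, each = interior))
      add_truth("saccade", i, i + sc$n, partial = FALSE,
                dur = sc$d_ms, amp = sc$A, vel = sc$v)
      pos <- pos + chord * u_px
      i <- i + interior
    }
  }
  tr <- gaze_trial(t_ms = (0:(n_total - 1L)) * dt_ms, x = x, y = y,
                   trial_id = trial_id,
                   participant_id = participant$participant_id,
                   class_label = participant$class_label, block = block,
                   rate_hz = rate, frame = frame)
  truth_df <- do.call(rbind, truth)
  truth_df$end_idx <- pmin(truth_df$end_idx, n_total)
  attr(tr, "truth") <- truth_df
  tr
}

#' Inject device errors into a trial
#'
#' Replaces geometric-length bursts of samples (mean 3) with the tracker's
#' `(0;0)`/invalid error encoding at the configured expected rate; optionally
#' degrades the whole trial below the 75% tracking-ratio threshold.
#'
#' @param trial a `gaze_trial`.
#' @param config a [sim_config()] (uses `dropout_rate`).
#' @param force_low_tracking degrade this trial below 75% tracking ratio.
#' @param mean_burst mean burst length in samples.
#' @return the modified `gaze_trial` (ground-truth attribute preserved).
#' @export
inject_errors <- function(trial, config, force_low_tracking = FALSE,
                          mean_burst = 3) {
  stopifnot(inherits(trial, "gaze_trial"))
  n <- length(trial$x)
  r <- config$dropout_rate
  kill <- rep(FALSE, n)
  if (r > 0) {
    starts <- which(runif(n) < r / mean_burst)
    for (s in starts) {
      len <- 1L + rgeom(1, 1 / mean_burst)
      kill[s:min(s + len - 1L, n)] <- TRUE
    }
  }
  if (force_low_tracking) {
    while (mean(!kill) >= 0.72) {
      s <- sample.int(n, 1)
      len <- 25L + rgeom(1, 1 / 50)
      kill[s:min(s + len - 1L, n)] <- TRUE
    }
  }
  if (any(kill)) {
    trial$x[kill] <- 0
    trial$y[kill] <- 0
    trial$valid[kill] <- FALSE
  }
  trial
}

#' Generate a full synthetic dataset
#'
#' Draws participant profiles per class, simulates every trial, injects
#' device errors, and returns a reproducible `gaze_dataset`. Class labels are
#' taken from the names of `profiles`, so passing the same profile under all
#' three names produces a zero-separation dataset.
#'
#' @param config a [sim_config()].
#' @param profiles named list of [class_profile()]s; names must match
#'   `names(config$participants)`.
#' @return a `gaze_dataset` with attributes `ledger` (trials per participant)
#'   and per-trial `truth` attributes on each trial.
#' @export
generate_dataset <- function(config = sim_config(),
                             profiles = default_class_profiles()) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(names(config$participants) %in% names(profiles)))
  set.seed(config$seed)
  trials <- list()
  ledger <- list()
  counter <- 0L
  for (label in names(config$participants)) {
    prof <- profiles[[label]]
    for (p in seq_len(config$participants[[label]])) {
      counter <- counter + 1L
      pid <- sprintf("P%02d", counter)
      pp <- sample_participant(prof, config$idiosyncrasy, pid)
      pp$class_label <- label
      half <- ceiling(config$trials_per_participant / 2)
      for (j in seq_len(config$trials_per_participant)) {
        tid <- sprintf("%s_t%02d", pid, j)
        tr <- generate_trial(pp, config, trial_id = tid,
                             block = if (j <= half) 1L else 2L)
        tr <- inject_errors(tr, config,
                            force_low_tracking =
                              runif(1) < config$low_tracking_fraction)
        trials[[length(trials) + 1L]] <- tr
      }
      ledger[[length(ledger) + 1L]] <- data.frame(
        participant_id = pid, class_label = label,
        n_trials = config$trials_per_participant, stringsAsFactors = FALSE)
    }
  }
  ds <- gaze_dataset(trials)
  attr(ds, "ledger") <- do.call(rbind, ledger)
  attr(ds, "config") <- config
  ds
}
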