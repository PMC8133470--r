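test_that("tracking ratio counts valid samples", {
  tr <- make_trace(runif(100, 1, 100), runif(100, 1, 100))
  expect_equal(tracking_ratio(tr), 1)
  v <- rep(TRUE, 5000); v[sample.int(5000, 600)] <- FALSE
  tr2 <- make_trace(runif(5000, 1, 100), runif(5000, 1, 100), valid = v)
  expect_equal(tracking_ratio(tr2), 0.88)
})

make_ratio_trial <- function(ratio, id, pid = "P01") {
  n <- 100
  v <- rep(TRUE, n)
  if (ratio < 1) v[seq_len(round((1 - ratio) * n))] <- FALSE
  make_trace(runif(n, 1, 100), runif(n, 1, 100), valid = v,
             trial_id = id, participant_id = pid)
}

test_that("trial filtering applies the 75% rule and reports a ledger", {
  ds <- gaze_dataset(list(
    make_ratio_trial(1.0, "t1"), make_ratio_trial(0.8, "t2"),
    make_ratio_trial(0.5, "t3"), make_ratio_trial(0.74, "t4", "P02")))
  out <- filter_trials(ds)
  expect_equal(out$n_kept, 2)
  expect_equal(out$fraction_lost, 0.5)
  led <- out$ledger
  expect_equal(led$n_invalid[led$participant_id == "P01"], 1)
  expect_equal(led$n_invalid[led$participant_id == "P02"], 1)
  # no invalid trials: identity
  ds2 <- gaze_dataset(list(make_ratio_trial(1, "a"), make_ratio_trial(1, "b")))
  out2 <- filter_trials(ds2)
  expect_equal(out2$n_kept, 2)
  expect_equal(out2$fraction_lost, 0)
})

test_that("path-length amplitude follows the mean-velocity x duration identity", {
  # straight 10-degree path in equal steps along x: 10 deg = 106.67 px
  n <- 6
  x <- 500 + (0:(n - 1)) * (10 / 0.09375) / (n - 1)
  y <- rep(800, n)
  expect_equal(saccade_amplitude(x, y), 10, tolerance = 1e-12)
  # L-shaped path: 3 degrees in x then 4 degrees in y -> 7 (path), not 5 (chord)
  xl <- c(500, 500 + 16, 500 + 32, 500 + 32, 500 + 32)
  yl <- c(800, 800, 800, 800 + 64 / 6, 800 + 64 / 3)
  expect_equal(saccade_amplitude(xl, yl), 7, tolerance = 1e-9)
  expect_equal(saccade_amplitude(xl, yl), oracle_path_amplitude(xl, yl),
               tolerance = 1e-9)
  expect_error(saccade_amplitude(1, 1), "2 samples")
})

test_that("saccade validation flags each physiological rule", {
  rec <- list(first_valid = TRUE, all_valid = TRUE, peak_vel = 300,
              peak_acc = 9000, peak_dec = -8000)
  expect_length(validate_saccade(rec), 0)
  rec$first_valid <- FALSE
  expect_true("invalid_start" %in% validate_saccade(rec))
  rec2 <- list(first_valid = TRUE, all_valid = TRUE, peak_vel = 1200,
               peak_acc = 9000, peak_dec = -8000)
  expect_identical(validate_saccade(rec2), "velocity_bound")
  rec3 <- list(first_valid = TRUE, all_valid = TRUE, peak_vel = 900,
               peak_acc = 2e5, peak_dec = -8000)
  expect_identical(validate_saccade(rec3), "accel_bound")
  rec4 <- list(first_valid = TRUE, all_valid = TRUE, peak_vel = 900,
               peak_acc = 9000, peak_dec = -2e5)
  expect_identical(validate_saccade(rec4), "accel_bound")
})

test_that("a device-error burst inside a saccade trips intra and velocity rules", {
  # hold, then a jump whose middle samples drop to (0;0): the 2400+ px
  # excursions produce speeds of the order of 5e4 deg/s
  x <- c(rep(1200, 60), 1300, 1400, 0, 0, 1700, 1800, rep(1900, 60))
  y <- c(rep(900, 60), 950, 1000, 0, 0, 1150, 1200, rep(1250, 60))
  valid <- rep(TRUE, length(x)); valid[63:64] <- FALSE
  tr <- make_trace(x, y, valid = valid)
  ev <- segment_trial(tr)
  sacc <- ev[ev$type == "saccade", ]
  expect_equal(nrow(sacc), 1)
  reasons <- validate_saccade(sacc[1, ])
  expect_true(all(c("invalid_intra", "velocity_bound") %in% reasons))
  expect_gt(sacc$peak_vel[1], 4e4)
  cl <- clean_dataset(ev)
  expect_equal(cl$report$n_removed, 1)
  expect_equal(sum(cl$events$type == "saccade"), 0)
})

test_that("cleaning an error-free dataset removes nothing", {
  cfg <- sim_config(participants = c(expert = 1), trials_per_participant = 6,
                    trial_duration_s = 8, dropout_rate = 0,
                    low_tracking_fraction = 0, idiosyncrasy = 0, seed = 12)
  ds <- generate_dataset(cfg)
  cl <- clean_dataset(segment_dataset(ds))
  expect_equal(cl$report$n_removed, 0)
  expect_true(all(cl$report$per_reason == 0))
  expect_equal(cl$report$fraction_samples_removed, 0)
})

test_that("cleaning is idempotent and a multi-rule saccade counts once", {
  ev <- data.frame(
    trial_id = "t", participant_id = "p", class_label = "novice",
    type = c("saccade", "saccade", "fixation"),
    start_idx = c(1, 20, 40), end_idx = c(10, 30, 100),
    start_ms = 0, end_ms = 1, duration_ms = c(40, 40, 240), n_samples = 10,
    centroid_x = NA, centroid_y = NA, dispersion_px = c(NA, NA, 50),
    amplitude_deg = 5, mean_vel = 200, peak_vel = c(1500, 300, NA),
    mean_acc = 5000, peak_acc = c(2e5, 1e4, NA), peak_dec = -1e4,
    first_valid = c(FALSE, TRUE, TRUE), all_valid = c(FALSE, TRUE, TRUE))
  cl <- clean_dataset(ev)
  # one saccade violates four rules but is removed (and counted) once
  expect_equal(cl$report$n_removed, 1)
  expect_equal(sum(cl$report$per_reason), 4)
  expect_gte(sum(cl$report$per_reason), cl$report$n_removed)
  # idempotence
  cl2 <- clean_dataset(cl$events)
  expect_equal(cl2$report$n_removed, 0)
  expect_equal(nrow(cl2$events), nrow(cl$events))
})

test_that("injected dropout leads to a plausible removal ledger", {
  ds <- clean_small_dataset()
  cl <- clean_dataset(segment_dataset(ds))
  rep <- cl$report
  expect_gt(rep$n_removed, 0)
  expect_lte(rep$n_removed, sum(rep$per_reason))
  expect_gt(rep$per_reason[["invalid_intra"]], 0)
  expect_lt(rep$fraction_saccades_removed, 0.2)
  # every surviving saccade satisfies all quality rules
  sacc <- cl$events[cl$events$type == "saccade", ]
  expect_true(all(sacc$first_valid))
  expect_true(all(sacc$all_valid))
  expect_true(all(sacc$peak_vel <= 1000))
  expect_true(all(abs(sacc$peak_acc) <= 1e5 & abs(sacc$peak_dec) <= 1e5))
})
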