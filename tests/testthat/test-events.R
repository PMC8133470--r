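test_that("pixel-degree conversion reproduces the equirectangular arithmetic", {
  expect_equal(px_to_deg(2400, 0)$x, 225)
  expect_equal(px_to_deg(0, 1000)$y, 187.5)
  expect_equal(px_to_deg(0, 0), list(x = 0, y = 0))
  # linearity and exact round-trip on integer pixels
  d <- px_to_deg(-37, 1234)
  expect_equal(px_to_deg(-74, 2468)$x, 2 * d$x)
  back <- deg_to_px(d$x, d$y)
  expect_identical(c(back$x, back$y), c(-37, 1234))
})

test_that("sample velocity matches a brute-force two-point computation", {
  # stationary trace
  tr <- make_trace(rep(100, 20), rep(200, 20))
  expect_true(all(sample_velocity(tr)$speed_deg_s == 0))
  # a 1200 px displacement in one 4 ms interval: 112.5 deg -> 28125 deg/s
  tr2 <- make_trace(c(100, 1300), c(500, 500))
  expect_equal(sample_velocity(tr2)$speed_deg_s, 112.5 / 0.004)
  # beyond half the frame width the equirectangular seam is the shorter way
  tr2b <- make_trace(c(100, 2500), c(500, 500))
  expect_equal(sample_velocity(tr2b)$speed_deg_s, (1440 * 360 / 3840) / 0.004)
  # uniform drift: constant speed equal to the oracle
  tr3 <- make_trace(500 + 3 * (0:99), rep(800, 100))
  v3 <- sample_velocity(tr3)$speed_deg_s
  expect_equal(v3, oracle_speed(tr3$x, tr3$y))
  expect_equal(max(v3) - min(v3), 0)
  # random walks, including the horizontal wrap-around seam
  set.seed(5)
  for (i in 1:25) {
    x <- cumsum(c(runif(1, 0, 3840), rnorm(60, 0, 40))) %% 3840
    y <- pmin(pmax(cumsum(c(960, rnorm(60, 0, 25))), 1), 1919)
    tr <- make_trace(x, y)
    expect_equal(sample_velocity(tr)$speed_deg_s, oracle_speed(x, y))
  }
  expect_error(sample_velocity(make_trace(1, 1)), "2 samples")
})

test_that("velocity flags pairs touching invalid samples", {
  tr <- make_trace(c(100, 100, 0, 100, 100), c(50, 50, 0, 50, 50),
                   valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  v <- sample_velocity(tr)
  expect_identical(v$valid_pair, c(TRUE, FALSE, FALSE, TRUE))
  # speeds stay numeric (the device-error jump is visible to detection)
  expect_true(all(is.finite(v$speed_deg_s)))
  expect_gt(v$speed_deg_s[2], 1000)
})

test_that("saccade detection finds supra-threshold runs with merging", {
  expect_equal(nrow(detect_saccades(rep(10, 100))), 0)
  # one run of 5 supra intervals starting at interval 11
  sp <- rep(5, 100); sp[11:15] <- 300
  s <- detect_saccades(sp)
  expect_equal(unname(s[1, ]), c(11L, 16L))
  # two jumps separated by a 300 ms hold
  sp2 <- rep(5, 200); sp2[21:26] <- 300; sp2[110:114] <- 300
  expect_equal(nrow(detect_saccades(sp2)), 2)
  # single sub-threshold sample inside a run is merged
  sp3 <- rep(5, 100); sp3[11:20] <- 300; sp3[15] <- 30
  expect_equal(nrow(detect_saccades(sp3)), 1)
  expect_equal(unname(detect_saccades(sp3)[1, ]), c(11L, 21L))
  # runs shorter than the minimum are discarded
  sp4 <- rep(5, 100); sp4[11:12] <- 300
  expect_equal(nrow(detect_saccades(sp4, min_samples = 3, merge_gap = 0)), 0)
})

test_that("dispersion uses the bounding-box sum over valid samples", {
  expect_equal(dispersion(rep(7, 5), rep(9, 5)), 0)
  expect_equal(dispersion(c(0, 30, 0), c(0, 0, 40)), 70)
  # interior points never change the value
  expect_equal(dispersion(c(0, 30, 0, 10), c(0, 0, 40, 12)), 70)
  # invalid samples are excluded
  expect_equal(dispersion(c(0, 30, 0, 999), c(0, 0, 40, 999),
                          valid = c(TRUE, TRUE, TRUE, FALSE)), 70)
  expect_error(dispersion(1, 1, valid = FALSE), "valid")
  set.seed(8)
  for (i in 1:25) {
    x <- runif(10, 0, 3840); y <- runif(10, 0, 1920)
    expect_equal(dispersion(x, y), oracle_dispersion(x, y))
  }
})

test_that("smooth-pursuit split partitions holds at the dispersion threshold", {
  ev <- data.frame(dispersion_px = c(99.9, 100.1, 0, 250))
  out <- split_smooth_pursuits(ev)
  expect_identical(out$type, c("fixation", "smooth_pursuit", "fixation",
                               "smooth_pursuit"))
  empty <- split_smooth_pursuits(ev[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("gap detection needs a long enough invalid run", {
  tr <- make_trace(runif(200, 100, 200), runif(200, 100, 200))
  expect_equal(nrow(detect_gaps(tr)), 0)
  # 150 ms = 38 samples invalid
  v <- rep(TRUE, 200); v[50:87] <- FALSE
  tr2 <- make_trace(tr$x, tr$y, valid = v)
  g <- detect_gaps(tr2)
  expect_equal(nrow(g), 1)
  expect_equal(unname(g[1, ]), c(50L, 87L))
  # 8 ms = 2 samples: no gap
  v3 <- rep(TRUE, 200); v3[50:51] <- FALSE
  expect_equal(nrow(detect_gaps(make_trace(tr$x, tr$y, valid = v3))), 0)
})

test_that("fixation assembly fills complements and rejects short holds", {
  none <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  f <- assemble_fixations(500, none, none)
  expect_equal(unname(f[1, ]), c(1L, 500L))
  # 40 ms (11 samples, 10 intervals) between two saccades: rejected
  sacc <- rbind(c(start = 100L, end = 120L), c(start = 132L, end = 150L))
  f2 <- assemble_fixations(500, sacc, none)
  expect_false(any(f2[, "start"] == 121))
  # a 200 ms hold between jumps survives
  sacc3 <- rbind(c(start = 100L, end = 110L), c(start = 162L, end = 170L))
  f3 <- assemble_fixations(500, sacc3, none)
  expect_true(any(f3[, "start"] == 111 & f3[, "end"] == 161))
})

test_that("segment_trial recovers a constructed event sequence and tiles the trial", {
  holds <- list(c(1000, 900), c(1600, 900), c(1600, 1300), c(1000, 1300))
  tr <- make_hold_jump_trace(holds, hold_samples = 60, jump_samples = 10)
  ev <- segment_trial(tr)
  expect_equal(sum(ev$type == "fixation"), 4)
  expect_equal(sum(ev$type == "saccade"), 3)
  expect_equal(sum(ev$type == "smooth_pursuit"), 0)
  # ordered, non-overlapping, and every sample accounted for at most once
  ev <- ev[order(ev$start_idx), ]
  expect_true(all(diff(ev$start_idx) > 0))
  expect_true(all(ev$end_idx[-nrow(ev)] < ev$start_idx[-1]))
  # saccade kinematics: straight jump amplitude equals the oracle path
  sc <- ev[ev$type == "saccade", ][1, ]
  idx <- sc$start_idx:sc$end_idx
  expect_equal(sc$amplitude_deg,
               oracle_path_amplitude(tr$x[idx], tr$y[idx]), tolerance = 1e-10)
  expect_true(all(ev$peak_vel[ev$type == "saccade"] >=
                  ev$mean_vel[ev$type == "saccade"]))
})

test_that("a pure drift trial with a large path is a single smooth pursuit", {
  x <- 800 + (0:999) * 0.9   # 0.9 px / 4 ms = 21 deg/s, 900 px total
  tr <- make_trace(x, rep(900, 1000))
  ev <- segment_trial(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "smooth_pursuit")
  expect_gt(ev$dispersion_px, 100)
})

test_that("emitted fixations and pursuits respect duration and dispersion rules", {
  ev <- clean_small_events()
  fx <- ev[ev$type == "fixation", ]
  sp <- ev[ev$type == "smooth_pursuit", ]
  expect_true(all(fx$duration_ms >= 50))
  expect_true(all(fx$dispersion_px <= 100))
  expect_true(all(sp$dispersion_px > 100))
  expect_true(all(sp$duration_ms >= 50))
})
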