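# --- truncated log-normal machinery -----------------------------------------
# Event measures are positive and right-skewed with published mean/sd/min/max;
# we use a log-normal matched by moments, truncated at the published range.
# Truncation shifts the mean, so the location parameter is re-solved such that
# the *truncated* mean equals the target exactly.

tlnorm_trunc_mean <- function(mu, sigma, lo, hi) {
  a <- (log(lo) - mu) / sigma
  b <- (log(hi) - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  # all mass outside the window: the truncated mean collapses to an edge
  if (!is.finite(z) || z < 1e-12) return(if (a > 0) lo else hi)
  exp(mu + sigma^2 / 2) * (pnorm(b - sigma) - pnorm(a - sigma)) / z
}

tlnorm_params <- function(mean, sd, lo, hi) {
  stopifnot(mean > 0, sd >= 0, lo > 0, hi > lo, mean > lo, mean < hi)
  if (sd == 0) return(list(mu = log(mean), sigma = 0, lo = lo, hi = hi))
  sigma <- sqrt(log(1 + (sd / mean)^2))
  mu0 <- log(mean) - sigma^2 / 2
  f <- function(mu) tlnorm_trunc_mean(mu, sigma, lo, hi) - mean
  mu <- uniroot(f, c(mu0 - 6, mu0 + 10), tol = 1e-10)$root
  list(mu = mu, sigma = sigma, lo = lo, hi = hi)
}

# quantile transform of u in [0,1] to the truncated log-normal
qtlnorm <- function(u, p) {
  if (p$sigma == 0) return(rep(exp(p$mu), length(u)))
  plo <- plnorm(p$lo, p$mu, p$sigma)
  phi <- plnorm(p$hi, p$mu, p$sigma)
  qlnorm(plo + u * (phi - plo), p$mu, p$sigma)
}

rtlnorm <- function(n, p) qtlnorm(runif(n), p)

# --- saccade velocity shape --------------------------------------------------
# The generator constructs the *detected* (supra-threshold) part of each
# saccade directly: discrete interval speeds v_j = thr + (vbar - thr) * s_j /
# mean(s), where s is a unit-peak shape from the Beta density family. The
# mean over the detected run is then vbar exactly, and the expected peak is
# thr + (vbar - thr) * max(g) with max(g) = 1 / mean(s). alpha/beta are fit
# so that max(g) matches the class excess peak/mean velocity ratio and the
# rising/falling slope ratio matches the peak-acceleration to
# peak-deceleration magnitude ratio. The minimum-jerk profile is the (3,3)
# member of the family.

fit_saccade_shape <- function(peak_gain, acc_dec_ratio) {
  tau <- seq(0, 1, length.out = 2001)
  dtau <- tau[2] - tau[1]
  obj <- function(par) {
    a <- 1 + exp(par[1]); b <- 1 + exp(par[2])
    g <- dbeta(tau, a, b)
    dg <- diff(g) / dtau
    (max(g) / peak_gain - 1)^2 +
      ((max(dg) / (-min(dg))) / acc_dec_ratio - 1)^2
  }
  fit <- optim(c(log(2), log(2.5)), obj)
  a <- 1 + exp(fit$par[1]); b <- 1 + exp(fit$par[2])
  g <- dbeta(tau, a, b)
  list(alpha = a, beta = b, tau = tau, s = g / max(g), max_g = max(g))
}

# --- duration/velocity copula ------------------------------------------------
# Saccade amplitude is, by the path-length definition, identically
# mean velocity x duration, so its mean is controlled through the correlation
# of the (duration, mean velocity) Gaussian copula. The correlation is solved
# on a deterministic quadrature grid so that E[v * d] hits the amplitude
# target.

copula_amp_mean <- function(rho, dpar, vpar, m = 80) {
  z <- qnorm(((1:m) - 0.5) / m)
  d <- qtlnorm(pnorm(z), dpar) / 1000      # ms -> s
  e <- 0
  s <- sqrt(1 - rho^2)
  for (j in seq_len(m)) {
    v <- qtlnorm(pnorm(rho * z + s * z[j]), vpar)
    e <- e + sum(d * v)
  }
  e / m^2
}

calibrate_rho <- function(dpar, vpar, amp_target) {
  f <- function(rho) copula_amp_mean(rho, dpar, vpar) - amp_target
  lo <- f(-0.95); hi <- f(0.95)
  if (lo > 0) return(-0.95)
  if (hi < 0) return(0.95)
  uniroot(f, c(-0.95, 0.95), tol = 1e-6)$root
}

# --- class profiles ----------------------------------------------------------

measure_names <- c("fix_dur", "fix_disp", "sacc_dur", "sacc_amp",
                   "sacc_acc_mean", "sacc_acc_peak", "sacc_dec_peak",
                   "sacc_vel_mean", "sacc_vel_peak", "sp_dur", "sp_disp")

#' Construct a class profile for the gaze generator
#'
#' A class profile carries the published per-class population statistics of
#' the eleven kinematic measures (`mean`, `sd`, `min`, `max` each) plus the
#' two event-frequency values, and derives from them the sampling machinery
#' the generator uses: truncated log-normal marginals with exact mean
#' correction, the duration/velocity copula correlation that reproduces the
#' amplitude mean, and the Beta velocity shape matching the peak-velocity and
#' acceleration ratios.
#'
#' Feasibility constraints imposed by the detection rules are applied to the
#' *sampling* bounds (targets are stored untouched): fixation dispersion is
#' truncated below the 100 px smooth-pursuit split, and the mean-velocity
#' floor is raised to 30 deg/s so every generated saccade clears the 40 deg/s
#' detection threshold. Smooth-pursuit duration is emergent (dispersion
#' divided by a sub-threshold drift speed) because the published
#' dispersion/duration pairs would imply drift speeds several times the
#' saccade threshold; the dispersion channel, which carries the class
#' separation, is honored exactly.
#'
#' @param class_label one of `"novice"`, `"intermediate"`, `"expert"` (free
#'   text is allowed for custom profiles).
#' @param targets named list; each of the eleven measures maps to
#'   `c(mean, sd, min, max)` (see [default_class_profiles()] for units).
#' @param fix_freq,sacc_freq published event-frequency values (stored as
#'   reporting targets; trial event rates are emergent from durations).
#' @param p_sp probability that a hold event is a smooth pursuit.
#' @param saccade_rate set to 0 to disable saccades entirely (degenerate
#'   single-fixation trials); any positive value enables the hold/saccade
#'   alternation.
#' @param threshold_deg_s detection threshold assumed by the trim correction.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(class_label, targets, fix_freq = NA_real_,
                          sacc_freq = NA_real_, p_sp = 0.15,
                          saccade_rate = 1, threshold_deg_s = 40) {
  stopifnot(all(measure_names %in% names(targets)))
  for (m in measure_names) {
    tg <- targets[[m]]
    stopifnot(length(tg) == 4, tg[2] >= 0)
  }
  stopifnot(p_sp >= 0, p_sp <= 1, saccade_rate >= 0)
  tg <- function(m) unname(targets[[m]])

  samp <- list(
    fix_dur = tlnorm_params(tg("fix_dur")[1], tg("fix_dur")[2],
                            tg("fix_dur")[3], tg("fix_dur")[4]),
    fix_disp = tlnorm_params(tg("fix_disp")[1], tg("fix_disp")[2],
                             tg("fix_disp")[3], min(tg("fix_disp")[4], 97)),
    sacc_dur = tlnorm_params(tg("sacc_dur")[1], tg("sacc_dur")[2],
                             tg("sacc_dur")[3], tg("sacc_dur")[4]),
    sacc_vel = tlnorm_params(tg("sacc_vel_mean")[1], tg("sacc_vel_mean")[2],
                             max(tg("sacc_vel_mean")[3], threshold_deg_s + 5),
                             tg("sacc_vel_mean")[4]),
    sp_disp = tlnorm_params(tg("sp_disp")[1], tg("sp_disp")[2],
                            max(tg("sp_disp")[3], 102), tg("sp_disp")[4])
  )
  # excess-over-threshold peak/mean velocity gain and the peak-acceleration
  # to peak-deceleration magnitude ratio jointly determine the shape
  peak_gain <- (tg("sacc_vel_peak")[1] - threshold_deg_s) /
    (tg("sacc_vel_mean")[1] - threshold_deg_s)
  adr <- tg("sacc_acc_peak")[1] / abs(tg("sacc_dec_peak")[1])
  shape <- fit_saccade_shape(peak_gain, adr)
  rho <- calibrate_rho(samp$sacc_dur, samp$sacc_vel, tg("sacc_amp")[1])

  structure(list(
    class_label = class_label,
    targets = targets,
    fix_freq = fix_freq, sacc_freq = sacc_freq,
    p_sp = p_sp, saccade_rate = saccade_rate,
    threshold_deg_s = threshold_deg_s,
    sampling = samp, shape = shape, rho = rho
  ), class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile %s> fix dur %.1f ms, sacc amp %.2f deg, sp disp %.1f px, p_sp %.2f\n",
              x$class_label, x$targets$fix_dur[1], x$targets$sacc_amp[1],
              x$targets$sp_disp[1], x$p_sp))
  invisible(x)
}

#' Default class profiles for the three expertise groups
#'
#' The published per-class averages, standard deviations, minima and maxima
#' of all eleven kinematic measures, for novice, intermediate and expert
#' observers. Units: durations ms, dispersions px, amplitude deg, velocities
#' deg/s, accelerations deg/s^2 (peak deceleration is a negative quantity by
#' convention). These values are the population targets the synthetic
#' generator is calibrated against.
#'
#' @param p_sp smooth-pursuit share of hold events (common to all classes).
#' @return named list of three [class_profile()]s
#'   (`novice`, `intermediate`, `expert`).
#' @export
default_class_profiles <- function(p_sp = 0.15) {
  novice <- list(
    fix_dur       = c(214.017, 31.926, 190.49, 239.30),
    fix_disp      = c(72.092, 25.68, 24.67, 110.523),
    sacc_dur      = c(71.688, 38.869, 26.514, 175.460),
    sacc_amp      = c(9.294, 9.417, 0.574, 51.402),
    sacc_acc_mean = c(4263.381, 2482.019, 366.666, 13984.563),
    sacc_acc_peak = c(9322.483168, 5777.273817, 231.836, 28355.224),
    sacc_dec_peak = c(-6848.104, 4166.262, -35563.646, -411.760),
    sacc_vel_mean = c(105.463, 65.023, 20.288, 298.134),
    sacc_vel_peak = c(215.245, 129.294, 40.310, 766.157),
    sp_dur        = c(302.637, 278.112, 75.629, 1026.329),
    sp_disp       = c(622.805, 201.268, 185.437, 1085.903)
  )
  intermediate <- list(
    fix_dur       = c(255.225, 53.379, 215.835, 299.623),
    fix_disp      = c(73.173, 26.548, 23.070, 114.762),
    sacc_dur      = c(84.349, 59.726, 26.127, 246.121),
    sacc_amp      = c(9.883, 10.674, 0.572, 54.835),
    sacc_acc_mean = c(4123.970, 2685.991, 315.346, 15472.889),
    sacc_acc_peak = c(8920.177, 5989.251, 216.722, 28266.000),
    sacc_dec_peak = c(-6948.491, 4770.063, -36334.137, -231.355),
    sacc_vel_mean = c(104.199, 66.682, 21.520, 331.111),
    sacc_vel_peak = c(213.835, 136.529, 40.109, 764.027),
    sp_dur        = c(291.092, 278.718, 73.835, 977.120),
    sp_disp       = c(425.089, 124.853, 168.320, 694.370)
  )
  expert <- list(
    fix_dur       = c(241.509, 58.629, 198.132, 291.721),
    fix_disp      = c(72.837, 25.989, 21.736, 114.549),
    sacc_dur      = c(65.472, 35.548, 25.019, 163.415),
    sacc_amp      = c(8.938, 9.430, 0.567, 52.029),
    sacc_acc_mean = c(4769.655, 3064.343, 390.094, 18965.944),
    sacc_acc_peak = c(10026.456, 7094.930, 175.242, 39445.125),
    sacc_dec_peak = c(-7912.190, 5492.287, -43479.916, -362.396),
    sacc_vel_mean = c(110.675, 72.737, 21.182, 375.363),
    sacc_vel_peak = c(238.371, 157.740, 40.262, 935.514),
    sp_dur        = c(276.785, 265.679, 74.404, 953.660),
    sp_disp       = c(399.939, 112.414, 336.016, 505.031)
  )
  list(
    novice = class_profile("novice", novice, fix_freq = 0.214,
                           sacc_freq = 0.071, p_sp = p_sp),
    intermediate = class_profile("intermediate", intermediate,
                                 fix_freq = 0.255, sacc_freq = 0.084,
                                 p_sp = p_sp),
    expert = class_profile("expert", expert, fix_freq = 0.241,
                           sacc_freq = 0.007, p_sp = p_sp)
  )
}

#' Draw a participant profile from a class profile
#'
#' Participant idiosyncrasy: each sampled measure's location is multiplied by
#' `1 + delta` with `delta ~ N(0, spread^2)` i.i.d. across measures, so the
#' expectation of every measure equals the class value and the relative
#' offset standard deviation equals `spread`. A spread of zero reproduces the
#' class profile exactly. Log-normal marginals are shifted in log-space
#' (bounds scale along), which scales the truncated mean exactly.
#'
#' @param profile a [class_profile()].
#' @param spread relative idiosyncrasy spread (>= 0).
#' @param participant_id identifier for the participant.
#' @param seed optional seed for reproducible draws.
#' @return an object of class `participant_profile`.
#' @export
sample_participant <- function(profile, spread = 0.1,
                               participant_id = "p01", seed = NULL) {
  stopifnot(inherits(profile, "class_profile"))
  if (spread < 0) stop("idiosyncrasy spread must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  idio_measures <- c("fix_dur", "fix_disp", "sacc_dur", "sacc_vel", "sp_disp")
  offsets <- rnorm(length(idio_measures) + 1, 0, spread)
  names(offsets) <- c(idio_measures, "p_sp")
  samp <- profile$sampling
  for (m in idio_measures) {
    f <- 1 + offsets[[m]]
    f <- max(f, 0.2)          # keep degenerate draws positive
    samp[[m]]$mu <- samp[[m]]$mu + log(f)
    samp[[m]]$lo <- samp[[m]]$lo * f
    samp[[m]]$hi <- samp[[m]]$hi * f
  }
  # detection-rule feasibility survives idiosyncrasy: fixations stay below the
  # dispersion split, pursuits above it
  samp$fix_disp$hi <- min(samp$fix_disp$hi, 97)
  samp$fix_disp$lo <- min(samp$fix_disp$lo, 90)
  samp$sp_disp$lo <- max(samp$sp_disp$lo, 102)
  samp$sp_disp$hi <- max(samp$sp_disp$hi, 130)
  p_sp <- min(max(profile$p_sp * (1 + offsets[["p_sp"]]), 0), 1)
  structure(list(
    participant_id = participant_id,
    class_label = profile$class_label,
    spread = spread,
    offsets = offsets,
    p_sp = p_sp,
    saccade_rate = profile$saccade_rate,
    threshold_deg_s = profile$threshold_deg_s,
    sampling = samp,
    shape = profile$shape,
    rho = profile$rho
  ), class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile %s> class %s, spread %.3f\n",
              x$participant_id, x$class_label, x$spread))
  invisible(x)
}
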