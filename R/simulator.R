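#' Simulation specification for synthetic thigh-IMU gait
#'
#' A parametric stride timeline plus waveform settings.  The simulator is
#' a specification-by-construction of the signal morphology the detector
#' relies on, not a biomechanical model: each detector rule has a unique,
#' exactly placed trigger in the noiseless signals.  Default event phases
#' (opposite toe off at 12%, opposite initial contact at 50%, toe off at
#' 62% of the cycle, initial contact at 0) reproduce the usual healthy
#' regime of about 62% stance and symmetry near 50%.
#'
#' @param n_strides number of strides.
#' @param stride_mean,stride_sd stride duration mean and SD, seconds;
#'   durations are drawn from a normal truncated below at
#'   `0.5 * stride_mean`.
#' @param oto_phase,oic_phase,to_phase event phases as fractions of the
#'   stride, with initial contact at phase 0; must satisfy
#'   `0 < oto < oic < to < 1` (after `asymmetry_shift` is added to
#'   `oic_phase`).
#' @param asymmetry_shift added to `oic_phase` to simulate asymmetric
#'   timing (e.g. `-0.03` moves the symmetry index to 47%).
#' @param gyro_amp pitch-rate amplitude, rad/s: the opposite-toe-off
#'   peak is `+gyro_amp`, the toe-off trough `-0.9 * gyro_amp`.
#' @param accz_amp amplitude of the two-per-stride vertical-acceleration
#'   oscillation, m/s^2.
#' @param impact_amp_ic,impact_amp_oic Gaussian impact-pulse amplitudes
#'   at initial contact and opposite initial contact, m/s^2.
#' @param impact_width impact pulse width, seconds (Gaussian sigma =
#'   `impact_width / 2`).
#' @param noise_sd_acc,noise_sd_gyro additive white Gaussian noise SD in
#'   m/s^2 and rad/s; default 0 (noiseless).
#' @param noise_frac if non-`NULL`, overrides the two SDs with this
#'   fraction of the RMS of the corresponding noiseless signal
#'   (vertical acceleration / pitch rate).
#' @param lead_in padding before the first and after the last initial
#'   contact, seconds, so edge strides keep their full morphology;
#'   default `0.5 * stride_mean`.
#' @param sample_rate sampling rate, Hz; default 100.
#' @param seed integer seed; all simulator randomness flows through it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_strides = 20, stride_mean = 1.2,
                            stride_sd = 0.05, oto_phase = 0.12,
                            oic_phase = 0.50, to_phase = 0.62,
                            asymmetry_shift = 0, gyro_amp = 2.0,
                            accz_amp = 1.5, impact_amp_ic = 3.0,
                            impact_amp_oic = 1.0, impact_width = 0.03,
                            noise_sd_acc = 0, noise_sd_gyro = 0,
                            noise_frac = NULL, lead_in = NULL,
                            sample_rate = 100, seed = 1L) {
  oic_eff <- oic_phase + asymmetry_shift
  if (!(0 < oto_phase && oto_phase < oic_eff && oic_eff < to_phase &&
        to_phase < 1))
    stop("need 0 < oto_phase < oic_phase + asymmetry_shift < to_phase < 1")
  if (stride_mean <= 0 || stride_sd < 0) stop("invalid stride parameters")
  if (n_strides < 1) stop("n_strides must be >= 1")
  if (any(c(gyro_amp, accz_amp, impact_amp_ic, impact_amp_oic) < 0))
    stop("amplitudes must be >= 0")
  if (impact_width <= 0) stop("impact_width must be positive")
  if (sample_rate <= 6) stop("sample_rate must exceed 6 Hz")
  structure(list(
    n_strides = as.integer(n_strides), stride_mean = stride_mean,
    stride_sd = stride_sd, oto_phase = oto_phase, oic_phase = oic_phase,
    to_phase = to_phase, asymmetry_shift = asymmetry_shift,
    gyro_amp = gyro_amp, accz_amp = accz_amp,
    impact_amp_ic = impact_amp_ic, impact_amp_oic = impact_amp_oic,
    impact_width = impact_width, noise_sd_acc = noise_sd_acc,
    noise_sd_gyro = noise_sd_gyro, noise_frac = noise_frac,
    lead_in = lead_in %||% 0.5 * stride_mean,
    sample_rate = sample_rate, seed = as.integer(seed)),
    class = "simulation_spec")
}

## stride durations + event times; consumes the current RNG stream
timeline_impl <- function(spec) {
  n <- spec$n_strides
  d <- stats::rnorm(n, spec$stride_mean, spec$stride_sd)
  for (rep in 1:100) {
    short <- d < 0.5 * spec$stride_mean
    if (!any(short)) break
    d[short] <- stats::rnorm(sum(short), spec$stride_mean, spec$stride_sd)
  }
  d <- pmax(d, 0.5 * spec$stride_mean)
  ics <- cumsum(c(0, d))
  structure(
    ground_truth(ic = ics,
                 oto = ics[seq_len(n)] + spec$oto_phase * d,
                 oic = ics[seq_len(n)] +
                   (spec$oic_phase + spec$asymmetry_shift) * d,
                 to = ics[seq_len(n)] + spec$to_phase * d,
                 source = "simulator"),
    strides = d)
}

#' Generate a ground-truth stride timeline
#'
#' Stride durations are drawn from a truncated normal (at least half the
#' mean stride), seeded by `spec$seed`; initial contacts are their
#' cumulative sums starting at time 0 and the other events sit at the
#' configured phases within each stride.
#'
#' @param spec a [simulation_spec()].
#' @return A [ground_truth()] object (attribute `"strides"` holds the
#'   stride durations).
#' @export
generate_timeline <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, timeline_impl(spec))
}

## shift all event times of a ground truth by dt
shift_truth <- function(truth, dt) {
  out <- truth
  for (k in c("ic", "oto", "oic", "to")) out[[k]] <- out[[k]] + dt
  out
}

## stride boundaries extended by one virtual stride (duration
## stride_mean) on each side, so edge strides keep full morphology
extended_strides <- function(truth, spec) {
  ics <- truth$ic
  d <- attr(truth, "strides") %||% diff(ics)
  n <- length(d)
  list(starts = c(ics[1] - spec$stride_mean, ics[seq_len(n)], ics[n + 1]),
       durations = c(spec$stride_mean, d, spec$stride_mean))
}

## cubic Hermite evaluation on nodes x (ascending) with values y and
## slopes m; end segments extend beyond the node range
hermite_interp <- function(x, y, m, xout) {
  j <- pmin(pmax(findInterval(xout, x), 1L), length(x) - 1L)
  h <- x[j + 1] - x[j]
  s <- (xout - x[j]) / h
  (1 + 2 * s) * (1 - s)^2 * y[j] + s * (1 - s)^2 * h * m[j] +
    s^2 * (3 - 2 * s) * y[j + 1] + s^2 * (s - 1) * h * m[j + 1]
}

#' Synthesise the pitch angular-velocity waveform
#'
#' Piecewise-cubic Hermite interpolation through per-stride anchors:
#' `+gyro_amp` at the opposite-toe-off phase, a descending zero at the
#' opposite-initial-contact phase, `-0.9 * gyro_amp` at the toe-off
#' phase (the stride minimum), and an ascending zero at mid swing,
#' continuing to the next opposite-toe-off peak.  Extremum anchors get
#' slope 0 and zero-crossing anchors a monotonicity-limited secant mean,
#' so in the noiseless case each stride has a unique sub-threshold local
#' minimum exactly at toe off, a unique descending zero crossing at
#' opposite initial contact and a unique local maximum at opposite toe
#' off.
#'
#' @param timeline a [ground_truth()] covering `t_grid`.
#' @param spec the [simulation_spec()].
#' @param t_grid time grid in seconds.
#' @param noise_sd additive Gaussian noise SD (drawn from the current
#'   RNG state), rad/s.
#' @return Pitch angular-velocity series on `t_grid`.
#' @export
synthesize_gyro <- function(timeline, spec, t_grid, noise_sd = 0) {
  ext <- extended_strides(timeline, spec)
  A <- spec$gyro_amp
  ta <- va <- numeric(0)
  extremum <- logical(0)
  ns <- length(ext$durations)
  for (j in seq_len(ns)) {
    s <- ext$starts[j]
    d <- ext$durations[j]
    nxt <- if (j < ns) ext$starts[j + 1] else s + d
    to_t <- s + spec$to_phase * d
    ta <- c(ta, s + spec$oto_phase * d,
            s + (spec$oic_phase + spec$asymmetry_shift) * d,
            to_t, (to_t + nxt) / 2)
    va <- c(va, A, 0, -0.9 * A, 0)
    extremum <- c(extremum, TRUE, FALSE, TRUE, FALSE)
  }
  ## flat zero tails outside the virtual strides
  ta <- c(ext$starts[1] - spec$stride_mean, ta,
          ext$starts[ns] + ext$durations[ns] + spec$stride_mean)
  va <- c(0, va, 0)
  extremum <- c(TRUE, extremum, TRUE)
  g <- if (A == 0) rep(0, length(t_grid)) else {
    sec <- diff(va) / diff(ta)
    m <- numeric(length(ta))
    for (i in seq_along(ta)) {
      if (extremum[i]) next
      s1 <- sec[i - 1]
      s2 <- sec[i]
      ## crossing nodes take the steeper adjacent secant (clamped for
      ## monotonicity): the waveform is then locally odd around the
      ## zero, so the 3 Hz low-pass does not displace the crossing
      m[i] <- if (s1 * s2 <= 0) 0 else
        sign(s1) * min(max(abs(s1), abs(s2)), 3 * min(abs(s1), abs(s2)))
    }
    hermite_interp(ta, va, m, t_grid)
  }
  if (noise_sd > 0) g <- g + stats::rnorm(length(t_grid), 0, noise_sd)
  g
}

## local stride phase in [0, 1) on the extended stride sequence
local_phase <- function(t_grid, ext) {
  bounds <- c(ext$starts, ext$starts[length(ext$starts)] +
                ext$durations[length(ext$durations)])
  j <- pmin(pmax(findInterval(t_grid, bounds), 1L), length(ext$durations))
  (t_grid - ext$starts[j]) / ext$durations[j]
}

gauss_pulses <- function(t_grid, centres, amp, sigma) {
  out <- numeric(length(t_grid))
  if (amp <= 0) return(out)
  for (tc in centres) out <- out + amp * exp(-(t_grid - tc)^2 / (2 * sigma^2))
  out
}

#' Synthesise the acceleration waveforms
#'
#' The vertical acceleration is `accz_amp * cos(4 * pi * phase)` - two
#' oscillations per stride, so its band-passed minima bracket each
#' initial contact - plus Gaussian impact pulses at each initial contact
#' and smaller ones at each opposite initial contact.  The
#' anterior-posterior acceleration carries the initial-contact pulses on
#' a `0.3 * accz_amp * sin(2 * pi * phase)` baseline.
#'
#' @inheritParams synthesize_gyro
#' @param noise_sd additive Gaussian noise SD, m/s^2.
#' @return List with elements `acc_ap` and `acc_v`.
#' @export
synthesize_acc <- function(timeline, spec, t_grid, noise_sd = 0) {
  ext <- extended_strides(timeline, spec)
  ph <- local_phase(t_grid, ext)
  sigma <- spec$impact_width / 2
  acc_v <- spec$accz_amp * cos(4 * pi * ph) +
    gauss_pulses(t_grid, timeline$ic, spec$impact_amp_ic, sigma) +
    gauss_pulses(t_grid, timeline$oic, spec$impact_amp_oic, sigma)
  acc_ap <- 0.3 * spec$accz_amp * sin(2 * pi * ph) +
    gauss_pulses(t_grid, timeline$ic, spec$impact_amp_ic, sigma)
  if (noise_sd > 0) {
    acc_ap <- acc_ap + stats::rnorm(length(t_grid), 0, noise_sd)
    acc_v <- acc_v + stats::rnorm(length(t_grid), 0, noise_sd)
  }
  list(acc_ap = acc_ap, acc_v = acc_v)
}

#' Simulate a full thigh-IMU gait recording with ground truth
#'
#' Draws the stride timeline, synthesises all six axes (the unused
#' medial-lateral acceleration and roll/yaw rates are noise only), adds
#' seeded Gaussian noise and returns the recording together with the
#' exact event times.  The recording starts `lead_in` seconds before the
#' first initial contact and ends `lead_in` seconds after the last, so
#' edge strides keep full morphology; the ground-truth times are on the
#' recording's clock.  Identical spec (including seed) gives
#' bit-identical output.
#'
#' @param spec a [simulation_spec()].
#' @return A `gait_simulation` list: `recording` ([imu_recording()]),
#'   `truth` ([ground_truth()]), `spec`, `noise_sd` (the realised SDs).
#' @examples
#' sim <- simulate_gait(simulation_spec(n_strides = 6, seed = 7))
#' sim$recording
#' @export
simulate_gait <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    truth <- shift_truth(timeline_impl(spec), spec$lead_in)
    attr(truth, "strides") <- diff(truth$ic)
    fs <- spec$sample_rate
    total <- truth$ic[length(truth$ic)] + spec$lead_in
    t_grid <- seq(0, by = 1 / fs, length.out = floor(total * fs) + 1)
    gyro0 <- synthesize_gyro(truth, spec, t_grid)
    acc0 <- synthesize_acc(truth, spec, t_grid)
    rms <- function(x) sqrt(mean(x^2))
    sd_acc <- if (!is.null(spec$noise_frac))
      spec$noise_frac * rms(acc0$acc_v) else spec$noise_sd_acc
    sd_gyro <- if (!is.null(spec$noise_frac))
      spec$noise_frac * rms(gyro0) else spec$noise_sd_gyro
    nse <- function(sd) if (sd > 0)
      stats::rnorm(length(t_grid), 0, sd) else numeric(length(t_grid))
    rec <- imu_recording(
      acc_ap = acc0$acc_ap + nse(sd_acc),
      acc_ml = nse(sd_acc),
      acc_v = acc0$acc_v + nse(sd_acc),
      gyro_roll = nse(sd_gyro),
      gyro_pitch = gyro0 + nse(sd_gyro),
      gyro_yaw = nse(sd_gyro),
      sample_rate = fs, side = "right")
    structure(list(recording = rec, truth = truth, spec = spec,
                   noise_sd = c(acc = sd_acc, gyro = sd_gyro)),
              class = "gait_simulation")
  })
}

#' @export
print.gait_simulation <- function(x, ...) {
  cat(sprintf(
    "<gait_simulation> %d strides @ %g Hz, stride %.3g +/- %.3g s, seed %d\n",
    x$spec$n_strides, x$spec$sample_rate, x$spec$stride_mean,
    x$spec$stride_sd, x$spec$seed))
  invisible(x)
}
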