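#' Estimate the dominant (main) frequency of an acceleration series
#'
#' The main frequency is the location of the largest magnitude in the
#' spectrum of the mean-removed series, searched within `search_band` and
#' refined by parabolic interpolation around the peak bin.  The series is
#' zero-padded so the bin width is at most 0.05 Hz.  For the vertical
#' acceleration of walking this is the step frequency, i.e. two per
#' stride.  The estimate is deterministic and invariant to scaling and to
#' a DC offset of the input.
#'
#' @param series numeric series (typically vertical acceleration, m/s^2).
#' @param sample_rate sampling rate, Hz.
#' @param search_band length-2 numeric, Hz; the peak is searched inside
#'   this band, default `c(0.5, 3)` covering usual step frequencies.
#' @return Peak frequency in Hz.
#' @examples
#' fs <- 100
#' t <- (0:2999) / fs
#' estimate_main_frequency(2 + sin(2 * pi * 1.6 * t), fs)
#' @export
estimate_main_frequency <- function(series, sample_rate,
                                    search_band = c(0.5, 3.0)) {
  if (!all(is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  if (n < 4 * sample_rate)
    stop("need at least 4 seconds of data to estimate the main frequency")
  nyq <- sample_rate / 2
  if (length(search_band) != 2L || search_band[1] <= 0 ||
      search_band[2] >= nyq || search_band[1] >= search_band[2])
    stop("search_band must lie within (0, Nyquist)")
  x <- series - mean(series)
  nfft <- 2^ceiling(log2(max(n, sample_rate / 0.05)))
  mag <- Mod(stats::fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2 + 1)]
  freq <- (seq_along(mag) - 1) * sample_rate / nfft
  inband <- which(freq >= search_band[1] & freq <= search_band[2])
  if (!length(inband) || all(mag[inband] <= 0) ||
      !any(is.finite(mag[inband])))
    stop("no spectral peak in the search band (degenerate input)")
  k <- inband[which.max(mag[inband])]
  ## parabolic refinement on the magnitude of the peak bin and neighbours
  delta <- 0
  if (k > 1 && k < length(mag)) {
    den <- mag[k - 1] - 2 * mag[k] + mag[k + 1]
    if (den < 0) delta <- 0.5 * (mag[k - 1] - mag[k + 1]) / den
  }
  (k - 1 + delta) * sample_rate / nfft
}

#' Band-pass the vertical acceleration around the main frequency
#'
#' Second-order Butterworth band-pass with passband
#' `main_freq +/- half_width`, applied zero-phase (forward-backward) by
#' default so event timings are not biased by filter delay.  Zero-phase
#' application squares the magnitude response, so the effective
#' attenuation is doubled relative to a single pass.
#'
#' @param acc_v vertical acceleration series, m/s^2.
#' @param sample_rate sampling rate, Hz.
#' @param main_freq centre of the passband, Hz (typically from
#'   [estimate_main_frequency()]).
#' @param half_width half the passband width, Hz; default 0.5.
#' @param causal if `TRUE` use a single forward pass instead of
#'   zero-phase filtering (for on-line use; shifts events by the group
#'   delay).
#' @return Filtered series, same length as the input, approximately zero
#'   mean.
#' @export
bandpass_az <- function(acc_v, sample_rate, main_freq, half_width = 0.5,
                        causal = FALSE) {
  lo <- main_freq - half_width
  hi <- main_freq + half_width
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi >= sample_rate / 2)
    stop("band edges must satisfy 0 < main_freq - half_width and ",
         "main_freq + half_width < Nyquist")
  f <- butter_design(2, sample_rate, low = lo, high = hi, type = "bandpass")
  if (causal) lfilter(f$b, f$a, acc_v, lfilter_zi(f$b, f$a) * acc_v[1])
  else filtfilt(f$b, f$a, acc_v)
}

#' Low-pass the pitch angular velocity
#'
#' Second-order Butterworth low-pass (default cutoff 3 Hz), zero-phase by
#' default.  Used to obtain the smoothed pitch rate whose descending zero
#' crossing marks opposite initial contact.
#'
#' @param gyro_pitch pitch angular-velocity series, rad/s.
#' @param sample_rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz; default 3.
#' @param causal single forward pass if `TRUE`; default zero-phase.
#' @return Filtered series, same length as the input.
#' @export
lowpass_gyro <- function(gyro_pitch, sample_rate, cutoff = 3.0,
                         causal = FALSE) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must lie in (0, Nyquist)")
  f <- butter_design(2, sample_rate, high = cutoff, type = "low")
  if (causal) lfilter(f$b, f$a, gyro_pitch,
                      lfilter_zi(f$b, f$a) * gyro_pitch[1])
  else filtfilt(f$b, f$a, gyro_pitch)
}

#' Assemble the feature signals used by the event detector
#'
#' Produces the three raw feature signals and their two filtered
#' derivatives: the anterior-posterior and vertical accelerations are
#' mean-centred (gravity / baseline removal for level walking, so the
#' configured thresholds are relative to the gravity-removed baseline),
#' the vertical acceleration is band-passed around the main frequency,
#' and the pitch angular velocity is low-passed.  When
#' `config$main_freq == "auto"` the main frequency is estimated from the
#' vertical acceleration; a numeric value fixes the passband instead.
#'
#' @param recording an [imu_recording()].
#' @param config a [detection_config()]; only the filter-related fields
#'   are used here.
#' @return An object of class `gait_features` with elements `acc_x`,
#'   `acc_z`, `gyro_y` (centred / raw sources), `az_bp`, `gy_lp3`,
#'   `main_freq` and `sample_rate`.
#' @export
compute_features <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "imu_recording"),
            inherits(config, "detection_config"))
  fs <- recording$sample_rate
  acc_x <- recording$acc_ap - mean(recording$acc_ap)
  acc_z <- recording$acc_v - mean(recording$acc_v)
  gyro_y <- recording$gyro_pitch
  main_freq <- if (identical(config$main_freq, "auto")) {
    estimate_main_frequency(acc_z, fs)
  } else {
    as.numeric(config$main_freq)
  }
  structure(list(
    acc_x = acc_x,
    acc_z = acc_z,
    gyro_y = gyro_y,
    az_bp = bandpass_az(acc_z, fs, main_freq,
                        half_width = config$bandpass_half_width,
                        causal = config$causal),
    gy_lp3 = lowpass_gyro(gyro_y, fs, cutoff = config$lowpass_cutoff,
                          causal = config$causal),
    main_freq = main_freq,
    sample_rate = fs), class = "gait_features")
}

#' @export
print.gait_features <- function(x, ...) {
  cat(sprintf(
    "<gait_features> %d samples @ %g Hz, main frequency %.3f Hz\n",
    length(x$acc_z), x$sample_rate, x$main_freq))
  invisible(x)
}
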