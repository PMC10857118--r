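#' Construct a thigh IMU recording
#'
#' Container for a uniformly sampled 6-axis inertial trace.  Axis
#' convention (sensor on the thigh): X = anterior-posterior, Y =
#' medial-lateral, Z = vertical; the pitch angular velocity is the
#' rotation about Y, positive for thigh flexion.  All series are stored in
#' internal units, m/s^2 and rad/s; [read_imu_csv()] converts from g or
#' deg/s at load time and negates the pitch rate for a left-side sensor so
#' one detector serves both legs.  The time base is implicit:
#' `time = (sample - 1) / sample_rate`.
#'
#' @param acc_ap,acc_ml,acc_v acceleration series, m/s^2
#'   (anterior-posterior / medial-lateral / vertical).
#' @param gyro_roll,gyro_pitch,gyro_yaw angular-velocity series, rad/s.
#' @param sample_rate sampling rate in Hz; must exceed 6 Hz so the 3 Hz
#'   low-pass cutoff stays below Nyquist.
#' @param side `"right"` or `"left"`; metadata only, the sign flip for a
#'   left sensor is applied by the reader.
#' @param units_declared optional list recording the source units.
#' @return An object of class `imu_recording`.
#' @seealso [read_imu_csv()], [simulate_gait()], [detect_events()]
#' @export
imu_recording <- function(acc_ap, acc_ml, acc_v,
                          gyro_roll, gyro_pitch, gyro_yaw,
                          sample_rate, side = c("right", "left"),
                          units_declared = list(acc = "m_s2", gyro = "rad_s")) {
  side <- match.arg(side)
  series <- list(acc_ap = acc_ap, acc_ml = acc_ml, acc_v = acc_v,
                 gyro_roll = gyro_roll, gyro_pitch = gyro_pitch,
                 gyro_yaw = gyro_yaw)
  n <- unique(lengths(series))
  if (length(n) != 1L)
    stop("all six series must have the same length")
  if (n < 2L)
    stop("recording must contain at least 2 samples")
  bad <- !vapply(series, function(s) all(is.finite(s)), logical(1))
  if (any(bad))
    stop("non-finite values in: ", paste(names(series)[bad], collapse = ", "))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 6)
    stop("sample_rate must be a single value > 6 Hz")
  structure(
    c(lapply(series, as.numeric),
      list(sample_rate = as.numeric(sample_rate), n_samples = as.integer(n),
           side = side, units_declared = units_declared)),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s), side = %s\n",
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate,
              x$side))
  invisible(x)
}

#' @export
as.data.frame.imu_recording <- function(x, ...) {
  data.frame(t = (seq_len(x$n_samples) - 1) / x$sample_rate,
             acc_x = x$acc_ap, acc_y = x$acc_ml, acc_z = x$acc_v,
             gyro_x = x$gyro_roll, gyro_y = x$gyro_pitch,
             gyro_z = x$gyro_yaw)
}
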