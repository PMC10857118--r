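#' Detection configuration
#'
#' Thresholds and filter settings for the event detector.  The three
#' thresholds carry physical units (internal units: m/s^2 and rad/s) and
#' are relative to the gravity-removed baseline of the acceleration
#' signals; the delay and peak-separation settings are fractions of the
#' estimated gait-cycle duration so they adapt to cadence.  Shipped
#' defaults are uncalibrated smoke-test values; the documented workflow is
#' [calibrate_thresholds()] then [detect_events()].
#'
#' @param th_to_gyro toe-off threshold on the raw pitch rate, rad/s;
#'   must be negative (toe off is a sub-threshold local minimum).
#' @param th_acc_x initial-contact gate on the anterior-posterior
#'   acceleration, m/s^2; positive.
#' @param th_acc_z initial-contact peak threshold on the vertical
#'   acceleration, m/s^2; positive.
#' @param oto_delay delay before the opposite-toe-off search starts,
#'   as a fraction of the cycle duration, in (0, 0.5).
#' @param min_peak_separation minimum separation between retained
#'   extrema, as a fraction of the cycle duration, in (0, 0.5).
#' @param main_freq `"auto"` (estimate from the vertical acceleration)
#'   or a fixed frequency in Hz.
#' @param bandpass_half_width half-width of the adaptive band-pass, Hz.
#' @param lowpass_cutoff cutoff of the pitch-rate low-pass, Hz.
#' @param causal use causal (single-pass) filters; default zero-phase.
#' @param sample_rate optional sampling rate, Hz; only needed when a
#'   file is read without a time column.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(th_to_gyro = -0.5,
                             th_acc_x = 1.5,
                             th_acc_z = 3.0,
                             oto_delay = 0.05,
                             min_peak_separation = 0.25,
                             main_freq = "auto",
                             bandpass_half_width = 0.5,
                             lowpass_cutoff = 3.0,
                             causal = FALSE,
                             sample_rate = NULL) {
  if (!is.numeric(th_to_gyro) || th_to_gyro >= 0)
    stop("th_to_gyro must be negative (rad/s)")
  if (th_acc_x <= 0 || th_acc_z <= 0)
    stop("th_acc_x and th_acc_z must be positive (m/s^2)")
  if (oto_delay <= 0 || oto_delay >= 0.5)
    stop("oto_delay must be in (0, 0.5)")
  if (min_peak_separation <= 0 || min_peak_separation >= 0.5)
    stop("min_peak_separation must be in (0, 0.5)")
  if (!identical(main_freq, "auto") &&
      (!is.numeric(main_freq) || main_freq <= 0))
    stop("main_freq must be \"auto\" or a positive frequency in Hz")
  structure(list(th_to_gyro = th_to_gyro, th_acc_x = th_acc_x,
                 th_acc_z = th_acc_z, oto_delay = oto_delay,
                 min_peak_separation = min_peak_separation,
                 main_freq = main_freq,
                 bandpass_half_width = bandpass_half_width,
                 lowpass_cutoff = lowpass_cutoff, causal = causal,
                 sample_rate = sample_rate),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  cat(sprintf("  th_to_gyro = %g rad/s, th_acc_x = %g m/s^2, th_acc_z = %g m/s^2\n",
              x$th_to_gyro, x$th_acc_x, x$th_acc_z))
  cat(sprintf("  oto_delay = %g, min_peak_separation = %g (cycle fractions)\n",
              x$oto_delay, x$min_peak_separation))
  cat(sprintf("  main_freq = %s, band +/- %g Hz, low-pass %g Hz, %s\n",
              if (identical(x$main_freq, "auto")) "auto"
              else sprintf("%g Hz", x$main_freq),
              x$bandpass_half_width, x$lowpass_cutoff,
              if (x$causal) "causal" else "zero-phase"))
  invisible(x)
}

## keep the more extreme of any two candidates closer than min_separation;
## ties broken toward the earlier index
prune_by_separation <- function(idx, values, min_separation, mode) {
  if (length(idx) <= 1L || min_separation <= 1) return(sort(idx))
  ord <- order(if (mode == "max") -values else values, idx)
  taken <- integer(0)
  keep <- logical(length(idx))
  for (j in ord) {
    if (!length(taken) || all(abs(idx[j] - taken) >= min_separation)) {
      keep[j] <- TRUE
      taken <- c(taken, idx[j])
    }
  }
  sort(idx[keep])
}

#' Find local extrema of a series
#'
#' Strict local extrema (greater / smaller than both neighbours); a
#' plateau counts once, at its first sample.  Among extrema closer than
#' `min_separation` samples only the most extreme survives (ties go to
#' the earlier index).
#'
#' @param series numeric series.
#' @param mode `"min"` or `"max"`.
#' @param min_separation minimum distance between retained extrema,
#'   samples; `1` disables pruning.
#' @return Ascending integer sample indices (1-based).
#' @export
find_local_extrema <- function(series, mode = c("min", "max"),
                               min_separation = 1L) {
  mode <- match.arg(mode)
  stopifnot(min_separation >= 1)
  if (length(series) < 3L) return(integer(0))
  r <- rle(as.numeric(series))
  v <- r$values
  m <- length(v)
  if (m < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths))[seq_len(m)]
  core <- 2:(m - 1)
  sel <- if (mode == "max") {
    v[core] > v[core - 1] & v[core] > v[core + 1]
  } else {
    v[core] < v[core - 1] & v[core] < v[core + 1]
  }
  idx <- starts[core][sel]
  prune_by_separation(idx, series[idx], min_separation, mode)
}

#' Detect toe-off candidates
#'
#' Toe off shows as a deep local minimum of the raw pitch angular
#' velocity: local minima with value below the (negative) threshold,
#' de-duplicated by `min_separation`.
#'
#' @param gyro_y raw pitch angular velocity, rad/s.
#' @param th_to_gyro negative threshold, rad/s.
#' @param min_separation minimum sample distance between retained minima.
#' @return Ascending sample indices of toe-off candidates.
#' @export
detect_to <- function(gyro_y, th_to_gyro, min_separation = 1L) {
  if (th_to_gyro >= 0) stop("th_to_gyro must be negative")
  mins <- find_local_extrema(gyro_y, "min", 1L)
  mins <- mins[gyro_y[mins] < th_to_gyro]
  prune_by_separation(mins, gyro_y[mins], min_separation, "min")
}

#' Initial-contact detection windows
#'
#' Consecutive pairs of local minima of the band-passed vertical
#' acceleration define half-open windows `[start, end)`; with two
#' band-passed oscillations per stride, every initial contact falls
#' strictly inside one window.
#'
#' @param az_bp band-passed vertical acceleration (from [bandpass_az()]).
#' @param min_separation minimum sample distance between the minima.
#' @return Integer matrix with columns `start`, `end` (1-based, half
#'   open); zero rows when fewer than two minima exist.
#' @export
ic_windows <- function(az_bp, min_separation = 1L) {
  mins <- find_local_extrema(az_bp, "min", min_separation)
  if (length(mins) < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = mins[-length(mins)], end = mins[-1])
}

## local maxima of x inside [start, end), with neighbours taken from the
## full series where available
window_maxima <- function(x, start, end) {
  lo <- max(1L, start - 1L)
  hi <- min(length(x), end)
  if (hi - lo < 2L) return(integer(0))
  pk <- find_local_extrema(x[lo:hi], "max", 1L) + lo - 1L
  pk[pk >= start & pk < end]
}

#' Detect initial contact within a window
#'
#' Two-branch impact-peak rule.  Branch A: if any anterior-posterior
#' acceleration sample in the window exceeds `th_acc_x`, initial contact
#' is the earliest supra-threshold local maximum of the vertical
#' acceleration at or after that first gating sample.  Branch B
#' (otherwise): the largest supra-threshold vertical-acceleration local
#' maximum in the window.  Absent (`NA`) when no qualifying peak exists;
#' the branch used is attached as attribute `"branch"` for audit.
#'
#' @param acc_x anterior-posterior acceleration (baseline-removed), m/s^2.
#' @param acc_z vertical acceleration (baseline-removed), m/s^2.
#' @param window length-2 integer `[start, end)` window.
#' @param th_acc_x,th_acc_z positive thresholds, m/s^2.
#' @return Sample index of the initial contact, or `NA_integer_`.
#' @export
detect_ic <- function(acc_x, acc_z, window, th_acc_x, th_acc_z) {
  start <- window[[1]]
  end <- window[[2]]
  if (end <= start) stop("window must be non-empty")
  pk <- window_maxima(acc_z, start, end)
  pk <- pk[acc_z[pk] > th_acc_z]
  win <- start:(end - 1L)
  gate <- win[acc_x[win] > th_acc_x][1]
  if (!is.na(gate)) {
    cand <- pk[pk >= gate]
    if (!length(cand)) return(structure(NA_integer_, branch = "A"))
    return(structure(cand[1], branch = "A"))
  }
  if (!length(pk)) return(structure(NA_integer_, branch = "B"))
  structure(pk[which.max(acc_z[pk])], branch = "B")
}

#' Detect opposite toe off
#'
#' First local maximum of the raw pitch angular velocity in
#' `[ic_index + delay, search_end)`.  With noisy data small maxima on the
#' rising limb can precede the true peak, so candidates are optionally
#' pruned by `min_separation` (keeping the more extreme) before the
#' first-peak rule is applied.
#'
#' @param gyro_y raw pitch angular velocity, rad/s.
#' @param ic_index sample index of the initial contact.
#' @param delay samples to skip after initial contact.
#' @param search_end exclusive end of the search range (typically the
#'   next detected toe off).
#' @param min_separation pruning distance in samples; `1` disables it.
#' @return Sample index or `NA_integer_`.
#' @export
detect_oto <- function(gyro_y, ic_index, delay, search_end,
                       min_separation = 1L) {
  from <- ic_index + delay
  if (from >= search_end) stop("ic_index + delay must precede search_end")
  pk <- window_maxima(gyro_y, from, search_end)
  pk <- prune_by_separation(pk, gyro_y[pk], min_separation, "max")
  if (!length(pk)) NA_integer_ else pk[1]
}

#' Detect opposite initial contact
#'
#' First descending zero crossing of the low-passed pitch angular
#' velocity after opposite toe off: the first index `i` with
#' `gy_lp3[i - 1] > 0 >= gy_lp3[i]` (an exact-zero sample is attributed
#' to the crossing).
#'
#' @param gy_lp3 low-passed pitch angular velocity, rad/s.
#' @param oto_index sample index of the opposite toe off.
#' @param search_end exclusive end of the search range.
#' @return Sample index or `NA_integer_`.
#' @export
detect_oic <- function(gy_lp3, oto_index, search_end) {
  if (oto_index >= search_end) stop("oto_index must precede search_end")
  last <- min(search_end - 1L, length(gy_lp3))
  if (last <= oto_index) return(NA_integer_)
  i <- (oto_index + 1L):last
  hit <- which(gy_lp3[i - 1L] > 0 & gy_lp3[i] <= 0)
  if (!length(hit)) NA_integer_ else i[hit[1]]
}

#' Detect gait events and assemble gait cycles
#'
#' Full detection pipeline: compute the feature signals, bootstrap the
#' cycle duration as `2 / main_freq`, find toe-off candidates and
#' initial-contact windows, then assemble cycles IC -> OTO -> OIC -> TO
#' between consecutive initial contacts.  The opposite-toe-off and
#' opposite-initial-contact searches are bounded by the cycle's detected
#' toe off; the delay and separation settings are rescaled per cycle from
#' the actual IC-to-IC interval.  A cycle missing any event or violating
#' the strict ordering IC < OTO < OIC < TO < next IC is returned with
#' `valid = FALSE`; the first and last cycles are flagged `edge` (filter
#' edge effects) and excluded from parameter statistics by default.
#'
#' @param recording an [imu_recording()] at least 3 estimated strides
#'   long.
#' @param config a [detection_config()].
#' @param features optional precomputed [compute_features()] result
#'   (reused by the calibration grid search).
#' @return A `gait_cycles` data frame with one row per cycle: sample
#'   indices and times of the four events and the next initial contact,
#'   the IC branch used, and `valid` / `edge` flags.  Attributes carry
#'   `sample_rate` and `main_freq`.
#' @export
detect_events <- function(recording, config = detection_config(),
                          features = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  features <- features %||% compute_features(recording, config)
  fs <- features$sample_rate
  cyc_samp <- 2 / features$main_freq * fs
  if (recording$n_samples < 3 * cyc_samp)
    stop("recording shorter than 3 estimated strides")
  sep <- max(1L, as.integer(round(config$min_peak_separation * cyc_samp)))
  to_all <- detect_to(features$gyro_y, config$th_to_gyro, sep)
  wins <- ic_windows(features$az_bp, sep)
  ics <- integer(0)
  branches <- character(0)
  for (w in seq_len(nrow(wins))) {
    r <- detect_ic(features$acc_x, features$acc_z, wins[w, ],
                   config$th_acc_x, config$th_acc_z)
    if (!is.na(r)) {
      ics <- c(ics, as.integer(r))
      branches <- c(branches, attr(r, "branch"))
    }
  }
  n_cyc <- max(0L, length(ics) - 1L)
  cyc <- data.frame(cycle = seq_len(n_cyc), ic = integer(n_cyc),
                    oto = rep(NA_integer_, n_cyc),
                    oic = rep(NA_integer_, n_cyc),
                    to = rep(NA_integer_, n_cyc),
                    next_ic = integer(n_cyc),
                    ic_branch = character(n_cyc),
                    valid = logical(n_cyc), edge = logical(n_cyc))
  for (k in seq_len(n_cyc)) {
    ic <- ics[k]
    nic <- ics[k + 1]
    t_samp <- nic - ic
    to_k <- to_all[to_all > ic][1]
    search_end <- if (is.na(to_k)) nic else to_k
    delay <- max(1L, as.integer(round(config$oto_delay * t_samp)))
    sep_k <- max(1L, as.integer(round(config$min_peak_separation * t_samp)))
    oto <- if (ic + delay < search_end) {
      detect_oto(features$gyro_y, ic, delay, search_end, sep_k)
    } else NA_integer_
    oic <- if (!is.na(oto) && oto < search_end) {
      detect_oic(features$gy_lp3, oto, search_end)
    } else NA_integer_
    cyc$ic[k] <- ic
    cyc$oto[k] <- oto
    cyc$oic[k] <- oic
    cyc$to[k] <- to_k
    cyc$next_ic[k] <- nic
    cyc$ic_branch[k] <- branches[k]
    cyc$valid[k] <- !anyNA(c(oto, oic, to_k)) &&
      ic < oto && oto < oic && oic < to_k && to_k < nic
  }
  if (n_cyc > 0) cyc$edge[c(1L, n_cyc)] <- TRUE
  for (col in c("ic", "oto", "oic", "to", "next_ic"))
    cyc[[paste0(col, "_time")]] <- (cyc[[col]] - 1) / fs
  structure(cyc, class = c("gait_cycles", "data.frame"),
            sample_rate = fs, main_freq = features$main_freq)
}

#' Long-format event table from detected cycles
#'
#' One row per event (`IC`, `OTO`, `OIC`, `TO`), ordered in time.  Each
#' cycle contributes its four events; the last cycle additionally
#' contributes its closing initial contact.  The `sample_index` column is
#' 0-based so that `time_s = sample_index / sample_rate`.
#'
#' @param cycles a `gait_cycles` object from [detect_events()].
#' @param only_valid drop events of invalid cycles.
#' @param include_edge keep events of edge cycles (default `TRUE`).
#' @return Data frame `cycle_index, event, sample_index, time_s, valid,
#'   edge`.
#' @export
events_long <- function(cycles, only_valid = FALSE, include_edge = TRUE) {
  stopifnot(inherits(cycles, "gait_cycles"))
  fs <- attr(cycles, "sample_rate")
  sel <- rep(TRUE, nrow(cycles))
  if (only_valid) sel <- sel & cycles$valid
  if (!include_edge) sel <- sel & !cycles$edge
  ks <- which(sel)
  idx <- c(cycles$ic[ks], cycles$oto[ks], cycles$oic[ks], cycles$to[ks])
  out <- data.frame(
    cycle_index = rep(ks, 4),
    event = rep(c("IC", "OTO", "OIC", "TO"), each = length(ks)),
    sample_index = idx - 1L,
    valid = rep(cycles$valid[ks], 4),
    edge = rep(cycles$edge[ks], 4))
  ## closing IC of the last selected cycle
  if (length(ks)) {
    k <- max(ks)
    out <- rbind(out, data.frame(
      cycle_index = k + 1L, event = "IC",
      sample_index = cycles$next_ic[k] - 1L,
      valid = cycles$valid[k], edge = TRUE))
  }
  out <- out[!is.na(out$sample_index), , drop = FALSE]
  out$time_s <- out$sample_index / fs
  out <- out[order(out$time_s, out$event),
             c("cycle_index", "event", "sample_index", "time_s",
               "valid", "edge")]
  rownames(out) <- NULL
  out
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf(
    "<gait_cycles> %d cycles (%d valid, %d interior) @ %g Hz, main freq %.3f Hz\n",
    nrow(x), sum(x$valid), sum(x$valid & !x$edge),
    attr(x, "sample_rate"), attr(x, "main_freq")))
  print(as.data.frame(x), ...)
  invisible(x)
}
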