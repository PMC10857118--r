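#' Default calibration grid
#'
#' Candidate values for the four calibratable settings: the toe-off
#' threshold on the pitch rate, the two initial-contact acceleration
#' thresholds and the opposite-toe-off delay (5 x 5 x 5 x 4 = 500 grid
#' points).  Ranges span the plausible physical scales; the delay range
#' follows the usual location of opposite toe off early in the cycle.
#'
#' @return Named list of numeric candidate vectors.
#' @export
default_calibration_grid <- function() {
  list(th_to_gyro = c(-1.5, -1.2, -0.9, -0.6, -0.3),
       th_acc_x = c(0.5, 1.0, 1.5, 2.0, 2.5),
       th_acc_z = c(1.0, 2.0, 3.0, 4.0, 5.0),
       oto_delay = c(0.03, 0.05, 0.08, 0.12))
}

#' Calibrate detection thresholds by grid search
#'
#' Exhaustively evaluates every grid point against reference events.
#' The objective is lexicographic: maximise the pooled event-matching F1
#' (all four kinds, all recordings) at the matching tolerance, then
#' minimise the mean absolute timing error of the matched events, then
#' prefer the point closest to the grid centre (range-normalised
#' Euclidean distance), then the lowest grid index - a fully
#' deterministic tie-break.  The result is invariant to the order of
#' the input recordings.
#'
#' @param recordings an [imu_recording()] or list of them.
#' @param references a [ground_truth()] or list of them, aligned with
#'   `recordings`.
#' @param grid named list of candidate vectors for `th_to_gyro`,
#'   `th_acc_x`, `th_acc_z`, `oto_delay`; see
#'   [default_calibration_grid()].
#' @param config base [detection_config()] supplying the non-searched
#'   settings.
#' @param tolerance event-matching tolerance in seconds, default 0.05
#'   (+/- 50 ms).
#' @return A `gait_calibration` list: `config` (winning
#'   [detection_config()]), `report` (per-point F1 and mean absolute
#'   error), `best` (row index of the winner).
#' @export
calibrate_thresholds <- function(recordings, references,
                                 grid = default_calibration_grid(),
                                 config = detection_config(),
                                 tolerance = 0.05) {
  if (inherits(recordings, "imu_recording")) recordings <- list(recordings)
  if (inherits(references, "ground_truth")) references <- list(references)
  if (!length(recordings) || length(recordings) != length(references))
    stop("need >= 1 recording with a matching reference")
  need <- c("th_to_gyro", "th_acc_x", "th_acc_z", "oto_delay")
  if (!all(need %in% names(grid)) || any(lengths(grid[need]) == 0))
    stop("grid must provide non-empty candidates for: ",
         paste(need, collapse = ", "))
  feats <- lapply(recordings, compute_features, config = config)
  pts <- expand.grid(grid[need], KEEP.OUT.ATTRS = FALSE)
  centre <- vapply(grid[need], function(v) (max(v) + min(v)) / 2, numeric(1))
  rng <- vapply(grid[need], function(v) max(max(v) - min(v), 1e-12),
                numeric(1))
  f1 <- mean_abs_ms <- centre_dist <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    cfg <- config
    for (nm in need) cfg[[nm]] <- pts[[nm]][p]
    tp <- fp <- fn <- 0L
    errs <- numeric(0)
    for (i in seq_along(recordings)) {
      det <- tryCatch(
        detect_events(recordings[[i]], cfg, features = feats[[i]]),
        error = function(e) NULL)
      ev <- if (is.null(det) || !nrow(det)) {
        data.frame(event = character(0), time_s = numeric(0))
      } else as_event_table(det)
      m <- match_events(ev, references[[i]], tolerance)
      tp <- tp + nrow(m$pairs)
      fp <- fp + nrow(m$spurious)
      fn <- fn + nrow(m$missed)
      errs <- c(errs, m$pairs$error_s)
    }
    f1[p] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    mean_abs_ms[p] <- if (length(errs)) mean(abs(errs)) * 1000 else Inf
    centre_dist[p] <- sqrt(sum(
      ((unlist(pts[p, need]) - centre) / rng)^2))
  }
  best <- order(-f1, mean_abs_ms, centre_dist, seq_len(nrow(pts)))[1]
  winner <- config
  for (nm in need) winner[[nm]] <- pts[[nm]][best]
  structure(list(
    config = winner,
    report = cbind(pts, f1 = f1, mean_abs_error_ms = mean_abs_ms,
                   centre_dist = centre_dist),
    best = best), class = "gait_calibration")
}

#' @export
print.gait_calibration <- function(x, ...) {
  b <- x$report[x$best, ]
  cat(sprintf(
    "<gait_calibration> %d grid points; winner F1 = %.3f, mean |error| = %.2f ms\n",
    nrow(x$report), b$f1, b$mean_abs_error_ms))
  print(x$config)
  invisible(x)
}
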