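EVENT_KINDS <- c("IC", "OTO", "OIC", "TO")

#' Reference (ground-truth) event times
#'
#' Ordered reference event times per kind, from force plates (consumed
#' as tables) or from the simulator.
#'
#' @param ic,oto,oic,to ascending event times in seconds.  For complete
#'   strides `ic` has one more element than the other three.
#' @param source `"force_plate"` or `"simulator"`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(ic, oto, oic, to,
                         source = c("simulator", "force_plate")) {
  source <- match.arg(source)
  lst <- list(ic = as.numeric(ic), oto = as.numeric(oto),
              oic = as.numeric(oic), to = as.numeric(to))
  for (k in names(lst)) {
    if (!all(is.finite(lst[[k]]))) stop("non-finite times in ", k)
    if (is.unsorted(lst[[k]], strictly = TRUE))
      stop(k, " times must be strictly ascending")
  }
  structure(c(lst, list(source = source)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> (%s) %d IC, %d OTO, %d OIC, %d TO\n",
              x$source, length(x$ic), length(x$oto), length(x$oic),
              length(x$to)))
  invisible(x)
}

## coerce detected cycles / ground truth / data frame to (event, time_s)
as_event_table <- function(x, ...) {
  if (inherits(x, "gait_cycles")) {
    e <- events_long(x, ...)
    return(data.frame(event = e$event, time_s = e$time_s))
  }
  if (inherits(x, "ground_truth")) {
    return(data.frame(
      event = rep(EVENT_KINDS, c(length(x$ic), length(x$oto),
                                 length(x$oic), length(x$to))),
      time_s = c(x$ic, x$oto, x$oic, x$to)))
  }
  stopifnot(is.data.frame(x), all(c("event", "time_s") %in% names(x)))
  data.frame(event = as.character(x$event), time_s = as.numeric(x$time_s))
}

#' Match detected events to reference events
#'
#' Greedy nearest-neighbour matching within each event kind: candidate
#' pairs with `|dt| <= tolerance` are taken in order of increasing
#' `|dt|`, each detected and each reference event used at most once.
#' Leftover detected events are spurious, leftover reference events
#' missed.
#'
#' @param detected a `gait_cycles` object, or a data frame with columns
#'   `event` and `time_s`.
#' @param reference a [ground_truth()] object or event data frame.
#' @param tolerance maximum pairing distance in seconds; default half
#'   the median reference cycle duration.
#' @return An `event_matching` list: `pairs` (`event, detected_time,
#'   reference_time, error_s`), `missed`, `spurious`, `tolerance`.
#' @export
match_events <- function(detected, reference, tolerance = NULL) {
  det <- as_event_table(detected)
  ref <- as_event_table(reference)
  if (is.null(tolerance)) {
    ics <- sort(ref$time_s[ref$event == "IC"])
    if (length(ics) < 2)
      stop("tolerance not given and reference has < 2 ICs to derive it")
    tolerance <- stats::median(diff(ics)) / 2
  }
  stopifnot(tolerance > 0)
  pairs <- missed <- spurious <- vector("list", length(EVENT_KINDS))
  names(pairs) <- EVENT_KINDS
  for (kind in EVENT_KINDS) {
    d <- sort(det$time_s[det$event == kind])
    r <- sort(ref$time_s[ref$event == kind])
    used_d <- logical(length(d))
    used_r <- logical(length(r))
    pi <- pk <- integer(0)
    if (length(d) && length(r)) {
      dt <- abs(outer(d, r, "-"))
      cand <- which(dt <= tolerance, arr.ind = TRUE)
      if (nrow(cand)) {
        for (j in order(dt[cand], cand[, 2], cand[, 1])) {
          i <- cand[j, 1]
          k <- cand[j, 2]
          if (!used_d[i] && !used_r[k]) {
            used_d[i] <- used_r[k] <- TRUE
            pi <- c(pi, i)
            pk <- c(pk, k)
          }
        }
      }
    }
    pairs[[kind]] <- data.frame(
      event = rep(kind, length(pi)), detected_time = d[pi],
      reference_time = r[pk], error_s = d[pi] - r[pk])
    missed[[kind]] <- data.frame(event = rep(kind, sum(!used_r)),
                                 time_s = r[!used_r])
    spurious[[kind]] <- data.frame(event = rep(kind, sum(!used_d)),
                                   time_s = d[!used_d])
  }
  structure(list(
    pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
    missed = do.call(rbind, c(missed, list(make.row.names = FALSE))),
    spurious = do.call(rbind, c(spurious, list(make.row.names = FALSE))),
    tolerance = tolerance), class = "event_matching")
}

#' @export
print.event_matching <- function(x, ...) {
  cat(sprintf(
    "<event_matching> %d matched, %d missed, %d spurious (tolerance %.3f s)\n",
    nrow(x$pairs), nrow(x$missed), nrow(x$spurious), x$tolerance))
  invisible(x)
}

#' Event timing errors and error rates
#'
#' For each matched pair computes the timing error in milliseconds,
#' `error_ms = (detected - reference) * 1000` (negative = early
#' detection), and the error rate as a percentage of the gait cycle,
#' `error_pct_gc = error_ms / cycle_ms * 100`, where the cycle duration
#' is the enclosing reference IC-to-IC interval.  Per kind the report
#' aggregates mean, SD and mean absolute value of both metrics, the
#' matched/missed/spurious counts, and flags outliers beyond 3 times the
#' interquartile range from the quartiles of `error_ms`.
#'
#' @param matching an [match_events()] result.
#' @param reference the [ground_truth()] used for matching (supplies the
#'   reference cycle durations).
#' @return An `event_error_report`: `pairs` (with `error_ms`,
#'   `error_pct_gc`, `cycle_s`, `outlier`) and `summary` (one row per
#'   kind).
#' @export
event_errors <- function(matching, reference) {
  stopifnot(inherits(matching, "event_matching"),
            inherits(reference, "ground_truth"))
  pairs <- matching$pairs
  ics <- reference$ic
  if (length(ics) < 2) stop("reference must contain at least 2 ICs")
  durs <- diff(ics)
  if (nrow(pairs)) {
    j <- findInterval(pairs$reference_time, ics)
    j <- pmin(pmax(j, 1L), length(durs))
    pairs$cycle_s <- durs[j]
    pairs$error_ms <- pairs$error_s * 1000
    pairs$error_pct_gc <- pairs$error_ms / (pairs$cycle_s * 1000) * 100
    pairs$outlier <- FALSE
    for (kind in unique(pairs$event)) {
      sel <- pairs$event == kind
      q <- stats::quantile(pairs$error_ms[sel], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      pairs$outlier[sel] <- pairs$error_ms[sel] < q[1] - 3 * iqr |
        pairs$error_ms[sel] > q[2] + 3 * iqr
    }
  }
  summ <- NULL
  for (kind in EVENT_KINDS) {
    sel <- if (nrow(pairs)) pairs$event == kind else logical(0)
    e_ms <- pairs$error_ms[sel]
    e_pc <- pairs$error_pct_gc[sel]
    summ <- rbind(summ, data.frame(
      event = kind,
      n_matched = sum(sel),
      n_missed = sum(matching$missed$event == kind),
      n_spurious = sum(matching$spurious$event == kind),
      mean_ms = if (length(e_ms)) mean(e_ms) else NA_real_,
      sd_ms = if (length(e_ms) > 1) stats::sd(e_ms) else
        if (length(e_ms) == 1) 0 else NA_real_,
      mean_abs_ms = if (length(e_ms)) mean(abs(e_ms)) else NA_real_,
      mean_pct_gc = if (length(e_pc)) mean(e_pc) else NA_real_,
      sd_pct_gc = if (length(e_pc) > 1) stats::sd(e_pc) else
        if (length(e_pc) == 1) 0 else NA_real_,
      mean_abs_pct_gc = if (length(e_pc)) mean(abs(e_pc)) else NA_real_,
      n_outliers = sum(pairs$outlier[sel])))
  }
  structure(list(pairs = pairs, summary = summ),
            class = "event_error_report")
}

#' @export
print.event_error_report <- function(x, ...) {
  cat("<event_error_report>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter errors: calculated minus measured
#'
#' Per-cycle differences between two aligned gait-parameter tables
#' (calculated from detected events vs measured from reference events),
#' reported per cycle and as mean +/- SD, in percent of gait cycle for
#' the percentage parameters.
#'
#' @param calculated,measured [gait_parameters()] tables aligned by
#'   cycle (same cycles, same order).
#' @return A `parameter_error_report`: `errors` (per cycle) and
#'   `summary` (`parameter, mean, sd, n`).
#' @export
parameter_errors <- function(calculated, measured) {
  stopifnot(is.data.frame(calculated), is.data.frame(measured))
  if (nrow(calculated) != nrow(measured))
    stop("tables are misaligned: different numbers of cycles")
  if ("cycle" %in% names(calculated) && "cycle" %in% names(measured) &&
      !identical(as.integer(calculated$cycle), as.integer(measured$cycle)))
    stop("tables are misaligned: cycle indices differ")
  cols <- intersect(
    c("stride_time", "cadence", "stance_pct", "swing_pct", "symmetry_pct",
      "dls_initial_pct", "sls_pct", "dls_terminal_pct", "dls_pct",
      "dls_total_pct"),
    intersect(names(calculated), names(measured)))
  if (!length(cols)) stop("no shared parameter columns")
  err <- as.data.frame(
    mapply(function(a, b) a - b, calculated[cols], measured[cols],
           SIMPLIFY = FALSE))
  if ("cycle" %in% names(calculated)) err <- cbind(cycle = calculated$cycle, err)
  summ <- data.frame(
    parameter = cols,
    mean = vapply(err[cols], mean, numeric(1)),
    sd = vapply(err[cols], function(v) if (length(v) < 2) 0 else
      stats::sd(v), numeric(1)),
    n = nrow(err), row.names = NULL)
  structure(list(errors = err, summary = summ),
            class = "parameter_error_report")
}

#' @export
print.parameter_error_report <- function(x, ...) {
  cat("<parameter_error_report> (calculated - measured)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert an error rate to sample frames
#'
#' An error rate of `rate_pct` percent of a gait cycle of duration
#' `cycle_s` seconds corresponds to
#' `rate_pct / 100 * cycle_s * sample_rate` frames.  For example 2% of a
#' 1.4 s cycle sampled at 100 Hz is 2.8 frames.
#'
#' @param rate_pct error rate, percent of gait cycle.
#' @param cycle_s cycle duration, seconds.
#' @param sample_rate sampling rate, Hz.
#' @return Error expressed in frames (samples).
#' @export
error_rate_frames <- function(rate_pct, cycle_s, sample_rate) {
  rate_pct / 100 * cycle_s * sample_rate
}
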