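#' Temporal gait parameters from event times
#'
#' Vectorised over cycles.  With `T = next_ic - ic` (stride time):
#' stance = (to - ic)/T, swing = 100 - stance, symmetry index =
#' (oic - ic)/T (50% for perfectly symmetric timing), initial double
#' limb support = (oto - ic)/T, single limb support = (oic - oto)/T,
#' terminal double limb support = (to - oic)/T, all as percentages of
#' the cycle.  The reported double-limb-support value is the mean of the
#' initial and terminal periods (so stance = SLS + 2 DLS exactly); the
#' total is also returned.  Cadence assumes one contralateral step per
#' stride: 120/T steps per minute.
#'
#' @param ic,oto,oic,to,next_ic event times in seconds (equal-length
#'   vectors).  Strict ordering `ic < oto < oic < to <= next_ic` is
#'   required; `to == next_ic` is a flagged boundary case (stance 100%),
#'   not an error.
#' @return Data frame with columns `stride_time`, `cadence`,
#'   `stance_pct`, `swing_pct`, `symmetry_pct`, `dls_initial_pct`,
#'   `sls_pct`, `dls_terminal_pct`, `dls_pct`, `dls_total_pct`,
#'   `boundary`.
#' @examples
#' cycle_parameters(0, 0.12, 0.50, 0.62, 1.00)
#' @export
cycle_parameters <- function(ic, oto, oic, to, next_ic) {
  len <- unique(c(length(ic), length(oto), length(oic), length(to),
                  length(next_ic)))
  if (length(len) != 1L) stop("event vectors must have equal length")
  if (!all(is.finite(c(ic, oto, oic, to, next_ic))))
    stop("event times must be finite (invalid cycle)")
  T <- next_ic - ic
  if (any(T <= 0)) stop("cycle duration must be positive")
  if (any(oto <= ic | oic <= oto | to <= oic | next_ic < to))
    stop("event ordering violated: need ic < oto < oic < to <= next_ic")
  stance <- (to - ic) / T * 100
  dls_i <- (oto - ic) / T * 100
  sls <- (oic - oto) / T * 100
  dls_t <- (to - oic) / T * 100
  data.frame(stride_time = T,
             cadence = 120 / T,
             stance_pct = stance,
             swing_pct = 100 - stance,
             symmetry_pct = (oic - ic) / T * 100,
             dls_initial_pct = dls_i,
             sls_pct = sls,
             dls_terminal_pct = dls_t,
             dls_pct = (dls_i + dls_t) / 2,
             dls_total_pct = dls_i + dls_t,
             boundary = to == next_ic)
}

#' Per-cycle gait parameters from detected cycles
#'
#' Applies [cycle_parameters()] to the valid cycles of a
#' [detect_events()] result.  Edge cycles (first/last, exposed to filter
#' edge effects) are excluded by default.
#'
#' @param cycles a `gait_cycles` object.
#' @param include_edge keep edge cycles.
#' @param include_invalid keep invalid cycles (their rows are `NA`).
#' @return A `gait_parameters` data frame, one row per retained cycle,
#'   with a leading `cycle` column plus `valid`/`edge` flags.
#' @export
gait_parameters <- function(cycles, include_edge = FALSE,
                            include_invalid = FALSE) {
  stopifnot(inherits(cycles, "gait_cycles"))
  sel <- if (include_invalid) rep(TRUE, nrow(cycles)) else cycles$valid
  if (!include_edge) sel <- sel & !cycles$edge
  if (!any(sel)) stop("no cycles left to compute parameters for")
  out <- NULL
  for (k in which(sel)) {
    row <- if (cycles$valid[k]) {
      cycle_parameters(cycles$ic_time[k], cycles$oto_time[k],
                       cycles$oic_time[k], cycles$to_time[k],
                       cycles$next_ic_time[k])
    } else {
      as.data.frame(as.list(stats::setNames(
        rep(NA_real_, 10),
        c("stride_time", "cadence", "stance_pct", "swing_pct",
          "symmetry_pct", "dls_initial_pct", "sls_pct",
          "dls_terminal_pct", "dls_pct", "dls_total_pct"))),
        optional = TRUE) |> cbind(boundary = NA)
    }
    out <- rbind(out, cbind(cycle = k, row, valid = cycles$valid[k],
                            edge = cycles$edge[k]))
  }
  structure(out, class = c("gait_parameters", "data.frame"))
}

#' Aggregate gait parameters (mean +/- SD)
#'
#' Per-parameter mean and sample standard deviation over the rows of a
#' [gait_parameters()] table (invalid rows dropped).  With a single
#' cycle the SD is reported as 0 and `n = 1` flags the convention.
#'
#' @param params a `gait_parameters` data frame.
#' @return Data frame `parameter, mean, sd, n`.
#' @export
aggregate_parameters <- function(params) {
  stopifnot(is.data.frame(params))
  cols <- intersect(
    c("stride_time", "cadence", "stance_pct", "swing_pct", "symmetry_pct",
      "dls_initial_pct", "sls_pct", "dls_terminal_pct", "dls_pct",
      "dls_total_pct"),
    names(params))
  keep <- stats::complete.cases(params[, cols, drop = FALSE])
  if (!any(keep)) stop("no valid cycles to aggregate")
  p <- params[keep, cols, drop = FALSE]
  data.frame(
    parameter = cols,
    mean = vapply(p, mean, numeric(1)),
    sd = vapply(p, function(v) if (length(v) < 2) 0 else stats::sd(v),
                numeric(1)),
    n = nrow(p),
    row.names = NULL)
}
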