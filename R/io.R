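G_PER_MS2 <- 9.80665

#' Read a thigh-IMU recording from CSV
#'
#' Expects columns `acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z` and
#' optionally `t` (seconds).  The time column, when present, must be
#' uniform within 10% of the sample period; without it `sample_rate`
#' is required and the time base is implicit.  Source units are
#' converted to internal units (m/s^2, rad/s) and for a left-side sensor
#' the pitch rate is negated so the same detector applies to both legs.
#'
#' @param path CSV file path.
#' @param sample_rate sampling rate in Hz; required when the file has no
#'   `t` column.
#' @param acc_units `"m_s2"` or `"g"`.
#' @param gyro_units `"rad_s"` or `"deg_s"`.
#' @param side `"right"` or `"left"`.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, sample_rate = NULL,
                         acc_units = c("m_s2", "g"),
                         gyro_units = c("rad_s", "deg_s"),
                         side = c("right", "left")) {
  acc_units <- match.arg(acc_units)
  gyro_units <- match.arg(gyro_units)
  side <- match.arg(side)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty IMU file: ", path)
  num <- df[, intersect(c("t", need), names(df)), drop = FALSE]
  badrow <- which(!apply(num, 1, function(r) all(is.finite(as.numeric(r)))))
  if (length(badrow))
    stop("non-finite value at data row ", badrow[1], " of ", path)
  if ("t" %in% names(df)) {
    dt <- diff(df$t)
    period <- stats::median(dt)
    if (period <= 0 || any(abs(dt - period) > 0.1 * period))
      stop("non-uniform time base in ", path,
           " (jitter above 10% of the sample period)")
    fs <- 1 / period
    if (!is.null(sample_rate) && abs(fs - sample_rate) > 0.01 * sample_rate)
      warning("sample_rate (", sample_rate, " Hz) disagrees with the ",
              "time column (", signif(fs, 6), " Hz); using the time column")
  } else {
    if (is.null(sample_rate))
      stop("file has no t column; sample_rate is required")
    fs <- sample_rate
  }
  af <- if (acc_units == "g") G_PER_MS2 else 1
  gf <- if (gyro_units == "deg_s") pi / 180 else 1
  gy <- df$gyro_y * gf
  if (side == "left") gy <- -gy
  imu_recording(acc_ap = df$acc_x * af, acc_ml = df$acc_y * af,
                acc_v = df$acc_z * af, gyro_roll = df$gyro_x * gf,
                gyro_pitch = gy, gyro_yaw = df$gyro_z * gf,
                sample_rate = fs, side = side,
                units_declared = list(acc = acc_units, gyro = gyro_units))
}

#' Write a recording to CSV (internal units)
#'
#' @param recording an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE)
  invisible(path)
}

#' Write / read detected events as CSV
#'
#' Long format `cycle_index,event,sample_index,time_s,valid,edge` with a
#' 0-based `sample_index` (`time_s = sample_index / sample_rate`).
#' `read_events_csv` restores a `gait_cycles` object from such a file.
#'
#' @param cycles a `gait_cycles` object.
#' @param path file path.
#' @return `write_events_csv`: `path` invisibly; `read_events_csv`: a
#'   `gait_cycles` data frame.
#' @export
write_events_csv <- function(cycles, path) {
  ev <- events_long(cycles)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param sample_rate sampling rate of the source recording, Hz.
#' @export
read_events_csv <- function(path, sample_rate) {
  ev <- utils::read.csv(path)
  need <- c("cycle_index", "event", "sample_index", "time_s")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  ics <- ev[ev$event == "IC", ]
  ics <- ics[order(ics$time_s), ]
  n_cyc <- max(0L, nrow(ics) - 1L)
  cyc <- data.frame(cycle = seq_len(n_cyc), ic = NA_integer_,
                    oto = NA_integer_, oic = NA_integer_,
                    to = NA_integer_, next_ic = NA_integer_,
                    ic_branch = NA_character_, valid = FALSE,
                    edge = FALSE)
  for (k in seq_len(n_cyc)) {
    cyc$ic[k] <- ics$sample_index[k] + 1L
    cyc$next_ic[k] <- ics$sample_index[k + 1] + 1L
    for (evk in c("OTO", "OIC", "TO")) {
      rows <- ev[ev$event == evk & ev$time_s > ics$time_s[k] &
                   ev$time_s < ics$time_s[k + 1], ]
      if (nrow(rows))
        cyc[[tolower(evk)]][k] <- rows$sample_index[1] + 1L
    }
    cyc$valid[k] <- !anyNA(cyc[k, c("oto", "oic", "to")]) &&
      cyc$ic[k] < cyc$oto[k] && cyc$oto[k] < cyc$oic[k] &&
      cyc$oic[k] < cyc$to[k] && cyc$to[k] < cyc$next_ic[k]
  }
  if (n_cyc > 0) cyc$edge[c(1L, n_cyc)] <- TRUE
  for (col in c("ic", "oto", "oic", "to", "next_ic"))
    cyc[[paste0(col, "_time")]] <- (cyc[[col]] - 1) / sample_rate
  structure(cyc, class = c("gait_cycles", "data.frame"),
            sample_rate = sample_rate, main_freq = NA_real_)
}

#' Write gait parameters as CSV
#'
#' One row per cycle plus `mean` and `sd` summary rows.
#'
#' @param params a [gait_parameters()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path) {
  agg <- aggregate_parameters(params)
  cols <- agg$parameter
  out <- params
  out$cycle <- as.character(out$cycle)
  for (stat in c("mean", "sd")) {
    row <- out[1, ]
    row[] <- NA
    row$cycle <- stat
    row[cols] <- as.list(agg[[stat]])
    out <- rbind(out, row)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read reference events (`event,time_s` CSV)
#'
#' @param truth a [ground_truth()].
#' @param path file path.
#' @return `write_reference_csv`: `path` invisibly;
#'   `read_reference_csv`: a [ground_truth()].
#' @export
write_reference_csv <- function(truth, path) {
  utils::write.csv(as_event_table(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @param source provenance label for the reference table.
#' @export
read_reference_csv <- function(path, source = c("force_plate", "simulator")) {
  source <- match.arg(source)
  df <- utils::read.csv(path)
  if (!all(c("event", "time_s") %in% names(df)))
    stop("reference CSV needs columns event,time_s")
  get <- function(kind) sort(df$time_s[df$event == kind])
  ground_truth(ic = get("IC"), oto = get("OTO"), oic = get("OIC"),
               to = get("TO"), source = source)
}

#' Write / read a detection configuration as YAML
#'
#' @param config a [detection_config()].
#' @param path file path.
#' @param io optional list of I/O settings (units, side) stored
#'   alongside the detection fields.
#' @return `write_config_yaml`: `path` invisibly; `read_config_yaml`:
#'   a list with elements `config` ([detection_config()]) and `io`.
#' @export
write_config_yaml <- function(config, path, io = NULL) {
  stopifnot(inherits(config, "detection_config"))
  lst <- unclass(config)
  lst$sample_rate_hz <- lst$sample_rate
  lst$sample_rate <- NULL
  lst$bandpass_half_width_hz <- lst$bandpass_half_width
  lst$bandpass_half_width <- NULL
  lst$lowpass_cutoff_hz <- lst$lowpass_cutoff
  lst$lowpass_cutoff <- NULL
  if (!is.null(io)) lst$io <- io
  yaml::write_yaml(lst[!vapply(lst, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cfg <- detection_config(
    th_to_gyro = lst$th_to_gyro %||% -0.5,
    th_acc_x = lst$th_acc_x %||% 1.5,
    th_acc_z = lst$th_acc_z %||% 1.5,
    oto_delay = lst$oto_delay %||% 0.05,
    min_peak_separation = lst$min_peak_separation %||% 0.25,
    main_freq = lst$main_freq %||% "auto",
    bandpass_half_width = lst$bandpass_half_width_hz %||% 0.5,
    lowpass_cutoff = lst$lowpass_cutoff_hz %||% 3.0,
    causal = lst$causal %||% FALSE,
    sample_rate = lst$sample_rate_hz)
  list(config = cfg, io = lst$io)
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation: tool version, command,
#' configuration hash, input file digests, seed, timestamp and
#' per-stage counts, so any run is reproducible from its manifest.
#'
#' @param path output path.
#' @param command subcommand name.
#' @param inputs character vector of input file paths (digested).
#' @param config optional [detection_config()] (hashed).
#' @param seed optional seed.
#' @param counts named list of per-stage counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, inputs = character(0),
                           config = NULL, seed = NULL, counts = list()) {
  digest <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else NULL
  cfg_hash <- if (!is.null(config)) {
    unname(tools::md5sum(local({
      f <- tempfile()
      writeLines(paste(deparse(unclass(config)), collapse = ""), f)
      f
    })))
  } else NULL
  jsonlite::write_json(
    list(tool = "thighgait",
         version = as.character(utils::packageVersion("thighgait")),
         command = command, timestamp = format(Sys.time(), tz = "UTC"),
         inputs = digest, config_hash = cfg_hash, seed = seed,
         counts = counts),
    path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
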