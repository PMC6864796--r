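#' Construct an IMU stream
#'
#' An IMU stream is a tibble of timestamped six-axis inertial samples: time `t`
#' in seconds, accelerometer `ax`, `ay`, `az` in m/s^2 and gyroscope `gx`,
#' `gy`, `gz` in degrees per second, all in the sensor frame. The sampling
#' rate, body side and a free-text label travel along as attributes.
#'
#' Validation enforces the sensor model: component magnitudes within the
#' +/-16 g accelerometer and +/-2000 deg/s gyroscope full-scale ranges,
#' strictly increasing timestamps, and a median sample spacing within 1% of
#' `1/fs`. Individual gaps larger than one nominal period are permitted (they
#' arise from transmission dropouts) and are handled downstream.
#'
#' @param data Data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param fs Sampling rate in Hz (nominal 500).
#' @param side `"left"` or `"right"`.
#' @param label Free-text label carried through to outputs.
#' @return A tibble of class `imu_stream`.
#' @examples
#' s <- imu_stream(data.frame(
#'   t = 0:4 / 500, ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0
#' ))
#' @export
imu_stream <- function(data, fs = 500, side = c("left", "right"), label = "") {
  side <- match.arg(side)
  x <- as_tibble(data)[, c("t", "ax", "ay", "az", "gx", "gy", "gz")]
  attr(x, "fs") <- fs
  attr(x, "side") <- side
  attr(x, "label") <- label
  class(x) <- c("imu_stream", class(tibble()))
  validate_imu_stream(x)
}

#' Validate an IMU stream
#'
#' @param x An [imu_stream()].
#' @return `x` invisibly re-classed; aborts with the offending row on failure.
#' @export
validate_imu_stream <- function(x) {
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("stream is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) < 1) abort("stream must contain at least one sample")
  bad <- which(!is.finite(as.matrix(x[need])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-finite value at row ", bad[1, 1], ", column ", need[bad[1, 2]]))
  }
  if (nrow(x) > 1) {
    dt <- diff(x$t)
    if (any(dt <= 0)) {
      abort(paste0("timestamps not strictly increasing at row ", which(dt <= 0)[1] + 1))
    }
    fs <- attr(x, "fs")
    if (!is.null(fs) && abs(median(dt) - 1 / fs) > 0.01 / fs) {
      abort(paste0(
        "median sample spacing ", signif(median(dt), 6),
        " s inconsistent with fs = ", fs, " Hz (tolerance 1%)"
      ))
    }
  }
  acc <- as.matrix(x[, c("ax", "ay", "az")])
  gyr <- as.matrix(x[, c("gx", "gy", "gz")])
  over_a <- which(abs(acc) > ACC_RANGE, arr.ind = TRUE)
  if (nrow(over_a) > 0) {
    abort(paste0("acceleration out of +/-16 g range at row ", over_a[1, 1]))
  }
  over_g <- which(abs(gyr) > GYR_RANGE, arr.ind = TRUE)
  if (nrow(over_g) > 0) {
    abort(paste0("angular velocity out of +/-2000 deg/s range at row ", over_g[1, 1]))
  }
  invisible(x)
}

stream_fs <- function(x, fs = NULL) {
  fs <- fs %||% attr(x, "fs")
  if (is.null(fs)) {
    if (nrow(x) < 2) abort("cannot infer sampling rate from a single sample")
    fs <- 1 / median(diff(x$t))
  }
  fs
}

stream_side <- function(x) attr(x, "side") %||% "left"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write IMU stream CSV files
#'
#' The on-disk dialect is comma-separated UTF-8 with a single header line
#' `t,ax,ay,az,gx,gy,gz` (seconds, m/s^2, deg/s). `write_imu_csv()` emits the
#' shortest round-trippable decimal representation, so
#' `read_imu_csv(write_imu_csv(x))` reproduces `x` bit-identically.
#'
#' @param path File path.
#' @param fs Sampling rate override in Hz; inferred from the median timestamp
#'   spacing when `NULL`.
#' @param side,label Stream metadata (not stored in the file).
#' @return `read_imu_csv()` returns an [imu_stream()]; `write_imu_csv()`
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path, fs = NULL, side = c("left", "right"), label = "") {
  side <- match.arg(side)
  x <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
  }
  # as.numeric is a correctly-rounded strtod; vroom's fast parser is not, and
  # would break bit-identical round trips
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(need), as.numeric))
  bad <- which(!stats::complete.cases(x[need]))
  if (length(bad) > 0) {
    abort(paste0(path, ": non-numeric value at row ", bad[1]))
  }
  if (nrow(x) < 2 && is.null(fs)) fs <- 500
  imu_stream(x, fs = fs %||% round(1 / median(diff(x$t))), side = side, label = label)
}

#' @rdname read_imu_csv
#' @param x An [imu_stream()].
#' @export
write_imu_csv <- function(x, path) {
  validate_imu_stream(x)
  out <- as_tibble(x)[, c("t", "ax", "ay", "az", "gx", "gy", "gz")]
  # 17 significant digits: the shortest representation that round-trips every
  # IEEE double bit-identically
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ sprintf("%.17g", .x)
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write gait-event CSV files
#'
#' Events are stored as `kind,side,index,t`: the event kind (one of
#' `r paste(gait_event_kinds, collapse = ", ")`), body side, the 1-based sample
#' ordinal within its stream, and the timestamp in seconds.
#'
#' @param path File path.
#' @return A tibble with columns `kind`, `side`, `index`, `t`.
#' @export
read_events_csv <- function(path) {
  x <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      kind = readr::col_character(), side = readr::col_character(),
      index = readr::col_integer(), t = readr::col_character()
    )
  )
  x$t <- as.numeric(x$t) # correctly-rounded strtod, for exact round trips
  validate_events(x, where = path)
}

#' @rdname read_events_csv
#' @param events Event tibble as produced by the detector or simulator.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events)
  out <- events[, c("kind", "side", "index", "t")]
  out$t <- sprintf("%.17g", out$t)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_events <- function(x, where = "events") {
  need <- c("kind", "side", "index", "t")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(where, ": missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!x$kind %in% gait_event_kinds)
  if (length(bad) > 0) {
    abort(paste0(
      where, ": unknown event kind \"", x$kind[bad[1]], "\" at row ", bad[1]
    ))
  }
  bad_side <- which(!x$side %in% c("left", "right"))
  if (length(bad_side) > 0) {
    abort(paste0(where, ": unknown side at row ", bad_side[1]))
  }
  if (any(x$index < 1)) abort(paste0(where, ": sample index must be >= 1"))
  as_tibble(x)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf(
    "# IMU stream: %d samples @ %g Hz, side %s%s\n",
    nrow(x), stream_fs(x), stream_side(x),
    if (nzchar(attr(x, "label") %||% "")) paste0(" (", attr(x, "label"), ")") else ""
  ))
  NextMethod()
}
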