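#' Default stimulation timing chart
#'
#' Per-muscle start/stop percentages of the gait cycle for the eight
#' stimulation channels (both sides of quadriceps femoris, biceps femoris,
#' tibialis anterior and gastrocnemius). Entries whose start exceeds their
#' stop wrap around the cycle boundary (e.g. left quadriceps: on at 90%, off
#' at 16% of the next cycle). The two sides are offset by half a cycle; each
#' entry is tied to its own limb's cycles.
#'
#' @return A tibble with columns `muscle`, `side`, `start_pct`, `stop_pct`.
#' @export
default_timing_chart <- function() {
  tibble(
    muscle = rep(c(
      "quadriceps_femoris", "biceps_femoris", "tibialis_anterior", "gastrocnemius"
    ), each = 2),
    side = rep(c("left", "right"), 4),
    start_pct = c(90, 40, 80, 30, 56, 6, 10, 60),
    stop_pct = c(16, 66, 12, 62, 12, 62, 50, 100)
  )
}

#' Read / write a timing chart CSV
#'
#' Columns `muscle,side,start_pct,stop_pct`; percentages in `[0, 100]`,
#' wrap-around (start > stop) permitted.
#'
#' @param path File path.
#' @return A validated timing-chart tibble.
#' @export
read_timing_chart <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_timing_chart(x)
}

#' @rdname read_timing_chart
#' @param chart A timing-chart tibble.
#' @export
write_timing_chart <- function(chart, path) {
  validate_timing_chart(chart)
  readr::write_csv(chart[, c("muscle", "side", "start_pct", "stop_pct")], path,
    progress = FALSE
  )
  invisible(path)
}

validate_timing_chart <- function(x) {
  need <- c("muscle", "side", "start_pct", "stop_pct")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("timing chart missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(x$start_pct < 0 | x$start_pct > 100 | x$stop_pct < 0 | x$stop_pct > 100)) {
    abort("timing chart percentages must lie in [0, 100]")
  }
  if (any(x$start_pct == x$stop_pct)) {
    abort("timing chart start_pct must differ from stop_pct")
  }
  if (any(!x$side %in% c("left", "right"))) abort("timing chart side must be left/right")
  as_tibble(x)
}

#' Gait-phase anchor percentages
#'
#' Percent-of-cycle positions assigned to the four events: IC opens the cycle
#' at 0%, the next IC closes it at 100%, and FC / HO / TO sit between.
#' Standard gait-phase values are the defaults; they are configuration, not
#' published constants.
#'
#' @param fc,ho,to Percent positions of Full Contact, Heel Off, Toe Off.
#' @return Named numeric vector `c(ic = 0, fc, ho, to, ic_next = 100)`.
#' @export
gait_phase_anchors <- function(fc = 8, ho = 40, to = 60) {
  stopifnot(0 < fc, fc < ho, ho < to, to < 100)
  c(ic = 0, fc = fc, ho = ho, to = to, ic_next = 100)
}

cycle_anchor_times <- function(cycle) {
  c(cycle$t_ic, cycle$t_fc, cycle$t_ho, cycle$t_to, cycle$t_ic_next)
}

#' Convert between time and percent of gait cycle
#'
#' Piecewise-linear interpolation through the anchor pairs (event time,
#' anchor percent) of one valid cycle. `phase_percent()` maps a time inside
#' the cycle to its percent; `percent_to_time()` is the inverse.
#'
#' @param cycle One row of a `gait_detection` `cycles` tibble (a valid cycle
#'   with all five event times).
#' @param t Time in seconds, within the cycle span.
#' @param pct Percent of gait cycle, in `[0, 100]`.
#' @param anchors See [gait_phase_anchors()].
#' @return Percent (or time) as a numeric vector.
#' @export
phase_percent <- function(cycle, t, anchors = gait_phase_anchors()) {
  tk <- cycle_anchor_times(cycle)
  if (anyNA(tk)) abort("cycle is not valid (missing event times)")
  if (any(t < tk[1] | t > tk[5])) abort("t outside the cycle span")
  approx(tk, unname(anchors), xout = t)$y
}

#' @rdname phase_percent
#' @export
percent_to_time <- function(cycle, pct, anchors = gait_phase_anchors()) {
  tk <- cycle_anchor_times(cycle)
  if (anyNA(tk)) abort("cycle is not valid (missing event times)")
  if (any(pct < 0 | pct > 100)) abort("pct outside [0, 100]")
  approx(unname(anchors), tk, xout = pct)$y
}

#' Build a per-muscle stimulation schedule from detected cycles
#'
#' For every chart entry and every valid detected cycle, emits one on/off
#' interval at the entry's start/stop percentages of that cycle. The
#' scheduler is causal: when a cycle opens, its duration is not yet known, so
#' within-cycle times are predicted from the previous IC-to-IC duration; the
#' first cycle of a session therefore produces no stimulation. Wrap-around
#' entries (start > stop) stay on across the cycle boundary and close at
#' `stop` percent of the following (predicted) cycle. Invalid cycles produce
#' no stimulation (safety: a broken event sequence must not trigger).
#'
#' @param cycles The `cycles` tibble of a `gait_detection` (or the object
#'   itself). Only cycles whose `side` matches the chart entry's side are
#'   scheduled.
#' @param chart A timing chart (default [default_timing_chart()]).
#' @return A tibble of class `stim_schedule`: `muscle`, `side`, `cycle`,
#'   `on_time`, `off_time` (seconds).
#' @export
build_schedule <- function(cycles, chart = default_timing_chart()) {
  if (inherits(cycles, "gait_detection")) cycles <- cycles$cycles
  validate_timing_chart(chart)
  if (nrow(chart) == 0 || nrow(cycles) == 0) {
    return(empty_schedule())
  }
  cycles <- cycles[order(cycles$t_ic), ]
  dur_prev <- c(NA_real_, diff(cycles$t_ic))
  usable <- cycles$valid & !is.na(dur_prev)
  if (!any(usable)) {
    return(empty_schedule())
  }
  rows <- lapply(seq_len(nrow(chart)), function(e) {
    ent <- chart[e, ]
    sel <- usable & cycles$side == ent$side
    if (!any(sel)) {
      return(NULL)
    }
    stop_eff <- if (ent$stop_pct > ent$start_pct) ent$stop_pct else ent$stop_pct + 100
    tibble(
      muscle = ent$muscle, side = ent$side,
      cycle = cycles$cycle[sel],
      on_time = cycles$t_ic[sel] + ent$start_pct / 100 * dur_prev[sel],
      off_time = cycles$t_ic[sel] + stop_eff / 100 * dur_prev[sel]
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$muscle, out$side, out$on_time), ]
  class(out) <- c("stim_schedule", class(tibble()))
  out
}

empty_schedule <- function() {
  out <- tibble(
    muscle = character(0), side = character(0), cycle = integer(0),
    on_time = double(0), off_time = double(0)
  )
  class(out) <- c("stim_schedule", class(tibble()))
  out
}

#' Validate stimulator parameters
#'
#' Checks a parameter set against the portable 8-channel stimulator's
#' constraints: current up to 130 mA in 5 mA steps, frequency 10-50 Hz in
#' 5 Hz steps, pulse width 20-500 microseconds in 10 microsecond steps
#' (biphasic rectangular impulses). Violations are returned as data, not
#' raised.
#'
#' @param current Stimulation current, mA.
#' @param frequency Pulse frequency, Hz.
#' @param pulse_width Pulse width, microseconds.
#' @return A tibble of violations (`parameter`, `value`, `constraint`);
#'   zero rows means the set is valid.
#' @examples
#' nrow(validate_stim_params(130, 50, 500)) # 0: the device maxima
#' validate_stim_params(135, 33, 505)
#' @export
validate_stim_params <- function(current, frequency, pulse_width) {
  v <- list()
  bad <- function(parameter, value, constraint) {
    v[[length(v) + 1L]] <<- tibble(
      parameter = parameter, value = value, constraint = constraint
    )
  }
  step_off <- function(value, step) abs(value / step - round(value / step)) > 1e-9
  if (current < 0 || current > 130) {
    bad("current", current, "0 <= current <= 130 mA")
  }
  if (step_off(current, 5)) bad("current", current, "step size 5 mA")
  if (frequency < 10 || frequency > 50) {
    bad("frequency", frequency, "10 <= frequency <= 50 Hz")
  }
  if (step_off(frequency, 5)) bad("frequency", frequency, "step size 5 Hz")
  if (pulse_width < 20 || pulse_width > 500) {
    bad("pulse_width", pulse_width, "20 <= pulse_width <= 500 us")
  }
  if (step_off(pulse_width, 10)) bad("pulse_width", pulse_width, "step size 10 us")
  if (length(v) == 0) {
    tibble(parameter = character(0), value = double(0), constraint = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}

#' Read / write a stimulation schedule CSV
#'
#' Columns `muscle,side,cycle,on_time,off_time` (times in seconds).
#'
#' @param path File path.
#' @param schedule A `stim_schedule` tibble.
#' @return The schedule (read) or `path` invisibly (write).
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(
    as_tibble(schedule)[, c("muscle", "side", "cycle", "on_time", "off_time")],
    path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("stim_schedule", class(tibble()))
  out
}
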