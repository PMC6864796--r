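#' Tidy a gait detection result
#'
#' @param x A `gait_detection` from [detect_gait_events()].
#' @param what `"events"` (one row per accepted event) or `"cycles"` (one row
#'   per IC-to-IC cycle).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gait_detection
#' @export
tidy.gait_detection <- function(x, what = c("events", "cycles"), ...) {
  what <- match.arg(what)
  as_tibble(x[[what]])
}

#' One-row summary of a gait detection result
#'
#' @param x A `gait_detection`.
#' @param ... Unused.
#' @return A tibble with event/cycle counts, validity, the adaptation factor
#'   after the last Toe Off and the final floating band.
#' @method glance gait_detection
#' @export
glance.gait_detection <- function(x, ...) {
  tr <- x$trace
  tibble(
    side = x$side,
    n_samples = nrow(x$rotated),
    duration = diff(range(x$rotated$t)),
    n_events = nrow(x$events),
    n_cycles = nrow(x$cycles),
    n_valid_cycles = sum(x$cycles$valid),
    n_rotation_estimates = nrow(x$alignment),
    adaptation_factor = if (nrow(tr)) tr$factor[nrow(tr)] else 1,
    jerk_min = if (nrow(tr)) tr$jerk_min[nrow(tr)] else x$config$jerk_min,
    jerk_max = if (nrow(tr)) tr$jerk_max[nrow(tr)] else x$config$jerk_max
  )
}

#' Tidy a gait alignment result
#'
#' @param x A `gait_alignment` from [run_alignment()].
#' @param ... Unused.
#' @return One row per rotation estimate with the nine matrix entries
#'   (`r11 ... r33`, row-major), the source Full Contact index, availability
#'   index, main axis and degeneracy flag -- the exportable CSV form.
#' @method tidy gait_alignment
#' @export
tidy.gait_alignment <- function(x, ...) {
  mats <- lapply(x$rotation, function(e) {
    m <- as.vector(t(e$R))
    setNames(as.list(m), paste0("r", rep(1:3, each = 3), rep(1:3, 3)))
  })
  dplyr::bind_cols(
    tibble(
      fc_index = x$fc_index, available_from = x$available_from,
      main_axis = x$main_axis, degenerate = x$degenerate
    ),
    dplyr::bind_rows(lapply(mats, as_tibble))
  )
}

#' @export
print.gait_detection <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "# Gait detection (%s, %s): %d events, %d/%d valid cycles over %.1f s\n",
    x$config$profile, g$side, g$n_events, g$n_valid_cycles, g$n_cycles, g$duration
  ))
  print(x$cycles, ...)
  invisible(x)
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf(
    "# Sensor-to-foot rotation (from Full Contact at sample %s, main axis %s%s)\n",
    x$source_index, x$main_axis, if (isTRUE(x$degenerate)) ", degenerate" else ""
  ))
  print(x$R, ...)
  invisible(x)
}
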