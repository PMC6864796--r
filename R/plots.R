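#' Plot an IMU stream
#'
#' Faceted time series of the six channels (accelerometer m/s^2, gyroscope
#' deg/s).
#'
#' @param object An [imu_stream()].
#' @param channels Subset of `c("ax","ay","az","gx","gy","gz")`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot imu_stream
#' @export
autoplot.imu_stream <- function(object, channels = c("ax", "ay", "az", "gx", "gy", "gz"),
                                ...) {
  long <- tidyr_pivot(as_tibble(object), channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(
      x = "time [s]", y = NULL,
      title = sprintf("IMU stream (%s, %g Hz)", stream_side(object), stream_fs(object))
    ) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call site)
tidyr_pivot <- function(x, channels) {
  dplyr::bind_rows(lapply(channels, function(ch) {
    tibble(t = x$t, channel = factor(ch, levels = channels), value = x[[ch]])
  }))
}

#' Plot a gait detection result
#'
#' Foot-frame pitch rate with the accepted events marked; the trace every
#' detection decision was made on.
#'
#' @param object A `gait_detection` from [detect_gait_events()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_detection
#' @export
autoplot.gait_detection <- function(object, ...) {
  rot <- as_tibble(object$rotated)
  ev <- object$events
  ev$gy <- rot$gy[ev$index]
  ggplot2::ggplot(rot, ggplot2::aes(x = .data$t, y = .data$gy)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(
      data = ev,
      ggplot2::aes(colour = .data$kind), size = 2
    ) +
    ggplot2::labs(
      x = "time [s]", y = "pitch rate [deg/s]", colour = "event",
      title = sprintf(
        "Detected gait events (%s, %s side)", object$config$profile, object$side
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stimulation schedule
#'
#' One horizontal on-interval per channel and cycle.
#'
#' @param object A `stim_schedule` from [build_schedule()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stim_schedule
#' @export
autoplot.stim_schedule <- function(object, ...) {
  x <- as_tibble(object)
  x$channel <- paste(x$muscle, x$side)
  ggplot2::ggplot(x) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$on_time, xend = .data$off_time,
        y = .data$channel, yend = .data$channel, colour = .data$side
      ),
      linewidth = 3
    ) +
    ggplot2::labs(
      x = "time [s]", y = NULL, colour = "side",
      title = "Stimulation schedule"
    ) +
    ggplot2::theme_minimal()
}
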