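#' Alignment configuration
#'
#' Parameters of the arbitrary sensor-to-foot alignment. A Full Contact is
#' declared once all three gyroscope components have stayed below
#' `omega_fc_thresh` for `k_fc` consecutive samples; the gravity (z) axis is
#' the mean accelerometer vector over that quiescence window, and the pitch
#' (y) axis is read off the per-axis gyroscope sums over the `k_y` samples
#' that follow, which span the heel-off rotation of the next step.
#'
#' `k_y` defaults to 400 samples (0.8 s at 500 Hz): the quiescence condition
#' completes in late swing / early stance, so the summation window must reach
#' past the upcoming heel rise to see the pitch rotation at cycle durations of
#' 1.05-1.4 s. `y_sum_floor` (deg/s, mean over the window) separates a real
#' rotation from gyroscope noise; below it the estimate is flagged degenerate.
#'
#' None of these values is printed in the source hardware documentation; they
#' are package defaults, exposed here and in the `[alignment]` config section.
#'
#' @param omega_fc_thresh Quiescence threshold, deg/s.
#' @param k_fc Quiescence window length, samples.
#' @param k_y Post-contact gyroscope summation window, samples.
#' @param y_sum_floor Mean |sum| (deg/s) below which the window carries no
#'   rotation information.
#' @return A list of class `alignment_config`.
#' @export
alignment_config <- function(omega_fc_thresh = 20, k_fc = 50, k_y = 400,
                             y_sum_floor = 5) {
  stopifnot(
    omega_fc_thresh > 0, k_fc >= 1, k_y >= 1, y_sum_floor >= 0
  )
  structure(
    list(
      omega_fc_thresh = omega_fc_thresh, k_fc = as.integer(k_fc),
      k_y = as.integer(k_y), y_sum_floor = y_sum_floor
    ),
    class = "alignment_config"
  )
}

# run length of consecutive TRUEs ending at each position (vectorized)
run_lengths <- function(flag) {
  i <- seq_along(flag)
  last_false <- cummax(ifelse(flag, 0L, i))
  as.integer(ifelse(flag, i - last_false, 0L))
}

quiet_runs <- function(stream, thresh) {
  run_lengths(
    abs(stream$gx) < thresh & abs(stream$gy) < thresh & abs(stream$gz) < thresh
  )
}

#' Detect a Full Contact by gyroscope quiescence
#'
#' Returns the first sample index at or after `start` at which all three
#' angular-velocity components have remained below `cfg$omega_fc_thresh` for
#' `cfg$k_fc` consecutive samples (the returned index is the last sample of
#' that window). `NA` when the stream never satisfies the condition.
#'
#' @param stream An [imu_stream()].
#' @param start 1-based sample index to search from.
#' @param cfg An [alignment_config()].
#' @return Sample index, or `NA_integer_`.
#' @export
detect_full_contact <- function(stream, start = 1L, cfg = alignment_config()) {
  n <- nrow(stream)
  if (start < 1 || start > n) abort("start index outside stream")
  r <- quiet_runs(stream, cfg$omega_fc_thresh)
  # window may begin before `start`; require only that it completes at or after
  idx <- which(r[seq.int(start, n)] >= cfg$k_fc)
  if (length(idx) == 0) {
    return(NA_integer_)
  }
  as.integer(start + idx[1] - 1L)
}

#' Estimate the gravity (z) axis at a Full Contact
#'
#' The sensor-frame direction of gravity: the accelerometer vector averaged
#' over the quiescence window ending at `fc_index` (averaging suppresses
#' sensor noise; during foot flat the only acceleration is gravity).
#'
#' @inheritParams detect_full_contact
#' @param fc_index Full Contact sample index from [detect_full_contact()].
#' @return Un-normalized 3-vector (m/s^2).
#' @export
estimate_z_axis <- function(stream, fc_index, cfg = alignment_config()) {
  lo <- max(1L, fc_index - cfg$k_fc + 1L)
  z <- colMeans(as.matrix(stream[lo:fc_index, c("ax", "ay", "az")]))
  if (sqrt(sum(z^2)) < 1e-9) abort("zero-magnitude acceleration at Full Contact")
  unname(z)
}

#' Estimate the pitch (y) axis after a Full Contact
#'
#' Sums the angular velocity of each sensor axis over the `k_y` samples
#' following `fc_index`. The componentwise absolute sums identify the main
#' rotation axis (their argmax); the signed sums give its direction, oriented
#' so that the heel-rise pitch rate is positive in the foot frame. No prior
#' knowledge of the sensor-to-foot orientation is needed.
#'
#' @inheritParams estimate_z_axis
#' @return List with `axis` (signed 3-vector, deg/s summed over samples),
#'   `sums_abs` (componentwise absolute sums), `main_axis` (`"x"`, `"y"` or
#'   `"z"`) and `degenerate` (`TRUE` when the window carries no rotation
#'   information above `cfg$y_sum_floor`).
#' @export
estimate_y_axis <- function(stream, fc_index, cfg = alignment_config()) {
  n <- nrow(stream)
  if (fc_index + cfg$k_y > n) {
    abort("y-axis summation window exceeds stream end")
  }
  win <- as.matrix(stream[(fc_index + 1L):(fc_index + cfg$k_y), c("gx", "gy", "gz")])
  s <- colSums(win)
  sums_abs <- abs(s)
  list(
    axis = unname(s),
    sums_abs = unname(sums_abs),
    main_axis = c("x", "y", "z")[which.max(sums_abs)],
    degenerate = max(sums_abs) / cfg$k_y < cfg$y_sum_floor
  )
}

#' Build the sensor-to-foot rotation matrix
#'
#' From the raw gravity axis `z_raw` and pitch axis `y_raw`: the forward axis
#' is their cross product `x = y x z`, all rows are normalized, and the pitch
#' row is re-orthogonalized (`y <- z x x`) so the result is a proper rotation
#' (orthonormal rows, determinant +1). Without re-orthogonalization the
#' measured pitch axis is generally not perpendicular to gravity and the
#' rotated frame would be sheared.
#'
#' @param z_raw,y_raw Nonzero, non-parallel 3-vectors in the sensor frame.
#' @param source_index Sample index of the Full Contact the estimate came from.
#' @param main_axis Dominant sensor rotation axis (bookkeeping only).
#' @param degenerate Whether `y_raw` was a fallback with no rotation
#'   information.
#' @return A `rotation_estimate`: list with the 3x3 matrix `R` (rows x, y, z),
#'   `source_index`, `main_axis`, `degenerate`.
#' @examples
#' r <- build_rotation_matrix(z_raw = c(0, 0, 1), y_raw = c(1, 0, 0))
#' r$R # rows: x = (0,-1,0), y = (1,0,0), z = (0,0,1)
#' @export
build_rotation_matrix <- function(z_raw, y_raw, source_index = NA_integer_,
                                  main_axis = NA_character_, degenerate = FALSE) {
  nz <- sqrt(sum(z_raw^2))
  ny <- sqrt(sum(y_raw^2))
  if (nz < 1e-12 || ny < 1e-12) abort("zero-length axis vector")
  x_raw <- cross3(y_raw, z_raw)
  nx <- sqrt(sum(x_raw^2))
  if (nx < 1e-9 * nz * ny) abort("pitch and gravity axes are parallel (degenerate geometry)")
  z_hat <- z_raw / nz
  x_hat <- x_raw / nx
  y_hat <- cross3(z_hat, x_hat) # re-orthogonalized; unit by construction
  R <- rbind(x_hat, y_hat, z_hat)
  dimnames(R) <- list(c("x", "y", "z"), NULL)
  structure(
    list(
      R = R, source_index = as.integer(source_index),
      main_axis = main_axis, degenerate = degenerate
    ),
    class = "rotation_estimate"
  )
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Rotate a stream segment into the foot frame
#'
#' Left-multiplies every accelerometer and gyroscope sample in
#' `[from, to]` by the rotation, as done for each incoming data point online.
#'
#' @param stream An [imu_stream()].
#' @param rotation A `rotation_estimate` from [build_rotation_matrix()], or a
#'   plain 3x3 rotation matrix.
#' @param from,to 1-based sample range (defaults: whole stream).
#' @return An [imu_stream()] of the rotated segment.
#' @export
rotate_stream <- function(stream, rotation, from = 1L, to = nrow(stream)) {
  R <- if (inherits(rotation, "rotation_estimate")) rotation$R else rotation
  if (from < 1 || to > nrow(stream) || from > to) abort("invalid index range")
  seg <- as_tibble(stream)[from:to, ]
  acc <- as.matrix(seg[, c("ax", "ay", "az")]) %*% t(R)
  gyr <- as.matrix(seg[, c("gx", "gy", "gz")]) %*% t(R)
  out <- tibble(
    t = seg$t,
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]
  )
  imu_stream(out,
    fs = stream_fs(stream), side = stream_side(stream),
    label = attr(stream, "label") %||% ""
  )
}

fallback_y_axis <- function(z_hat) {
  # no rotation information: any axis not parallel to gravity serves
  e <- if (abs(z_hat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e - sum(e * z_hat) * z_hat
}

#' Run the alignment over a whole stream
#'
#' Scans the stream for Full Contacts and produces one rotation estimate per
#' stance (or rest) period. Each estimate becomes available once its `k_y`
#' summation window has passed (`available_from`) and governs the rotation of
#' samples from there until the next estimate; samples before the first
#' informative estimate are rotated with it retroactively. Degenerate windows
#' (no rotation above the noise floor, e.g. pure rest) yield a gravity-only
#' estimate with an arbitrary but consistent pitch axis; once an informative
#' estimate exists, later degenerate windows are skipped and the previous
#' estimate stays in force.
#'
#' @inheritParams detect_full_contact
#' @return A tibble of class `gait_alignment`: one row per estimate with
#'   `fc_index`, `available_from`, `main_axis`, `degenerate` and a list-column
#'   `rotation` of `rotation_estimate` objects.
#' @export
run_alignment <- function(stream, cfg = alignment_config()) {
  n <- nrow(stream)
  ests <- list()
  pos <- 1L
  have_good <- FALSE
  step <- max(cfg$k_y - cfg$k_fc, 1L)
  while (pos <= n) {
    fc <- detect_full_contact(stream, pos, cfg)
    if (is.na(fc) || fc + cfg$k_y > n) break
    z_raw <- estimate_z_axis(stream, fc, cfg)
    ys <- estimate_y_axis(stream, fc, cfg)
    if (ys$degenerate) {
      if (!have_good && length(ests) == 0) {
        z_hat <- z_raw / sqrt(sum(z_raw^2))
        est <- build_rotation_matrix(
          z_raw, fallback_y_axis(z_hat),
          source_index = fc, main_axis = ys$main_axis, degenerate = TRUE
        )
        ests[[length(ests) + 1L]] <- est
      }
      pos <- fc + step
    } else {
      est <- build_rotation_matrix(
        z_raw, ys$axis,
        source_index = fc, main_axis = ys$main_axis, degenerate = FALSE
      )
      if (!have_good && length(ests) > 0 && ests[[1]]$degenerate) {
        ests[1] <- NULL # informative estimate supersedes the rest bootstrap
      }
      have_good <- TRUE
      ests[[length(ests) + 1L]] <- est
      pos <- fc + step
    }
  }
  if (length(ests) == 0) {
    abort("alignment failure: no Full Contact found in stream")
  }
  out <- tibble(
    fc_index = vapply(ests, function(e) e$source_index, integer(1)),
    available_from = pmin(
      vapply(ests, function(e) e$source_index, integer(1)) + cfg$k_y, n
    ),
    main_axis = vapply(ests, function(e) e$main_axis, character(1)),
    degenerate = vapply(ests, function(e) e$degenerate, logical(1)),
    rotation = ests
  )
  class(out) <- c("gait_alignment", class(out))
  attr(out, "n_samples") <- n
  out
}

#' Apply a [run_alignment()] result to its stream
#'
#' Rotates every sample with the estimate in force at that sample (the most
#' recent `available_from` at or before it; the first estimate covers earlier
#' samples).
#'
#' @param stream The [imu_stream()] that produced `alignment`.
#' @param alignment A `gait_alignment` from [run_alignment()].
#' @return The rotated [imu_stream()].
#' @export
align_stream <- function(stream, alignment) {
  n <- nrow(stream)
  starts <- c(1L, alignment$available_from[-1])
  ends <- c(alignment$available_from[-1] - 1L, n)
  pieces <- vector("list", nrow(alignment))
  for (i in seq_len(nrow(alignment))) {
    if (starts[i] > ends[i]) next
    pieces[[i]] <- as_tibble(
      rotate_stream(stream, alignment$rotation[[i]], starts[i], ends[i])
    )
  }
  out <- dplyr::bind_rows(pieces)
  imu_stream(out,
    fs = stream_fs(stream), side = stream_side(stream),
    label = attr(stream, "label") %||% ""
  )
}
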