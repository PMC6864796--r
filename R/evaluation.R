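#' Match detected steps against reference steps
#'
#' Greedy one-to-one matching in time order: each detected valid cycle is
#' correct iff its opening Initial Contact lies within `tol` seconds of a
#' still-unmatched reference Initial Contact (the earliest such reference is
#' taken, which makes the greedy matching maximum-cardinality); otherwise it
#' is an incorrectly detected step. Unmatched reference steps are missed
#' (type-2) steps.
#'
#' @param detected Numeric vector of detected opening-IC times (s), one per
#'   valid cycle, or a `gait_detection` object (valid cycles are used).
#' @param reference Numeric vector of reference opening-IC times (s), one per
#'   complete reference cycle.
#' @param tol Matching tolerance, s. Default: 10% of the median reference
#'   cycle duration (the reference counts were manual, with no published
#'   tolerance).
#' @return List with counts `n_reference`, `n_detected`, `n_correct`,
#'   `n_incorrect`, `n_missed`, and index vectors `matched_reference` (per
#'   detected step; NA when incorrect).
#' @export
match_steps <- function(detected, reference, tol = NULL) {
  if (inherits(detected, "gait_detection")) {
    detected <- detected$cycles$t_ic[detected$cycles$valid]
  }
  detected <- sort(detected)
  reference <- sort(reference)
  if (is.null(tol)) {
    if (length(reference) < 2) {
      abort("tol must be given when fewer than 2 reference steps exist")
    }
    tol <- 0.1 * median(diff(reference))
  }
  used <- rep(FALSE, length(reference))
  matched <- rep(NA_integer_, length(detected))
  for (i in seq_along(detected)) {
    free <- which(!used & abs(reference - detected[i]) <= tol)
    if (length(free) > 0) {
      used[free[1]] <- TRUE
      matched[i] <- free[1]
    }
  }
  list(
    n_reference = length(reference),
    n_detected = length(detected),
    n_correct = sum(!is.na(matched)),
    n_incorrect = sum(is.na(matched)),
    n_missed = sum(!used),
    matched_reference = matched
  )
}

#' Detection rate and error rates
#'
#' `detection_rate()` is the percentage of reference steps the algorithm got
#' right: `100 / steps_reference * (steps_detected - steps_incorrect)`.
#' `type1_error()` is the percentage of incorrectly detected steps,
#' `100 / steps_reference * steps_incorrect` -- the hazardous kind, since an
#' incorrect step can mistime the stimulation. `type2_error()` is the
#' percentage of missed steps (not hazardous: a missed step simply triggers
#' nothing).
#'
#' @param steps_reference Number of (manually counted or ground-truth)
#'   reference steps; must be positive.
#' @param steps_detected Number of steps the algorithm reported.
#' @param steps_incorrect Number of reported steps that do not represent the
#'   typical movement pattern.
#' @return Percentage (0-100 scale; `detection_rate` can exceed 100 only if
#'   matching is not one-to-one).
#' @examples
#' detection_rate(100, 99, 1) # 98
#' type1_error(100, 1) # 1
#' @export
detection_rate <- function(steps_reference, steps_detected, steps_incorrect = 0) {
  if (steps_reference <= 0) abort("steps_reference must be positive")
  100 / steps_reference * (steps_detected - steps_incorrect)
}

#' @rdname detection_rate
#' @export
type1_error <- function(steps_reference, steps_incorrect) {
  if (steps_reference <= 0) abort("steps_reference must be positive")
  100 / steps_reference * steps_incorrect
}

#' @rdname detection_rate
#' @param steps_missed Number of reference steps never detected.
#' @export
type2_error <- function(steps_reference, steps_missed) {
  if (steps_reference <= 0) abort("steps_reference must be positive")
  100 / steps_reference * steps_missed
}

#' Normalize a signal for shape comparison
#'
#' Removes the offset by subtracting the mean, then divides by the square
#' root of the maximum of the signal's autocorrelation (which, for the
#' mean-removed signal, is its energy at zero lag). The autocorrelation
#' maximum of the result equals 1, indicating 100% self-similarity and
#' providing the base for cross-correlation comparison. Idempotent and
#' scale-invariant.
#'
#' @param x Non-constant numeric vector.
#' @return Normalized numeric vector.
#' @export
normalize_signal <- function(x) {
  y <- x - mean(x)
  e <- max(xcorr_full(y, y))
  if (e < .Machine$double.eps * length(x)) {
    abort("cannot normalize a constant signal")
  }
  y / sqrt(e)
}

# full cross-correlation sum_i x[i] * y[i + lag], lag ascending from
# -(length(x) - 1) to length(y) - 1; position p corresponds to
# lag = p - length(x). (R's convolve(x, y, type = "open") returns these
# values in reverse order.)
xcorr_full <- function(x, y) {
  rev(convolve(x, y, type = "open"))
}

#' Shape similarity of two signals
#'
#' Maximum of the cross-correlation of the two signals after
#' [normalize_signal()]; 1 means identical shape (up to amplitude, offset and
#' a time shift within the lag range). By Cauchy-Schwarz the value never
#' exceeds 1 for unit-energy inputs.
#'
#' @param ref,test Numeric vectors (e.g. the pitch-rate trace of one gait
#'   cycle from the reference and the rotated sensor).
#' @param max_lag Largest |lag| (samples) considered; default half the
#'   shorter signal.
#' @param normalize Normalize the inputs first (set `FALSE` if already
#'   normalized).
#' @return Similarity value in `[-1, 1]`.
#' @export
cross_similarity <- function(ref, test, max_lag = NULL, normalize = TRUE) {
  max_lag <- max_lag %||% floor(min(length(ref), length(test)) / 2)
  if (abs(length(ref) - length(test)) > max_lag) {
    abort("signal length mismatch exceeds the configured lag range")
  }
  if (normalize) {
    ref <- normalize_signal(ref)
    test <- normalize_signal(test)
  }
  cc <- xcorr_full(test, ref)
  lags <- seq_along(cc) - length(test) # lag of each output position
  max(cc[abs(lags) <= max_lag])
}

#' Windowed detection-rate evaluation
#'
#' Scores detector output against reference steps over fixed-size sample
#' windows (75,000 samples = 2.5 min at 500 Hz), the procedure used to make
#' recordings comparable. Window starts snap forward to the nearest resting
#' phase (gyroscope quiescence) from evenly spaced candidate positions; each
#' window is scored with [match_steps()] and Eqs.-style rates.
#'
#' @param stream The [imu_stream()] that was processed (used for rest-phase
#'   snapping).
#' @param detection A `gait_detection` object, or a numeric vector of
#'   detected opening-IC times.
#' @param reference Numeric vector of reference opening-IC times, or a
#'   simulator truth list (its complete cycles are used).
#' @param window_samples Window length in samples.
#' @param n_windows Number of windows.
#' @param tol Matching tolerance, s (see [match_steps()]).
#' @param quiet_thresh,quiet_run Rest-phase definition for snapping: all gyro
#'   components below `quiet_thresh` deg/s for `quiet_run` samples.
#' @return A tibble with one row per window: `window`, `start_index`,
#'   `end_index`, `steps_reference`, `steps_detected`, `steps_incorrect`,
#'   `steps_missed`, `detection_rate`, `type1_error`, `type2_error`.
#'   Mean/sd summaries are attached as attribute `"summary"`.
#' @export
windowed_evaluation <- function(stream, detection, reference,
                                window_samples = 75000, n_windows = 1,
                                tol = NULL, quiet_thresh = 20, quiet_run = 50) {
  n <- nrow(stream)
  if (n < window_samples) {
    abort("stream shorter than one evaluation window")
  }
  det_times <- if (inherits(detection, "gait_detection")) {
    detection$cycles$t_ic[detection$cycles$valid]
  } else {
    detection
  }
  ref_times <- if (is.list(reference) && !is.null(reference$cycles)) {
    reference$cycles$t_ic
  } else {
    reference
  }
  if (is.null(tol)) {
    if (length(ref_times) < 2) abort("need >= 2 reference steps to derive tol")
    tol <- 0.1 * median(diff(sort(ref_times)))
  }

  r <- quiet_runs(stream, quiet_thresh)
  rest_ok <- r >= quiet_run
  max_start <- n - window_samples + 1L
  cand <- as.integer(floor(seq(1L, max_start, length.out = n_windows)))
  starts <- vapply(cand, function(s) {
    # snap to the nearest rest phase: forward if the window still fits,
    # otherwise the last rest phase before the candidate
    hit <- first_at_least(rest_ok, s)
    if (!is.na(hit) && hit <= max_start) {
      return(hit)
    }
    before <- which(rest_ok[seq_len(s)])
    if (length(before) > 0) tail(before, 1) else s
  }, integer(1))

  rows <- lapply(seq_len(n_windows), function(w) {
    s <- starts[w]
    e <- s + window_samples - 1L
    t0 <- stream$t[s]
    t1 <- stream$t[e]
    refw <- ref_times[ref_times >= t0 & ref_times <= t1]
    detw <- det_times[det_times >= t0 & det_times <= t1]
    if (length(refw) == 0) {
      return(tibble(
        window = w, start_index = s, end_index = e,
        steps_reference = 0L, steps_detected = length(detw),
        steps_incorrect = length(detw), steps_missed = 0L,
        detection_rate = NA_real_, type1_error = NA_real_, type2_error = NA_real_
      ))
    }
    m <- match_steps(detw, refw, tol = tol)
    tibble(
      window = w, start_index = s, end_index = e,
      steps_reference = m$n_reference, steps_detected = m$n_detected,
      steps_incorrect = m$n_incorrect, steps_missed = m$n_missed,
      detection_rate = detection_rate(m$n_reference, m$n_detected, m$n_incorrect),
      type1_error = type1_error(m$n_reference, m$n_incorrect),
      type2_error = type2_error(m$n_reference, m$n_missed)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- tibble(
    detection_rate_mean = mean(out$detection_rate, na.rm = TRUE),
    detection_rate_sd = stats::sd(out$detection_rate, na.rm = TRUE),
    type1_error_mean = mean(out$type1_error, na.rm = TRUE),
    type1_error_sd = stats::sd(out$type1_error, na.rm = TRUE)
  )
  out
}
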