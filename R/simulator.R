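#' Map treadmill belt speed to a gait-cycle duration
#'
#' Built-in editable table for the three rehabilitation belt speeds; the
#' robots publish belt speeds, not cadences, so this mapping is a package
#' convention (typical robot-assisted cadences of 43-57 steps/min per leg).
#'
#' @param speed Belt speed, m/s.
#' @param table Named numeric: cycle duration (s) per speed.
#' @return Cycle duration in seconds.
#' @examples
#' speed_to_cycle_duration(1.5) # 1.2 s
#' @export
speed_to_cycle_duration <- function(speed,
                                    table = c("1.2" = 1.4, "1.5" = 1.2, "1.7" = 1.05)) {
  key <- as.character(speed)
  if (!key %in% names(table)) {
    abort(paste0(
      "no cycle duration tabulated for speed ", speed,
      " m/s (have: ", paste(names(table), collapse = ", "), ")"
    ))
  }
  unname(table[key])
}

#' Draw a uniformly random proper rotation
#'
#' QR-based Haar sampling with the sign fix that makes the factorization
#' unique and the determinant +1.
#'
#' @param seed Optional integer seed (local to this call).
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Express a foot-frame stream in an arbitrary sensor frame
#'
#' Pre-multiplies every accelerometer and gyroscope sample by the mounting
#' rotation `R0` (the unknown, fixed rotation between sensor case and foot
#' axes that the alignment algorithm must neutralize). Invertible:
#' `apply_mounting(apply_mounting(s, R0), t(R0))` restores `s`.
#'
#' @param stream An [imu_stream()].
#' @param R0 Proper 3x3 rotation matrix.
#' @return The re-expressed [imu_stream()].
#' @export
apply_mounting <- function(stream, R0) {
  if (!is.matrix(R0) || any(dim(R0) != 3) ||
    max(abs(R0 %*% t(R0) - diag(3))) > 1e-8 || det(R0) < 0) {
    abort("mounting must be a proper (orthonormal, det +1) rotation matrix")
  }
  rotate_stream(stream, R0)
}

# raised-cosine pulse on [0, width], peak amplitude `amp`
raised_cosine <- function(tau, width, amp) {
  ifelse(tau >= 0 & tau <= width, amp / 2 * (1 - cos(2 * pi * tau / width)), 0)
}

#' Simulate a foot-IMU gait recording with ground truth
#'
#' Generates the canonical foot-frame signal of cyclic robot-induced foot
#' motion, then maps it into an arbitrary sensor frame and adds noise. Each
#' cycle of duration `cycle_duration` contains:
#'
#' * an Initial Contact jerk pulse in the z acceleration at 0% of the cycle
#'   (raised cosine of width `ic_pulse_width`, scaled so the analytic jerk
#'   peak equals `ic_jerk_amp`);
#' * a quiet foot-flat interval (gyroscope zero, acceleration `(0, 0, g)`)
#'   until Heel Off;
#' * a pitch-rate ramp from Heel Off rising through a swing peak of
#'   `swing_peak_omega` shortly after Toe Off, then falling strictly
#'   monotonically back to zero before the next Initial Contact;
#' * gravity resolved into the instantaneous foot pitch, which rises to
#'   `pitch_max` degrees mid-swing and returns to zero.
#'
#' Lead-in and tail rest phases frame the cycles. The `lyra` profile scales
#' the Initial Contact jerk down and can inject spurious jerk spikes late in
#' swing, while the pitch rate is still away from zero
#' (`spurious_spike_rate` per cycle) -- the artifact pattern the angular
#' velocity IC band exists to reject. Samples are clipped to the +/-16 g and
#' +/-2000 deg/s sensor ranges (never reached at default amplitudes). Output
#' is deterministic given `seed`.
#'
#' Ground truth: `n_cycles` of each event are emitted; only the
#' `n_cycles - 1` spans between consecutive Initial Contacts are complete
#' reference cycles (steps), and those are what evaluation counts.
#'
#' @param n_cycles Number of gait cycles.
#' @param cycle_duration Cycle duration in seconds (see
#'   [speed_to_cycle_duration()]).
#' @param fs Sampling rate, Hz.
#' @param profile `"lokomat"` or `"lyra"` (sets the default jerk amplitude
#'   and spike behaviour).
#' @param side Body side recorded in the stream and ground truth.
#' @param rest_lead,rest_tail Rest phases before/after the cycles, s.
#' @param ic_jerk_amp Analytic jerk peak of the IC pulse, m/s^3 (default 400
#'   for lokomat, 150 for lyra).
#' @param ic_pulse_width IC pulse width, s.
#' @param swing_peak_omega Swing pitch-rate peak, deg/s.
#' @param event_pcts Named numeric: percent-of-cycle positions of `fc`, `ho`,
#'   `to`.
#' @param peak_pct,end_pct Percent positions of the swing pitch-rate peak and
#'   of its return to zero.
#' @param pitch_max Peak foot pitch, degrees.
#' @param mounting 3x3 mounting rotation, `TRUE` to draw one from `seed`, or
#'   `NULL` for an aligned sensor.
#' @param noise_sd_acc,noise_sd_gyr Gaussian sensor noise, m/s^2 and deg/s.
#' @param spurious_spike_rate Spurious jerk spikes per cycle (lyra artifact;
#'   up to 3, placed at 94/91/88% of the cycle).
#' @param dropout Optional `c(start, duration)` in seconds: samples in that
#'   span are deleted (transmission loss).
#' @param seed Integer seed; all randomness (mounting draw, noise) derives
#'   from it.
#' @return A list of class `gait_sim`: `stream` (the sensor-frame
#'   [imu_stream()]), `truth` (list with `events` tibble, `cycles` tibble,
#'   `mounting` matrix actually used, `canonical` foot-frame stream before
#'   mounting/noise).
#' @export
simulate_gait <- function(n_cycles = 20, cycle_duration = 1.2, fs = 500,
                          profile = c("lokomat", "lyra"),
                          side = c("left", "right"),
                          rest_lead = 2, rest_tail = 1,
                          ic_jerk_amp = NULL, ic_pulse_width = 0.04,
                          swing_peak_omega = 300,
                          event_pcts = c(fc = 8, ho = 40, to = 60),
                          peak_pct = 65, end_pct = 97,
                          pitch_max = 15,
                          mounting = NULL,
                          noise_sd_acc = 0.2, noise_sd_gyr = 1,
                          spurious_spike_rate = NULL,
                          dropout = NULL, seed = NULL) {
  profile <- match.arg(profile)
  side <- match.arg(side)
  ic_jerk_amp <- ic_jerk_amp %||% switch(profile, lokomat = 400, lyra = 150)
  spurious_spike_rate <- spurious_spike_rate %||% 0
  stopifnot(
    n_cycles >= 0, cycle_duration > 0, fs > 0, rest_lead >= 0, rest_tail >= 0,
    event_pcts["fc"] > 0, event_pcts["fc"] < event_pcts["ho"],
    event_pcts["ho"] < event_pcts["to"], event_pcts["to"] < 100,
    peak_pct > event_pcts["to"], end_pct > peak_pct, end_pct < 100
  )
  if (cycle_duration * fs < 100) {
    abort("event percentages are not resolvable at this fs / cycle duration")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (isTRUE(mounting)) mounting <- random_rotation()

  total <- rest_lead + n_cycles * cycle_duration + rest_tail
  n <- max(1L, round(total * fs))
  t <- (seq_len(n) - 1L) / fs
  g <- GRAVITY

  # percent of cycle (NA during rest)
  in_gait <- t >= rest_lead & t < rest_lead + n_cycles * cycle_duration
  tau <- (t - rest_lead) %% cycle_duration
  pct <- ifelse(in_gait, tau / cycle_duration * 100, NA_real_)

  ho <- unname(event_pcts["ho"])
  to <- unname(event_pcts["to"])
  fc <- unname(event_pcts["fc"])

  gy <- numeric(n)
  rise <- in_gait & pct >= ho & pct < peak_pct
  fall <- in_gait & pct >= peak_pct & pct < end_pct
  gy[rise] <- swing_peak_omega *
    sin(pi / 2 * (pct[rise] - ho) / (peak_pct - ho))^2
  gy[fall] <- swing_peak_omega * (1 - (pct[fall] - peak_pct) / (end_pct - peak_pct))

  theta <- numeric(n) # foot pitch, rad
  sw <- in_gait & pct >= ho & pct < end_pct
  theta[sw] <- pitch_max * pi / 180 * sin(pi * (pct[sw] - ho) / (end_pct - ho))^2

  ax <- g * sin(theta)
  ay <- numeric(n)
  az <- g * cos(theta)

  # IC jerk pulse: raised cosine in a_z, amplitude from the analytic jerk peak
  pulse_amp <- ic_jerk_amp * ic_pulse_width / pi
  az <- az + ifelse(in_gait, raised_cosine(tau, ic_pulse_width, pulse_amp), 0)

  # lyra artifact: spurious IC-like jerk spikes late in swing
  n_spur <- min(3L, max(0L, round(spurious_spike_rate)))
  if (n_spur > 0 && n_cycles > 0) {
    for (k in seq_len(n_spur)) {
      off <- (94 - 3 * (k - 1)) / 100 * cycle_duration
      spur_w <- ic_pulse_width / 2 # artifact spikes are sharper than heel strikes
      spur_amp <- ic_jerk_amp * spur_w / pi
      az <- az + ifelse(in_gait, raised_cosine(tau - off, spur_w, spur_amp), 0)
    }
  }

  canonical <- tibble(t = t, ax = ax, ay = ay, az = az, gx = 0, gy = gy, gz = 0)

  acc <- as.matrix(canonical[, c("ax", "ay", "az")])
  gyr <- as.matrix(canonical[, c("gx", "gy", "gz")])
  if (!is.null(mounting)) {
    acc <- acc %*% t(mounting)
    gyr <- gyr %*% t(mounting)
  }
  if (noise_sd_acc > 0) acc <- acc + rnorm(3 * n, sd = noise_sd_acc)
  if (noise_sd_gyr > 0) gyr <- gyr + rnorm(3 * n, sd = noise_sd_gyr)
  acc <- pmin(pmax(acc, -ACC_RANGE), ACC_RANGE)
  gyr <- pmin(pmax(gyr, -GYR_RANGE), GYR_RANGE)

  out <- tibble(
    t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]
  )

  pct_to_index <- function(cyc, p) {
    round((rest_lead + (cyc - 1 + p / 100) * cycle_duration) * fs) + 1L
  }
  events <- if (n_cycles > 0) {
    dplyr::bind_rows(lapply(seq_len(n_cycles), function(k) {
      tibble(
        kind = gait_event_kinds, side = side,
        index = c(
          pct_to_index(k, 0), pct_to_index(k, fc),
          pct_to_index(k, ho), pct_to_index(k, to)
        )
      )
    }))
  } else {
    tibble(kind = character(0), side = character(0), index = integer(0))
  }
  events$t <- (events$index - 1L) / fs
  events <- events[order(events$index), ]

  cycles <- if (n_cycles > 1) {
    tibble(
      cycle = seq_len(n_cycles - 1L), side = side,
      ic_index = pct_to_index(seq_len(n_cycles - 1L), 0),
      ic_next_index = pct_to_index(seq_len(n_cycles - 1L) + 1L, 0)
    )
  } else {
    tibble(
      cycle = integer(0), side = character(0),
      ic_index = integer(0), ic_next_index = integer(0)
    )
  }
  cycles$t_ic <- (cycles$ic_index - 1L) / fs
  cycles$t_ic_next <- (cycles$ic_next_index - 1L) / fs

  stream <- imu_stream(out, fs = fs, side = side, label = profile)
  if (!is.null(dropout)) {
    stream <- inject_disturbance(stream,
      kind = "dropout",
      at = dropout[1], duration = dropout[2]
    )
  }
  structure(
    list(
      stream = stream,
      truth = list(
        events = events, cycles = cycles,
        mounting = mounting %||% diag(3),
        canonical = imu_stream(canonical, fs = fs, side = side, label = "canonical")
      ),
      profile = profile
    ),
    class = "gait_sim"
  )
}

#' Inject a disturbance into a stream
#'
#' Three error modes the measuring chain can produce: `"spike"` adds an
#' IC-like jerk pulse at a chosen time (an impact not associated with the
#' gait pattern), `"dropout"` deletes the samples in a time span (lost
#' transmission; most real errors are missing data points), `"drift"` adds a
#' slowly growing gyroscope bias (badly calibrated sensor).
#'
#' @param stream An [imu_stream()].
#' @param kind `"spike"`, `"dropout"` or `"drift"`.
#' @param at Start time of the disturbance, s.
#' @param duration Dropout length, s.
#' @param jerk_amp Spike analytic jerk peak, m/s^3.
#' @param width Spike width, s.
#' @param rate Drift rate, deg/s per second.
#' @param axis Drift axis: `"gx"`, `"gy"` or `"gz"`.
#' @return The disturbed [imu_stream()].
#' @export
inject_disturbance <- function(stream, kind = c("spike", "dropout", "drift"),
                               at = 0, duration = 0, jerk_amp = 400,
                               width = 0.04, rate = 1, axis = "gy") {
  kind <- match.arg(kind)
  x <- as_tibble(stream)
  if (kind == "spike") {
    amp <- jerk_amp * width / pi
    x$az <- x$az + raised_cosine(x$t - at, width, amp)
  } else if (kind == "dropout") {
    if (duration > 0) {
      keep <- x$t < at | x$t >= at + duration
      if (!any(keep)) abort("dropout would delete the whole stream")
      x <- x[keep, ]
    }
  } else {
    axis <- match.arg(axis, c("gx", "gy", "gz"))
    x[[axis]] <- x[[axis]] + rate * pmax(x$t - at, 0)
  }
  imu_stream(x,
    fs = stream_fs(stream), side = stream_side(stream),
    label = attr(stream, "label") %||% ""
  )
}
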