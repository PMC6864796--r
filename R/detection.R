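#' Detector configuration and device profiles
#'
#' All thresholds, windows and temporal gates of the gait-event detector,
#' bundled with an [alignment_config()]. Two named device profiles ship as
#' presets:
#'
#' * `"lokomat"` (exoskeleton trainer): higher initial jerk band, angular
#'   velocity IC band disabled.
#' * `"lyra"` (end-effector trainer): the heel strike produces a much lower
#'   jerk, so the initial band is lower; the swing phase carries spurious jerk
#'   spikes, so an angular-velocity band around zero gates the IC condition
#'   (a candidate IC whose pitch rate lies outside `ic_band` is discarded);
#'   the minimum swing time is slightly longer.
#'
#' Every numeric default here is a package choice, not a published value: the
#' source publication prints none of its initial thresholds. They are sized to
#' the synthetic signal amplitudes and to gait-cycle durations of 1.05-1.4 s
#' (treadmill 1.2-1.7 m/s); all are exposed in the `[detector]` and
#' `[profile.*]` config sections.
#'
#' @param profile `"lokomat"` or `"lyra"`.
#' @param jerk_min,jerk_max Initial Contact jerk band, m/s^3 (floating; these
#'   are the pre-adaptation values).
#' @param float_alpha Blend weight of the floating-threshold update (0 keeps
#'   the band fixed, 1 replaces it each step).
#' @param float_gamma_lo,float_gamma_hi Fractions of the current peak jerk the
#'   band edges move toward (`float_gamma_lo` defaults per profile: 0.5
#'   lokomat, 0.6 lyra -- the lower-jerk trainer needs the tighter floor to
#'   stay clear of the differentiated noise).
#' @param min_swing_time Minimum time from Toe Off to the next Initial
#'   Contact, s.
#' @param min_roll_time Minimum time from Initial Contact to Heel Off, s.
#' @param omega_heeloff_thresh_y Pitch-rate threshold the heel rise must
#'   exceed, deg/s.
#' @param a_heeloff_thresh Length-3 accelerometer thresholds (x, y,
#'   gravity-corrected z) that must NOT be exceeded at Heel Off, m/s^2.
#' @param heeloff_omega_exceeds,heeloff_acc_below Comparator directions of the
#'   Heel Off conditions (the printed conditions and the surrounding prose
#'   disagree; defaults follow the prose: rotation rises while translation is
#'   still quiet).
#' @param omega_threshold_high,omega_threshold_low Toe Off pitch-rate
#'   thresholds, deg/s: the rate must exceed `high`, then fall monotonically,
#'   then drop below `low`.
#' @param k_to Length of the strictly-decreasing run required between the two
#'   Toe Off thresholds, samples.
#' @param to_smooth Trailing moving-average width (samples) applied to the
#'   pitch rate for the Toe Off conditions; 1 disables.
#' @param jerk_smooth Trailing moving-average width (samples) applied to the
#'   jerk series; 1 disables. Profile defaults: 5 (lokomat), 9 (lyra). A
#'   backward difference at 500 Hz amplifies accelerometer noise by the
#'   sampling rate, so some smoothing is required at realistic noise levels;
#'   the moving average keeps the differentiator causal.
#' @param peak_window Samples after an IC trigger scanned for the pulse peak
#'   that feeds the floating-threshold update.
#' @param ic_band Length-2 pitch-rate band (deg/s) an IC candidate must lie
#'   inside, or `NULL` to disable (lokomat default).
#' @param omega_ref Reference Toe Off peak pitch rate for threshold
#'   adaptation, deg/s.
#' @param adapt_min,adapt_max Clamp on the adaptation factor.
#' @param gap_factor Cycles containing a timestamp gap larger than
#'   `gap_factor / fs` are marked invalid (transmission dropouts).
#' @param gravity Gravity magnitude used for the z-acceleration correction,
#'   m/s^2.
#' @param alignment An [alignment_config()].
#' @param ... Named overrides of any of the above applied after the profile
#'   preset.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(profile = c("lokomat", "lyra"),
                            jerk_min = NULL, jerk_max = NULL,
                            float_alpha = 0.3,
                            float_gamma_lo = NULL, float_gamma_hi = 1.5,
                            min_swing_time = NULL, min_roll_time = 0.15,
                            omega_heeloff_thresh_y = 15,
                            a_heeloff_thresh = c(3, 3, 3),
                            heeloff_omega_exceeds = TRUE,
                            heeloff_acc_below = TRUE,
                            omega_threshold_high = 200,
                            omega_threshold_low = 150,
                            k_to = 25, to_smooth = 5, jerk_smooth = NULL,
                            peak_window = 25,
                            ic_band = NULL,
                            omega_ref = 300, adapt_min = 0.5, adapt_max = 2,
                            gap_factor = 5, gravity = GRAVITY,
                            alignment = alignment_config(), ...) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    lokomat = list(
      jerk_min = 150, jerk_max = 1500, min_swing_time = 0.10, ic_band = NULL,
      jerk_smooth = 5, float_gamma_lo = 0.5
    ),
    lyra = list(
      jerk_min = 70, jerk_max = 800, min_swing_time = 0.12, ic_band = c(-5, 5),
      jerk_smooth = 9, float_gamma_lo = 0.6
    )
  )
  cfg <- list(
    profile = profile,
    jerk_min = jerk_min %||% preset$jerk_min,
    jerk_max = jerk_max %||% preset$jerk_max,
    float_alpha = float_alpha,
    float_gamma_lo = float_gamma_lo %||% preset$float_gamma_lo,
    float_gamma_hi = float_gamma_hi,
    min_swing_time = min_swing_time %||% preset$min_swing_time,
    min_roll_time = min_roll_time,
    omega_heeloff_thresh_y = omega_heeloff_thresh_y,
    a_heeloff_thresh = a_heeloff_thresh,
    heeloff_omega_exceeds = heeloff_omega_exceeds,
    heeloff_acc_below = heeloff_acc_below,
    omega_threshold_high = omega_threshold_high,
    omega_threshold_low = omega_threshold_low,
    k_to = as.integer(k_to), to_smooth = as.integer(to_smooth),
    jerk_smooth = as.integer(jerk_smooth %||% preset$jerk_smooth),
    peak_window = as.integer(peak_window),
    ic_band = if (!is.null(ic_band) || !missing(ic_band)) ic_band else preset$ic_band,
    omega_ref = omega_ref, adapt_min = adapt_min, adapt_max = adapt_max,
    gap_factor = gap_factor, gravity = gravity,
    alignment = alignment
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$jerk_min < cfg$jerk_max,
    cfg$omega_threshold_low < cfg$omega_threshold_high,
    cfg$min_swing_time > 0, cfg$min_roll_time > 0,
    cfg$float_alpha >= 0, cfg$float_alpha <= 1,
    cfg$float_gamma_lo < cfg$float_gamma_hi,
    length(cfg$a_heeloff_thresh) == 3,
    is.null(cfg$ic_band) || length(cfg$ic_band) == 2,
    cfg$omega_ref > 0, cfg$adapt_min <= cfg$adapt_max
  )
  structure(cfg, class = "detector_config")
}

# trailing moving average of width w (causal, zero history: the first w-1
# outputs are damped rather than under-smoothed, so the startup transient can
# never exceed the steady-state noise floor)
trailing_ma <- function(x, w) {
  if (w <= 1L) {
    return(x)
  }
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / w
}

#' Jerk series of a foot-frame stream
#'
#' First-order backward difference of the z-axis acceleration scaled by the
#' sampling rate (a causal differentiator, suitable for streaming); the first
#' sample is 0. An optional trailing moving average (`cfg$jerk_smooth`)
#' pre-smooths the result.
#'
#' @param stream A rotated (foot-frame) [imu_stream()].
#' @param fs Sampling rate override, Hz.
#' @param smooth Moving-average width in samples; 1 disables.
#' @return Numeric vector, m/s^3, same length as the stream.
#' @export
jerk_series <- function(stream, fs = NULL, smooth = 1L) {
  fs <- stream_fs(stream, fs)
  j <- c(0, diff(stream$az)) * fs
  trailing_ma(j, smooth)
}

#' Update the floating Initial Contact jerk band
#'
#' Each accepted Initial Contact moves the band toward fractions of the
#' current pulse peak: `edge' = (1 - alpha) * edge + alpha * gamma * peak`.
#' With `alpha = 0` the band is fixed; with `alpha = 1` it is replaced by
#' `(gamma_lo * peak, gamma_hi * peak)` outright. Partial updates keep the
#' band robust against single outlier steps.
#'
#' @param band Length-2 numeric, current `(jerk_min, jerk_max)` in m/s^3.
#' @param peak_jerk Peak |jerk| of the current Initial Contact pulse, m/s^3.
#' @param cfg A [detector_config()] supplying `float_alpha`, `float_gamma_lo`,
#'   `float_gamma_hi`.
#' @return Length-2 numeric, the updated band.
#' @export
update_floating_threshold <- function(band, peak_jerk, cfg) {
  stopifnot(peak_jerk > 0)
  a <- cfg$float_alpha
  out <- c(
    (1 - a) * band[1] + a * cfg$float_gamma_lo * peak_jerk,
    (1 - a) * band[2] + a * cfg$float_gamma_hi * peak_jerk
  )
  if (out[1] >= out[2]) {
    abort("floating-threshold update produced jerk_min >= jerk_max (check gammas)")
  }
  out
}

#' Speed-adapt thresholds from the last Toe Off peak
#'
#' The maximum pitch rate observed during the last Toe Off, relative to the
#' reference peak `omega_ref`, yields a clamped adaptation factor
#' `f = clamp(omega_max / omega_ref, adapt_min, adapt_max)`. The two Toe Off
#' thresholds scale by `f` (faster cycles swing faster) and the temporal
#' gates scale by `1/f` (faster cycles have shorter phases).
#'
#' @param omega_max Maximum pitch rate during the last Toe Off, deg/s.
#' @param cfg A [detector_config()].
#' @return List with `factor`, `omega_threshold_high`, `omega_threshold_low`,
#'   `min_swing_time`, `min_roll_time`.
#' @export
adapt_thresholds <- function(omega_max, cfg) {
  if (cfg$omega_ref <= 0) abort("omega_ref must be positive")
  f <- min(max(omega_max / cfg$omega_ref, cfg$adapt_min), cfg$adapt_max)
  list(
    factor = f,
    omega_threshold_high = cfg$omega_threshold_high * f,
    omega_threshold_low = cfg$omega_threshold_low * f,
    min_swing_time = cfg$min_swing_time / f,
    min_roll_time = cfg$min_roll_time / f
  )
}

fsm_states <- c("AwaitIC", "AwaitFC", "AwaitHO", "AwaitTO")
fsm_expected <- c(AwaitIC = "IC", AwaitFC = "FC", AwaitHO = "HO", AwaitTO = "TO")
fsm_next <- c(AwaitIC = "AwaitFC", AwaitFC = "AwaitHO", AwaitHO = "AwaitTO", AwaitTO = "AwaitIC")

#' Step the gait-event finite-state machine
#'
#' Events must occur in the fixed order IC, FC, HO, TO, IC, ...; a candidate
#' whose kind does not match the awaited event is discarded and the state is
#' unchanged.
#'
#' @param state One of `"AwaitIC"`, `"AwaitFC"`, `"AwaitHO"`, `"AwaitTO"`.
#' @param kind Candidate event kind (see [gait_event_kinds]).
#' @return List with `state` (possibly advanced) and `accepted` (logical).
#' @export
step_fsm <- function(state, kind) {
  state <- match.arg(state, fsm_states)
  kind <- match.arg(kind, gait_event_kinds)
  if (identical(unname(fsm_expected[state]), kind)) {
    list(state = unname(fsm_next[state]), accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

first_at_least <- function(flags, from) {
  n <- length(flags)
  if (from > n) {
    return(NA_integer_)
  }
  hit <- which(flags[from:n])
  if (length(hit) == 0) NA_integer_ else as.integer(from + hit[1] - 1L)
}

#' Detect gait events in an IMU stream
#'
#' The full processing chain for one foot sensor: estimate and refresh the
#' sensor-to-foot rotation at every Full Contact ([run_alignment()]), rotate
#' the stream ([align_stream()]), then run the staged event detector under
#' the finite-state machine:
#'
#' 1. **Initial Contact** -- |jerk| of the z acceleration enters the floating
#'    band, no earlier than `min_swing_time` after the previous Toe Off; for
#'    the lyra profile the pitch rate must additionally lie inside `ic_band`.
#'    The band then updates from the pulse peak
#'    ([update_floating_threshold()]).
#' 2. **Full Contact** -- all gyroscope components quiet for `k_fc`
#'    consecutive samples after the IC.
#' 3. **Heel Off** -- pitch rate exceeds its threshold while the three
#'    accelerations (z gravity-corrected) are still quiet, no earlier than
#'    `min_roll_time` after the IC.
#' 4. **Toe Off** -- pitch rate exceeds the high threshold, then decreases
#'    strictly for `k_to` samples, then drops below the low threshold (the
#'    event fires there). The observed peak feeds [adapt_thresholds()].
#'
#' A gait cycle is the span between consecutive accepted ICs; it is valid iff
#' all four events occurred in order within it and it contains no timestamp
#' gap larger than `gap_factor / fs`. Invalid cycles never produce
#' stimulation.
#'
#' @param stream An [imu_stream()] (sensor frame; rotation is handled
#'   internally).
#' @param cfg A [detector_config()].
#' @return An object of class `gait_detection`: list with `events` (tibble
#'   `kind, side, index, t`), `cycles` (tibble with the five event times per
#'   cycle and `valid`), `alignment`, `rotated` (the foot-frame stream),
#'   `trace` (state-transition log: index, t, state entered, adaptation
#'   factor, active band) and `config`.
#' @seealso [tidy.gait_detection()], [glance.gait_detection()],
#'   [autoplot.gait_detection()]
#' @export
detect_gait_events <- function(stream, cfg = detector_config()) {
  validate_imu_stream(stream)
  fs <- stream_fs(stream)
  side <- stream_side(stream)
  aln <- run_alignment(stream, cfg$alignment)
  rot <- align_stream(stream, aln)
  n <- nrow(rot)
  tt <- rot$t

  jerk <- jerk_series(rot, fs = fs, smooth = cfg$jerk_smooth)
  gy_raw <- rot$gy
  gy_to <- trailing_ma(gy_raw, cfg$to_smooth)
  quiet <- quiet_runs(rot, cfg$alignment$omega_fc_thresh)
  dec_run <- run_lengths(c(FALSE, diff(gy_to) < 0))
  gap_after <- c(diff(tt) > cfg$gap_factor / fs, FALSE)

  # precomputed, adaptation-independent conditions
  ho_acc_ok <- abs(rot$ax) < cfg$a_heeloff_thresh[1] &
    abs(rot$ay) < cfg$a_heeloff_thresh[2] &
    abs(rot$az - cfg$gravity) < cfg$a_heeloff_thresh[3]
  if (!cfg$heeloff_acc_below) ho_acc_ok <- !ho_acc_ok
  ho_rot <- abs(gy_raw) > cfg$omega_heeloff_thresh_y
  if (!cfg$heeloff_omega_exceeds) {
    ho_rot <- abs(gy_raw) < cfg$omega_heeloff_thresh_y
  }
  ic_band_ok <- if (is.null(cfg$ic_band)) {
    rep(TRUE, n)
  } else {
    gy_raw >= cfg$ic_band[1] & gy_raw <= cfg$ic_band[2]
  }

  band <- c(cfg$jerk_min, cfg$jerk_max)
  adapt <- adapt_thresholds(cfg$omega_ref, cfg) # f = 1 start
  state <- "AwaitIC"
  last_to_t <- -Inf
  last_ic_t <- -Inf
  ev_kind <- character(0)
  ev_idx <- integer(0)
  trace <- list()
  log_state <- function(i, st, f) {
    trace[[length(trace) + 1L]] <<- list(
      index = i, t = tt[i], state = st, factor = f,
      jerk_min = band[1], jerk_max = band[2]
    )
  }

  i <- 1L
  while (i <= n) {
    if (state == "AwaitIC") {
      ok <- abs(jerk) > band[1] & abs(jerk) < band[2] & ic_band_ok
      j <- first_at_least(ok & tt - last_to_t >= adapt$min_swing_time, i)
      if (is.na(j)) break
      peak <- max(abs(jerk[j:min(n, j + cfg$peak_window)]))
      band <- update_floating_threshold(band, peak, cfg)
      ev_kind <- c(ev_kind, "IC")
      ev_idx <- c(ev_idx, j)
      last_ic_t <- tt[j]
      state <- "AwaitFC"
      log_state(j, state, adapt$factor)
      i <- j + 1L
    } else if (state == "AwaitFC") {
      ic <- ev_idx[length(ev_idx)]
      j <- first_at_least(quiet >= cfg$alignment$k_fc, max(i, ic + cfg$alignment$k_fc))
      if (is.na(j)) break
      ev_kind <- c(ev_kind, "FC")
      ev_idx <- c(ev_idx, j)
      state <- "AwaitHO"
      log_state(j, state, adapt$factor)
      i <- j + 1L
    } else if (state == "AwaitHO") {
      j <- first_at_least(
        ho_rot & ho_acc_ok & tt - last_ic_t >= adapt$min_roll_time, i
      )
      if (is.na(j)) break
      ev_kind <- c(ev_kind, "HO")
      ev_idx <- c(ev_idx, j)
      state <- "AwaitTO"
      log_state(j, state, adapt$factor)
      i <- j + 1L
    } else { # AwaitTO: three conditions satisfied sequentially
      j1 <- first_at_least(gy_to > adapt$omega_threshold_high, i)
      if (is.na(j1)) break
      j2 <- first_at_least(dec_run >= cfg$k_to, j1 + 1L)
      if (is.na(j2)) break
      j3 <- first_at_least(gy_to < adapt$omega_threshold_low, j2)
      if (is.na(j3)) break
      omega_max <- max(gy_to[j1:j3])
      adapt <- adapt_thresholds(omega_max, cfg)
      ev_kind <- c(ev_kind, "TO")
      ev_idx <- c(ev_idx, j3)
      last_to_t <- tt[j3]
      state <- "AwaitIC"
      log_state(j3, state, adapt$factor)
      i <- j3 + 1L
    }
  }

  events <- tibble(
    kind = ev_kind, side = side, index = ev_idx, t = tt[ev_idx]
  )
  cycles <- assemble_cycles(events, tt, gap_after)
  structure(
    list(
      events = events, cycles = cycles, alignment = aln, rotated = rot,
      trace = dplyr::bind_rows(lapply(trace, as_tibble)),
      config = cfg, fs = fs, side = side
    ),
    class = "gait_detection"
  )
}

# group the accepted event sequence (IC FC HO TO)* into IC-to-IC cycles
assemble_cycles <- function(events, tt, gap_after) {
  ic_pos <- which(events$kind == "IC")
  if (length(ic_pos) < 2) {
    return(tibble(
      cycle = integer(0), side = character(0),
      t_ic = double(0), t_fc = double(0), t_ho = double(0), t_to = double(0),
      t_ic_next = double(0), ic_index = integer(0), valid = logical(0)
    ))
  }
  out <- vector("list", length(ic_pos) - 1L)
  for (k in seq_len(length(ic_pos) - 1L)) {
    span <- events[ic_pos[k]:ic_pos[k + 1L], ]
    complete <- identical(span$kind, c("IC", "FC", "HO", "TO", "IC"))
    has_gap <- any(gap_after[span$index[1]:(span$index[nrow(span)] - 1L)])
    out[[k]] <- tibble(
      cycle = k, side = span$side[1],
      t_ic = span$t[1],
      t_fc = if (complete) span$t[2] else NA_real_,
      t_ho = if (complete) span$t[3] else NA_real_,
      t_to = if (complete) span$t[4] else NA_real_,
      t_ic_next = span$t[nrow(span)],
      ic_index = span$index[1],
      valid = complete && !has_gap
    )
  }
  dplyr::bind_rows(out)
}
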