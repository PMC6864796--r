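test_that("jerk is the backward difference of z acceleration times fs", {
  expect_equal(jerk_series(quiet_stream(100)), rep(0, 100))
  # a +2 m/s^2 step between consecutive samples at 500 Hz -> 1000 m/s^3
  s <- make_stream(10, az = c(rep(9.81, 5), rep(11.81, 5)))
  j <- jerk_series(s, smooth = 1)
  expect_equal(j[6], 1000)
  expect_equal(j[-6], rep(0, 9))
  # simulated IC pulse: peak within 5% of the analytic value amp*pi/width
  sim <- simulate_gait(
    n_cycles = 3, ic_jerk_amp = 400, noise_sd_acc = 0, noise_sd_gyr = 0
  )
  j <- jerk_series(sim$truth$canonical, smooth = 1)
  expect_equal(max(j), 400, tolerance = 0.05)
})

test_that("floating threshold blends toward fractions of the current peak", {
  cfg0 <- detector_config(float_alpha = 0, float_gamma_lo = 0.5, float_gamma_hi = 1.5)
  expect_equal(update_floating_threshold(c(100, 900), 5000, cfg0), c(100, 900))
  cfg1 <- detector_config(float_alpha = 1, float_gamma_lo = 0.5, float_gamma_hi = 1.5)
  expect_equal(update_floating_threshold(c(100, 900), 1000, cfg1), c(500, 1500))
  # repeated identical peaks: geometric convergence with ratio (1 - alpha)
  cfg <- detector_config(float_alpha = 0.3, float_gamma_lo = 0.5, float_gamma_hi = 1.5)
  band <- c(100, 900)
  errs <- numeric(6)
  for (i in 1:6) {
    band <- update_floating_threshold(band, 1000, cfg)
    errs[i] <- abs(band[1] - 500)
  }
  expect_equal(errs[-1] / errs[-6], rep(0.7, 5), tolerance = 1e-9)
  # an update that would invert the band is a config error
  bad <- detector_config(float_alpha = 1)
  bad$float_gamma_lo <- 1.5
  bad$float_gamma_hi <- 1.6
  bad$float_gamma_lo <- 2 # force inversion against gamma_hi
  expect_error(update_floating_threshold(c(1, 2), 100, bad), "jerk_min")
})

test_that("threshold adaptation scales thresholds up and gates down", {
  cfg <- detector_config(omega_ref = 300, adapt_min = 0.5, adapt_max = 2)
  a1 <- adapt_thresholds(300, cfg)
  expect_equal(a1$factor, 1)
  expect_equal(a1$omega_threshold_high, cfg$omega_threshold_high)
  expect_equal(a1$min_swing_time, cfg$min_swing_time)
  a2 <- adapt_thresholds(600, cfg)
  expect_equal(a2$factor, 2)
  expect_equal(a2$omega_threshold_high, 2 * cfg$omega_threshold_high)
  expect_equal(a2$omega_threshold_low, 2 * cfg$omega_threshold_low)
  expect_equal(a2$min_swing_time, cfg$min_swing_time / 2)
  expect_equal(a2$min_roll_time, cfg$min_roll_time / 2)
  expect_equal(adapt_thresholds(3000, cfg)$factor, 2) # clamped
  expect_equal(adapt_thresholds(10, cfg)$factor, 0.5)
})

test_that("the FSM only accepts the awaited event kind", {
  expect_false(step_fsm("AwaitFC", "HO")$accepted)
  expect_equal(step_fsm("AwaitFC", "HO")$state, "AwaitFC")
  st <- step_fsm("AwaitIC", "IC")
  expect_true(st$accepted)
  expect_equal(st$state, "AwaitFC")
  # full tour
  st <- "AwaitIC"
  for (k in c("IC", "FC", "HO", "TO")) {
    r <- step_fsm(st, k)
    expect_true(r$accepted)
    st <- r$state
  }
  expect_equal(st, "AwaitIC")
})

test_that("clean signals yield complete, well-timed detections", {
  for (speed in c(1.2, 1.5, 1.7)) {
    sim <- simulate_gait(
      n_cycles = 8, cycle_duration = speed_to_cycle_duration(speed),
      noise_sd_acc = 0, noise_sd_gyr = 0
    )
    det <- detect_gait_events(sim$stream, detector_config("lokomat"))
    expect_true(all(det$cycles$valid))
    m <- match_steps(det, sim$truth$cycles$t_ic)
    expect_equal(m$n_incorrect, 0)
    expect_equal(m$n_missed, 0)
    # detected ICs within 20 ms of ground truth
    ic_det <- det$events$t[det$events$kind == "IC"]
    ic_ref <- sim$truth$events$t[sim$truth$events$kind == "IC"]
    expect_lt(max(abs(ic_det[seq_along(ic_ref)] - ic_ref)), 0.020)
    # HO/TO fire after their ground-truth onsets (threshold-crossing lag),
    # within physiological bounds
    for (kind in c("HO", "TO")) {
      d <- det$events$t[det$events$kind == kind]
      r <- sim$truth$events$t[sim$truth$events$kind == kind]
      lag <- d[seq_along(r)] - r
      expect_true(all(lag >= 0))
      expect_lt(max(lag), 0.35 * speed_to_cycle_duration(speed))
    }
  }
})

test_that("temporal gates suppress early events", {
  # a second jerk spike right after a cycle's IC must not fire (min swing)
  sim <- simulate_gait(n_cycles = 5, noise_sd_acc = 0, noise_sd_gyr = 0)
  spiked <- inject_disturbance(sim$stream, "spike", at = 2 + 1.2 + 0.03, jerk_amp = 400)
  det <- detect_gait_events(spiked, detector_config("lokomat"))
  ics <- det$events$t[det$events$kind == "IC"]
  tos <- det$events$t[det$events$kind == "TO"]
  for (ic in ics[-1]) {
    prev_to <- max(tos[tos < ic])
    expect_gte(ic - prev_to, 0.099) # min_swing_time at factor ~1
  }
  # pure rest: no cycles, no accepted events beyond FSM suppression
  rest <- simulate_gait(n_cycles = 0, rest_lead = 3, rest_tail = 0, seed = 8)
  det0 <- detect_gait_events(rest$stream, detector_config("lokomat"))
  expect_equal(nrow(det0$cycles), 0)
  expect_equal(nrow(det0$events), 0)
})

test_that("heel-off needs rotation with quiet accelerations", {
  sim <- simulate_gait(n_cycles = 6, noise_sd_acc = 0, noise_sd_gyr = 0)
  det <- detect_gait_events(sim$stream, detector_config("lokomat"))
  rot <- det$rotated
  hos <- det$events[det$events$kind == "HO", ]
  expect_gt(nrow(hos), 0)
  for (i in hos$index) {
    expect_gt(abs(rot$gy[i]), 15)
    expect_lt(abs(rot$ax[i]), 3)
    expect_lt(abs(rot$az[i] - 9.81), 3)
  }
  # with an impossible acceleration threshold the event never fires
  cfg_tight <- detector_config("lokomat", a_heeloff_thresh = c(1e-9, 1e-9, 1e-9))
  det2 <- detect_gait_events(sim$stream, cfg_tight)
  expect_equal(sum(det2$events$kind == "HO"), 0)
})

test_that("toe-off needs its three conditions sequentially", {
  sim <- simulate_gait(n_cycles = 6, noise_sd_acc = 0, noise_sd_gyr = 0)
  # peak below the high threshold: no TO at all
  low <- simulate_gait(
    n_cycles = 6, swing_peak_omega = 150, noise_sd_acc = 0, noise_sd_gyr = 0
  )
  det_low <- detect_gait_events(
    low$stream, detector_config("lokomat", adapt_min = 1, adapt_max = 1)
  )
  expect_equal(sum(det_low$events$kind == "TO"), 0)
  # normal peak: TO fires at the low-threshold crossing after the peak
  det <- detect_gait_events(sim$stream, detector_config("lokomat"))
  tos <- det$events[det$events$kind == "TO", ]
  expect_gt(nrow(tos), 0)
  gy <- trailing_ma_ref(det$rotated$gy, 5)
  f <- det$trace$factor # adaptation stays within ~0.1% of 1 here
  expect_true(all(abs(f - 1) < 0.005))
  for (i in tos$index) {
    expect_lt(gy[i], 150)      # below the low threshold at the event
    expect_gt(gy[i - 1], 148)  # the sample before sat at/above it
    expect_lt(gy[i], gy[i - 1]) # on the decreasing flank
  }
})

test_that("faster cycles never lengthen the swing gate", {
  cfg <- detector_config("lokomat")
  peaks <- c(200, 300, 450, 600)
  gates <- vapply(peaks, function(p) adapt_thresholds(p, cfg)$min_swing_time, numeric(1))
  expect_true(all(diff(gates) <= 0))
  # end-to-end: a faster simulated swing lowers the realized gate
  fast <- simulate_gait(n_cycles = 6, swing_peak_omega = 420,
                        noise_sd_acc = 0, noise_sd_gyr = 0)
  det_fast <- detect_gait_events(fast$stream, cfg)
  slow <- simulate_gait(n_cycles = 6, swing_peak_omega = 300,
                        noise_sd_acc = 0, noise_sd_gyr = 0)
  det_slow <- detect_gait_events(slow$stream, cfg)
  expect_gt(
    tail(det_fast$trace$factor, 1), tail(det_slow$trace$factor, 1)
  )
})

test_that("the lyra angular-velocity band rejects late-swing jerk spikes", {
  sim <- simulate_gait(
    n_cycles = 10, cycle_duration = 1.4, profile = "lyra",
    spurious_spike_rate = 2, mounting = TRUE, seed = 13
  )
  with_band <- detect_gait_events(sim$stream, detector_config("lyra"))
  without <- detect_gait_events(sim$stream, detector_config("lyra", ic_band = NULL))
  ref <- sim$truth$cycles$t_ic
  m_with <- match_steps(with_band, ref)
  m_without <- match_steps(without, ref)
  expect_equal(type1_error(m_with$n_reference, m_with$n_incorrect), 0)
  expect_gt(type1_error(m_without$n_reference, m_without$n_incorrect), 0)
})

test_that("dropouts invalidate the spanned cycle and detection recovers", {
  sim <- simulate_gait(
    n_cycles = 12, mounting = TRUE, seed = 5, dropout = c(7.5, 5)
  )
  det <- detect_gait_events(sim$stream, detector_config("lokomat"))
  gap_cycle <- det$cycles[det$cycles$t_ic < 7.5 & det$cycles$t_ic_next > 12, ]
  expect_equal(nrow(gap_cycle), 1)
  expect_false(gap_cycle$valid)
  after <- det$cycles[det$cycles$t_ic > 12.5, ]
  expect_gt(nrow(after), 0)
  expect_true(all(after$valid))
})

test_that("tidy, glance and the debug trace describe the run", {
  sim <- simulate_gait(n_cycles = 4, seed = 3)
  det <- detect_gait_events(sim$stream, detector_config("lokomat"))
  ev <- tidy(det)
  expect_named(ev, c("kind", "side", "index", "t"))
  cyc <- tidy(det, "cycles")
  expect_true(all(c("t_ic", "valid") %in% names(cyc)))
  g <- glance(det)
  expect_equal(g$n_events, nrow(ev))
  expect_equal(nrow(det$trace), nrow(ev)) # one state transition per event
  expect_true(all(det$trace$jerk_min < det$trace$jerk_max))
})
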