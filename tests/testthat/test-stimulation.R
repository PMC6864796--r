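test_that("the default timing chart carries the eight stimulation channels", {
  chart <- default_timing_chart()
  expect_equal(nrow(chart), 8)
  row <- function(m, s) chart[chart$muscle == m & chart$side == s, ]
  expect_equal(row("gastrocnemius", "right")$start_pct, 60)
  expect_equal(row("gastrocnemius", "right")$stop_pct, 100)
  expect_equal(row("quadriceps_femoris", "left")$start_pct, 90)
  expect_equal(row("quadriceps_femoris", "left")$stop_pct, 16)
  # wrap-around entries span the cycle boundary; e.g. 90 -> 16 lasts 26%
  wrap <- chart$start_pct > chart$stop_pct
  expect_equal(sum(wrap), 3) # quadriceps, biceps femoris, tibialis (left)
  expect_true(all(((chart$stop_pct - chart$start_pct) %% 100) > 0))
})

test_that("timing chart CSV round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_timing_chart(default_timing_chart(), path)
  expect_equal(
    as.data.frame(read_timing_chart(path)),
    as.data.frame(default_timing_chart())
  )
  bad <- default_timing_chart()
  bad$start_pct[1] <- 120
  expect_error(write_timing_chart(bad, path), "\\[0, 100\\]")
})

test_that("phase percent interpolates through the event anchors", {
  cyc <- tibble::tibble(
    t_ic = 10, t_fc = 10.08, t_ho = 10.4, t_to = 10.6, t_ic_next = 11
  )
  expect_equal(phase_percent(cyc, 10), 0)
  expect_equal(phase_percent(cyc, 11), 100)
  expect_equal(phase_percent(cyc, 10.5), 50) # midpoint of HO (40) and TO (60)
  expect_error(phase_percent(cyc, 11.5), "outside")
  # inverse consistency across the whole cycle
  ts <- seq(10, 11, by = 0.01)
  expect_equal(percent_to_time(cyc, phase_percent(cyc, ts)), ts, tolerance = 1e-12)
})

test_that("schedules fire at chart percentages of each valid cycle", {
  sim <- simulate_gait(n_cycles = 12, cycle_duration = 1.2, seed = 2, mounting = TRUE)
  det <- detect_gait_events(sim$stream, detector_config("lokomat"))
  sch <- build_schedule(det, default_timing_chart())
  # left-side stream: the four left chart entries are scheduled
  expect_setequal(unique(sch$side), "left")
  expect_equal(length(unique(sch$muscle)), 4)
  # left gastrocnemius switches on at 10% of each scheduled cycle
  cyc <- det$cycles
  gas <- sch[sch$muscle == "gastrocnemius", ]
  for (i in seq_len(nrow(gas))) {
    k <- gas$cycle[i]
    d_prev <- cyc$t_ic[cyc$cycle == k] - cyc$t_ic[cyc$cycle == k - 1]
    expect_equal(
      (gas$on_time[i] - cyc$t_ic[cyc$cycle == k]) / d_prev * 100, 10,
      tolerance = 1e-9
    )
  }
  # wrap-around entry crosses the cycle boundary with ~26% duration
  quad <- sch[sch$muscle == "quadriceps_femoris", ]
  cyc_of <- function(k) cyc[cyc$cycle == k, ]
  for (i in seq_len(nrow(quad))) {
    k <- quad$cycle[i]
    expect_gt(quad$off_time[i], cyc_of(k)$t_ic_next - 0.05)
    d_prev <- cyc$t_ic[cyc$cycle == k] - cyc$t_ic[cyc$cycle == k - 1]
    expect_equal((quad$off_time[i] - quad$on_time[i]) / d_prev, 0.26,
      tolerance = 1e-9
    )
  }
  # per-channel intervals never overlap
  for (m in unique(sch$muscle)) {
    ch <- sch[sch$muscle == m, ]
    ch <- ch[order(ch$on_time), ]
    if (nrow(ch) > 1) expect_true(all(ch$on_time[-1] >= ch$off_time[-nrow(ch)]))
  }
  # idempotent on the same cycle list
  expect_identical(
    as.data.frame(build_schedule(det$cycles)), as.data.frame(sch)
  )
})

test_that("on-fraction over uniform cycles converges to the chart fraction", {
  n <- 40
  cycles <- tibble::tibble(
    cycle = 1:n, side = "left",
    t_ic = 1.2 * (0:(n - 1)), t_fc = t_ic + 0.1, t_ho = t_ic + 0.48,
    t_to = t_ic + 0.72, t_ic_next = t_ic + 1.2, valid = TRUE
  )
  sch <- build_schedule(cycles, default_timing_chart())
  for (m in unique(sch$muscle)) {
    ch <- sch[sch$muscle == m, ]
    ent <- default_timing_chart()
    ent <- ent[ent$muscle == m & ent$side == "left", ]
    frac <- sum(ch$off_time - ch$on_time) / (1.2 * (n - 1))
    expect_equal(frac, ((ent$stop_pct - ent$start_pct) %% 100) / 100,
      tolerance = 0.03
    )
  }
})

test_that("invalid and first cycles never produce stimulation", {
  cycles <- tibble::tibble(
    cycle = 1:4, side = "left",
    t_ic = c(0, 1.2, 2.4, 3.6), t_fc = t_ic + 0.1, t_ho = t_ic + 0.48,
    t_to = t_ic + 0.72, t_ic_next = t_ic + 1.2,
    valid = c(TRUE, TRUE, FALSE, TRUE)
  )
  sch <- build_schedule(cycles, default_timing_chart())
  expect_false(1 %in% sch$cycle) # no previous duration known
  expect_false(3 %in% sch$cycle) # invalid cycle: safety
  expect_setequal(unique(sch$cycle), c(2, 4))
  # zero valid cycles / empty chart -> empty schedule, not an error
  none <- cycles
  none$valid <- FALSE
  expect_equal(nrow(build_schedule(none)), 0)
  expect_equal(nrow(build_schedule(cycles, default_timing_chart()[0, ])), 0)
})

test_that("stimulator bounds accept and reject exactly at the device limits", {
  expect_equal(nrow(validate_stim_params(130, 50, 500)), 0) # maxima
  expect_equal(nrow(validate_stim_params(0, 10, 20)), 0) # minima
  expect_equal(nrow(validate_stim_params(125, 35, 490)), 0)
  v <- validate_stim_params(135, 50, 500) # just above the current bound
  expect_true(any(v$parameter == "current"))
  expect_true(any(grepl("130", v$constraint)))
  v2 <- validate_stim_params(10, 33, 500) # frequency off the 5 Hz grid
  expect_equal(v2$parameter, "frequency")
  expect_true(grepl("step", v2$constraint))
  v3 <- validate_stim_params(10, 5, 515)
  expect_setequal(v3$parameter, c("frequency", "pulse_width"))
})
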