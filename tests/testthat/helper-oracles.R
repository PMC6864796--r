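# Shared fixtures and independent oracles, built in code at test time.

# quiet stream: constant gravity, zero rotation
quiet_stream <- function(n = 200, fs = 500, acc = c(0, 0, 9.81)) {
  imu_stream(tibble::tibble(
    t = (seq_len(n) - 1) / fs,
    ax = acc[1], ay = acc[2], az = acc[3],
    gx = 0, gy = 0, gz = 0
  ), fs = fs)
}

# stream from explicit channel vectors (recycled)
make_stream <- function(n, fs = 500, ax = 0, ay = 0, az = 9.81,
                        gx = 0, gy = 0, gz = 0) {
  imu_stream(tibble::tibble(
    t = (seq_len(n) - 1) / fs,
    ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
    gx = rep_len(gx, n), gy = rep_len(gy, n), gz = rep_len(gz, n)
  ), fs = fs)
}

# exhaustive maximum one-to-one matching count (oracle for match_steps);
# exponential recursion, for <= 10 events only
brute_force_max_matching <- function(detected, reference, tol) {
  recurse <- function(i, used) {
    if (i > length(detected)) {
      return(0L)
    }
    best <- recurse(i + 1L, used) # leave detected[i] unmatched
    for (j in seq_along(reference)) {
      if (!used[j] && abs(detected[i] - reference[j]) <= tol) {
        used2 <- used
        used2[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used2))
      }
    }
    best
  }
  recurse(1L, rep(FALSE, length(reference)))
}

# direct (lag-looped) cross-correlation maximum, independent of convolve()
xcorr_max_direct <- function(x, y, max_lag = length(x)) {
  best <- -Inf
  for (lag in -max_lag:max_lag) {
    s <- 0
    for (i in seq_along(x)) {
      j <- i + lag
      if (j >= 1 && j <= length(y)) s <- s + x[i] * y[j]
    }
    best <- max(best, s)
  }
  best
}

# accepted event kinds must spell a prefix of (IC FC HO TO)*
is_valid_event_sequence <- function(kinds) {
  if (length(kinds) == 0) {
    return(TRUE)
  }
  expected <- rep(c("IC", "FC", "HO", "TO"), length.out = length(kinds))
  identical(kinds, expected)
}

expect_proper_rotation <- function(R, tol = 1e-9) {
  expect_lt(max(abs(R %*% t(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}

# reference trailing moving average (independent loop implementation,
# zero history before the first sample)
trailing_ma_ref <- function(x, w) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1L, i - w + 1L)
    out[i] <- sum(x[lo:i]) / w
  }
  out
}
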