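test_that("the smoother preserves polynomials of degree <= 4", {
  tvec <- seq(0, 2, by = 0.01)
  for (p in list(function(t) rep(3, length(t)),
                 function(t) 2 - 0.5 * t,
                 function(t) t^4 - 2 * t^2 + t)) {
    x <- p(tvec)
    sm <- savgol_smooth(x, filter_config())
    interior <- 21:(length(x) - 20)
    expect_lt(max(abs(sm[interior] - x[interior]) /
                    pmax(abs(x[interior]), 1)), 1e-10)
  }
})

test_that("the interior output equals an explicit local quartic fit", {
  set.seed(3)
  x <- sin(seq(0, 3, by = 0.01)) + rnorm(301, sd = 0.05)
  sm <- savgol_smooth(x, filter_config())
  i <- 150
  win <- (i - 20):(i + 20)
  fit <- lm(x[win] ~ poly(seq(-20, 20), 4, raw = TRUE))
  expect_equal(sm[i], unname(predict(fit)[21]), tolerance = 1e-9)
})

test_that("smoothing strictly reduces white-noise variance", {
  set.seed(9)
  x <- rnorm(2000)
  expect_lt(var(savgol_smooth(x, filter_config())), var(x))
})

test_that("velocity from the polynomial coefficients matches analytic derivatives", {
  cfg <- filter_config()
  tvec <- seq(0, 3, by = 0.01)
  interior <- 21:(length(tvec) - 20)
  # linear ramp: slope recovered exactly
  ramp <- cbind(0.7 * tvec, 0, 0)
  out <- savgol_velocity(ramp, cfg)
  expect_equal(out$speed[interior], rep(0.7, length(interior)),
               tolerance = 1e-10)
  # cubic position: derivative 3 t^2
  cub <- cbind(tvec^3, 0, 0)
  out <- savgol_velocity(cub, cfg)
  expect_lt(max(abs(out$velocity[interior, 1] - 3 * tvec[interior]^2)), 1e-9)
  # circular motion at 0.5 Hz: speed r * omega to 0.1%
  r <- 0.3; omega <- pi
  circ <- cbind(r * cos(omega * tvec), r * sin(omega * tvec), 0)
  out <- savgol_velocity(circ, cfg)
  expect_lt(max(abs(out$speed[interior] - r * omega)) / (r * omega), 1e-3)
})

test_that("series shorter than the window are rejected", {
  expect_error(savgol_smooth(rnorm(40), filter_config()), "shorter")
  expect_error(filter_config(window_length = 40), "odd")
  expect_error(filter_config(poly_order = 41), "smaller")
})

brute_onset <- function(speed, pk, fraction = 0.05) {
  thr <- fraction * speed[pk]
  for (i in pk:1) if (speed[i] <= thr) return(i)
  1L
}
brute_contact <- function(speed, pk, fraction = 0.05) {
  thr <- fraction * speed[pk]
  for (i in pk:length(speed)) if (speed[i] <= thr) return(i)
  length(speed)
}

test_that("onset is the last at-threshold sample before the rise", {
  # bell jumps straight above the 5% threshold, so onset is the last zero
  speed <- c(rep(0, 10), 1 + dodgekin:::mj_vel(seq(0.01, 0.99, by = 0.01)), 0)
  pk <- which.max(speed)
  expect_equal(as.integer(detect_onset(speed, pk)), 10L)
})

test_that("onset/contact equal exhaustive threshold scans on minimum-jerk reaches", {
  for (dur in c(0.3, 0.5, 0.9)) {
    speed <- padded_mj_speed(duration = dur)
    pk <- which.max(speed)
    expect_equal(as.integer(detect_onset(speed, pk)), brute_onset(speed, pk))
    expect_equal(as.integer(detect_contact(speed, pk)), brute_contact(speed, pk))
  }
})

test_that("a symmetric bell gives onset and contact equidistant from the peak", {
  speed <- padded_mj_speed(duration = 0.5)
  pk <- which.max(speed)
  on <- as.integer(detect_onset(speed, pk))
  ct <- as.integer(detect_contact(speed, pk))
  expect_equal(pk - on, ct - pk)
})

test_that("degenerate speed profiles return the boundary with a warning", {
  always_up <- seq(1, 2, length.out = 50)
  expect_warning(on <- detect_onset(always_up, 50L), "threshold")
  expect_equal(as.integer(on), 1L)
  expect_false(attr(on, "found"))
  expect_warning(ct <- detect_contact(always_up, 1L), "threshold")
  expect_equal(as.integer(ct), 50L)
  expect_error(detect_onset(numeric(0), 1L), "empty")
})

test_that("raising the threshold fraction never moves onset earlier nor contact later", {
  set.seed(21)
  for (i in 1:20) {
    speed <- padded_mj_speed(duration = runif(1, 0.3, 0.8)) +
      abs(rnorm(1, sd = 1e-4))
    pk <- which.max(speed)
    ons <- vapply(c(0.02, 0.05, 0.10, 0.20), function(f)
      as.integer(suppressWarnings(detect_onset(speed, pk, f))), integer(1))
    cts <- vapply(c(0.02, 0.05, 0.10, 0.20), function(f)
      as.integer(suppressWarnings(detect_contact(speed, pk, f))), integer(1))
    expect_true(all(diff(ons) >= 0))
    expect_true(all(diff(cts) <= 0))
    expect_true(all(ons <= pk & pk <= cts))
  }
})

test_that("movement time converts onset-to-contact samples to milliseconds", {
  expect_equal(movement_time(reach_event(10, 30, 58, 2), 100), 480)
  expect_equal(movement_time(reach_event(5, 5, 5, 1), 100), 0)
  expect_equal(movement_time(reach_event(1, 40, 67, 2), 100), 660)
  expect_error(reach_event(10, 5, 20, 1), "onset <= peak <= contact")
  expect_error(reach_event(1, 2, 3, 0), "positive")
})
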