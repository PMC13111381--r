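# Filtering, cutoff selection, synchronisation, local frame and
# body-weight normalisation.

test_that("zero-phase Butterworth passes DC and separates pass/stop bands", {
  # DC
  y <- butterworth_lowpass(rep(5, 300), fc = 10, fs = 300)
  expect_lt(max(abs(y - 5)), 1e-6)

  # 1 Hz sine through a 12 Hz filter: central attenuation < 1%
  # (analytic dual-pass magnitude at 1 Hz: (1 + (1/12)^4)^-2 ~ 0.9999)
  t <- seq(0, 3, by = 1 / 300)
  x <- sin(2 * pi * 1 * t)
  y <- butterworth_lowpass(x, fc = 12, fs = 300)
  ctr <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_gt(max(abs(y[ctr])) / max(abs(x[ctr])), 0.99)

  # 60 Hz sine through the same filter: central amplitude < 1% of input
  x60 <- sin(2 * pi * 60 * t)
  y60 <- butterworth_lowpass(x60, fc = 12, fs = 300)
  expect_lt(max(abs(y60[ctr])), 0.01)
})

test_that("filtering a symmetric pulse does not shift its peak", {
  n <- 601
  x <- exp(-((seq_len(n) - 301) / 30)^2)
  y <- butterworth_lowpass(x, fc = 8, fs = 300)
  expect_lt(abs(which.max(y) - which.max(x)), 1 + 1e-9)
})

test_that("Butterworth rejects bad cutoffs and short series", {
  expect_error(butterworth_lowpass(rnorm(100), fc = 150, fs = 300),
               "Nyquist")
  expect_error(butterworth_lowpass(rnorm(100), fc = 0, fs = 300),
               "invalid parameter")
  expect_error(butterworth_lowpass(rnorm(5), fc = 10, fs = 300),
               "insufficient data")
})

test_that("residual method finds the noise floor", {
  # pure noise: nothing to preserve, cutoff at the bottom of the grid
  set.seed(9)
  fc <- residual_cutoff(rnorm(900, sd = 0.002), fs = 300)
  expect_lte(fc, 3)

  # 2 Hz signal + noise: cutoff preserves the signal band, inside the
  # 9-15 Hz clip range used for marker data for >= 95% of seeds
  hits <- 0L
  t <- (0:899) / 300
  for (s in 1:100) {
    set.seed(s)
    x <- sin(2 * pi * 2 * t) + rnorm(900, sd = 0.002)
    f <- tryCatch(residual_cutoff(x, fs = 300), error = function(e) NA)
    if (!is.na(f) && f >= 2 && f <= 15) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # noiseless signal: no noise floor to extrapolate
  expect_error(residual_cutoff(sin(2 * pi * 2 * t), fs = 300),
               "degenerate signal")
  expect_error(residual_cutoff(rnorm(50), fs = 300), "insufficient data")
})

test_that("force decimation preserves constants, lengths and slow sinusoids", {
  f <- matrix(rep(c(0, 0, 700), each = 900), ncol = 3)
  d <- resample_to_rate(f, 900, 300)
  expect_equal(nrow(d), 300L)
  expect_lt(max(abs(d[, 3] - 700)), 1e-9)
  expect_true(all(abs(d[, 1:2]) < 1e-9))

  t <- (0:899) / 900
  x <- sin(2 * pi * 5 * t)
  y <- resample_to_rate(x, 900, 300)
  ref <- sin(2 * pi * 5 * (0:299) / 300)
  ctr <- 75:225
  expect_lt(max(abs(y[ctr] - ref[ctr])), 0.01)

  expect_error(resample_to_rate(x, 900, 250), "integer multiple")
})

test_that("local frame follows the horizontal CM velocity", {
  fr <- local_frame(c(0, 5, -0.2))
  expect_equal(drop(fr$Y), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(drop(fr$Z), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(drop(fr$X), c(1, 0, 0), tolerance = 1e-12)

  fr2 <- local_frame(c(3, 4, 0))
  expect_equal(drop(fr2$Y), c(0.6, 0.8, 0), tolerance = 1e-12)

  expect_error(local_frame(c(0, 0.01, 1)), "near-stationary")
})

test_that("local frames are orthonormal and right-handed for random velocities", {
  set.seed(7)
  v <- cbind(rnorm(200), rnorm(200), rnorm(200))
  v <- v[sqrt(v[, 1]^2 + v[, 2]^2) > 0.2, ]
  fr <- local_frame(v)
  for (ax in list(fr$X, fr$Y, fr$Z))
    expect_lt(max(abs(sqrt(rowSums(ax^2)) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$X * fr$Y))), 1e-9)
  expect_lt(max(abs(rowSums(fr$Y * fr$Z))), 1e-9)
  expect_lt(max(abs(rowSums(fr$X * fr$Z))), 1e-9)
  # right-handedness: X = Y x Z
  yz <- cbind(fr$Y[, 2] * fr$Z[, 3] - fr$Y[, 3] * fr$Z[, 2],
              fr$Y[, 3] * fr$Z[, 1] - fr$Y[, 1] * fr$Z[, 3],
              fr$Y[, 1] * fr$Z[, 2] - fr$Y[, 2] * fr$Z[, 1])
  expect_lt(max(abs(yz - fr$X)), 1e-9)
})

test_that("to_local projects correctly and inverts exactly", {
  fr <- local_frame(c(0, 5, 0))
  expect_equal(drop(to_local(c(0, 0, 1), fr)), c(X = 0, Y = 0, Z = 1),
               tolerance = 1e-12)
  expect_equal(drop(to_local(c(1, 0, 0), fr)), c(X = 1, Y = 0, Z = 0),
               tolerance = 1e-12)
  # frame with Y' = global x: X' = Y' x Z' = (0, -1, 0)
  fr2 <- local_frame(c(5, 0, 0))
  expect_equal(drop(to_local(c(1, 0, 0), fr2)), c(X = 0, Y = 1, Z = 0),
               tolerance = 1e-12)

  set.seed(11)
  v <- cbind(rnorm(50, sd = 3), rnorm(50, sd = 3), rnorm(50))
  v[, 1] <- v[, 1] + 5
  fr3 <- local_frame(v)
  vec <- cbind(rnorm(50), rnorm(50), rnorm(50))
  back <- to_global(to_local(vec, fr3), fr3)
  expect_lt(max(abs(back - vec)), 1e-9)
  # norm preservation
  expect_lt(max(abs(sqrt(rowSums(to_local(vec, fr3)^2)) -
                      sqrt(rowSums(vec^2)))), 1e-9)
})

test_that("body-weight normalisation divides element-wise and inverts", {
  expect_equal(drop(normalize_by_bw(c(0, 0, 700), 700)), c(0, 0, 1))
  expect_equal(normalize_by_bw(1050, 700), 1.5)
  expect_equal(drop(normalize_by_bw(c(0, 0, 0), 123)), c(0, 0, 0))
  x <- c(12.3, -45.6, 78.9)
  expect_identical(normalize_by_bw(x, 700) * 700, x)
  expect_error(normalize_by_bw(1, 0), "invalid parameter")
  expect_error(normalize_by_bw(1, -5), "invalid parameter")
})
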