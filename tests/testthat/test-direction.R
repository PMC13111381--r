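# Sole-normal estimators, component projection, mirroring and the
# linear correction.

test_that("estimate_direction reproduces hand-computed geometries", {
  # flat blade, joint straight above the midpoint: vertical normal
  d1 <- estimate_direction(c(0, 0, 0), c(0.3, 0, 0), c(0.15, 0, 0.40),
                           "est1")
  expect_equal(drop(d1$z_b), c(0, 0, 1), tolerance = 1e-12)

  # off-axis joint: z_b = (0, 0.6, 0.8) after the upward sign fix
  d2 <- estimate_direction(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.3, 0.4),
                           "est2")
  expect_equal(drop(d2$x_b), c(0, -0.8, 0.6), tolerance = 1e-12)
  expect_equal(drop(d2$z_b), c(0, 0.6, 0.8), tolerance = 1e-12)

  # blade along y: literal cross order points down, sign flip restores up
  d3 <- estimate_direction(c(0, 0, 0), c(0, 1, 0), c(0, 0.3, 1), "est1")
  expect_equal(drop(d3$z_b), c(0, 0, 1), tolerance = 1e-12)

  expect_error(estimate_direction(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0)),
               "geometry error")
  expect_error(estimate_direction(c(0, 0, 0), c(0, 0, 0), c(0.5, 0.3, 0.4)),
               "geometry error")
})

test_that("z_b is a unit vector perpendicular to the blade axis", {
  set.seed(3)
  n <- 500
  rear <- cbind(rnorm(n), rnorm(n), runif(n, 0, 0.02))
  dir <- cbind(rnorm(n), rnorm(n), rnorm(n, sd = 0.1))
  dir <- dir / sqrt(rowSums(dir^2))
  front <- rear + 0.3 * dir
  joint <- rear + cbind(rnorm(n, sd = 0.1), rnorm(n, sd = 0.1),
                        runif(n, 0.2, 0.5))
  de <- estimate_direction(rear, front, joint, "est2")
  expect_lt(max(abs(sqrt(rowSums(de$z_b^2)) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(de$z_b * de$y_b))), 1e-9)
  expect_true(all(de$z_b[, 3] > 0))
})

test_that("local components are equivariant under rotations about the vertical", {
  set.seed(5)
  rot_z <- function(m, th) {
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    m %*% t(R)
  }
  rear <- cbind(runif(20), runif(20), 0.01)
  front <- rear + matrix(c(0.28, 0.05, 0.02), 20, 3, byrow = TRUE)
  joint <- rear + matrix(c(0.1, 0.05, 0.45), 20, 3, byrow = TRUE)
  vel <- cbind(rnorm(20, 1), rnorm(20, 5), rnorm(20, 0, 0.2))
  e0 <- to_local(estimate_direction(rear, front, joint)$z_b,
                 local_frame(vel))
  for (th in c(0.7, 2.1, -1.3)) {
    e1 <- to_local(estimate_direction(rot_z(rear, th), rot_z(front, th),
                                      rot_z(joint, th))$z_b,
                   local_frame(rot_z(vel, th)))
    expect_lt(max(abs(e1 - e0)), 1e-9)
  }
})

test_that("longer levers damp marker noise: Est2 beats Est1 angularly", {
  # static blade + joints with the knee lever about twice the ankle
  # lever, 3 mm isotropic noise on all four markers, 1000 draws
  set.seed(123)
  n <- 1000
  rear0 <- c(0, 0, 0); front0 <- c(0.3, 0, 0)
  ankle0 <- c(0.15, 0.03, 0.20)   # lever ~0.25 m
  knee0 <- c(0.15, 0.10, 0.48)    # lever ~0.51 m
  noise <- function(p) matrix(p, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, sd = 0.003), n, 3)
  z_true1 <- estimate_direction(rear0, front0, ankle0, "est1")$z_b
  z_true2 <- estimate_direction(rear0, front0, knee0, "est2")$z_b
  rear <- noise(rear0); front <- noise(front0)
  z1 <- estimate_direction(rear, front, noise(ankle0), "est1")$z_b
  z2 <- estimate_direction(rear, front, noise(knee0), "est2")$z_b
  ang <- function(z, zt) acos(pmin(1, rowSums(z * matrix(zt, n, 3, byrow = TRUE))))
  expect_lt(mean(ang(z2, z_true2)), mean(ang(z1, z_true1)))
})

test_that("grf_components scales the unit direction by the resultant", {
  g <- grf_components(1.5, c(0, 0.6, 0.8))
  expect_equal(drop(g$components), c(X = 0, Y = 0.9, Z = 1.2),
               tolerance = 1e-12)
  expect_equal(drop(grf_components(0, c(0, 0, 1))$components),
               c(X = 0, Y = 0, Z = 0))
  expect_equal(drop(grf_components(1, c(0, 0, 1))$components),
               c(X = 0, Y = 0, Z = 1))
  # uncorrected norm invariant
  set.seed(2)
  e <- cbind(rnorm(30), rnorm(30), abs(rnorm(30)) + 0.5)
  e <- e / sqrt(rowSums(e^2))
  f <- runif(30, 0, 2)
  g2 <- grf_components(f, e)
  expect_lt(max(abs(sqrt(rowSums(g2$components^2)) - f)), 1e-9)
  expect_error(grf_components(1, c(1, 1, 1)), "contract error")
  expect_error(grf_components(-0.1, c(0, 0, 1)), "non-negative")
})

test_that("left-right mirroring negates X' and is an involution", {
  v <- c(0.2, 0.1, 1.0)
  expect_equal(mirror_left(v), c(-0.2, 0.1, 1.0))
  expect_equal(mirror_left(c(0, 0.1, 1.0)), c(0, 0.1, 1.0))
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(mirror_left(mirror_left(m)), m)
})

test_that("the default correction model carries the curve-left coefficients", {
  g0 <- grf_components(0, c(0, 0, 1))     # all-zero components
  suppressWarnings(c0 <- apply_correction(g0))
  expect_equal(drop(c0$components),
               c(X = -0.029, Y = -0.025, Z = 0.030), tolerance = 1e-12)
  one <- matrix(1, 1, 3)
  cc <- apply_correction(one)
  expect_equal(drop(cc), c(X = 0.818, Y = 0.571, Z = 1.017),
               tolerance = 1e-12)
  # scope / method warnings
  est1 <- grf_components(1, c(0, 0, 1), method = "est1")
  expect_warning(apply_correction(est1), "est2")
  est2 <- grf_components(1, c(0, 0, 1), method = "est2")
  expect_warning(apply_correction(est2, motion = "straight"),
                 "curve-left")
  out <- apply_correction(est2, motion = "curve-left")
  expect_true(out$corrected)
  expect_identical(out$method, "est2c")
})

test_that("fit_correction recovers exact and noisy linear relations", {
  est <- seq(-1, 1, length.out = 21)
  m3 <- cbind(est, est, est)
  exact <- fit_correction(0.9 * m3 + 0.1, m3)
  expect_equal(unname(exact$slope), rep(0.9, 3), tolerance = 1e-12)
  expect_equal(unname(exact$intercept), rep(0.1, 3), tolerance = 1e-12)

  ident <- fit_correction(m3, m3)
  expect_equal(unname(ident$slope), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(ident$intercept), rep(0, 3), tolerance = 1e-12)

  set.seed(31)
  est2 <- matrix(runif(600, -1, 1), 200, 3)
  noisy <- fit_correction(0.85 * est2 - 0.03 +
                            matrix(rnorm(600, sd = 0.01), 200, 3), est2)
  expect_true(all(abs(noisy$slope - 0.85) < 0.02))
  expect_true(all(abs(noisy$intercept + 0.03) < 0.01))

  expect_error(fit_correction(m3[1:2, ], m3[1:2, ]), "insufficient data")
  expect_error(fit_correction(m3, 0 * m3), "fit error")
})

test_that("distort_components is the exact inverse of apply_correction", {
  set.seed(8)
  comp <- cbind(runif(40, -0.5, 0.5), runif(40, 0, 0.2), runif(40, 0, 2))
  model <- default_correction_model()
  round_trip <- apply_correction(distort_components(comp, model), model)
  expect_lt(max(abs(round_trip - comp)), 1e-12)
})
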