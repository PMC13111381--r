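# Phase segmentation, force-plate frame selection and 20/60/20
# normalisation.

test_that("phases cover the supporting period with the one-frame-before rule", {
  ev <- blade_events(0.00, 0.16, 0.76, 0.92)
  t <- (0:299) / 300
  seg <- segment_phases(ev, t)
  counts <- table(seg$phase)
  expect_equal(unname(counts["contact"]), 48L)
  expect_equal(unname(counts["single_support"]), 180L)
  expect_equal(unname(counts["push_off"]), 48L)
  # raw phase fractions of the supporting period: 17.4 / 65.2 / 17.4%
  expect_equal(0.16 / 0.92 * 100, 17.4, tolerance = 0.01)
  expect_equal(0.60 / 0.92 * 100, 65.2, tolerance = 0.01)

  # instantaneous opposite off/on: empty single support, no error
  ev2 <- blade_events(0.00, 0.40, 0.40, 0.80)
  seg2 <- segment_phases(ev2, t)
  expect_equal(sum(seg2$phase == "single_support"), 0L)

  expect_error(blade_events(0.1, 0.05, 0.5, 0.9), "analyzed_on")
  expect_error(blade_events(0, 0.3, 0.2, 0.9), "opposite_off")
})

test_that("analyzable frames require the analysed blade alone on the plate", {
  plate <- c(0, 0.6, 0, 5.4)
  one <- function(x1, y1, x2, y2) list(r = cbind(x1, y1), f = cbind(x2, y2))
  # analysed blade inside, opposite airborne (single support)
  a <- one(0.2, 1.0, 0.2, 1.3)
  expect_true(analyzable_mask(a$r, a$f, opposite_airborne = TRUE,
                              plate = plate))
  # opposite blade grounded but entirely outside the plate
  o <- one(0.9, 2.0, 0.9, 2.3)
  expect_true(analyzable_mask(a$r, a$f, o$r, o$f,
                              opposite_airborne = FALSE, plate = plate))
  # analysed blade straddling the plate edge
  s <- one(0.5, -0.1, 0.5, 0.2)
  expect_false(analyzable_mask(s$r, s$f, opposite_airborne = TRUE,
                               plate = plate))
  # both blades fully on the plate
  b <- one(0.4, 2.0, 0.4, 2.3)
  expect_false(analyzable_mask(a$r, a$f, b$r, b$f,
                               opposite_airborne = FALSE, plate = plate))
  expect_error(analyzable_mask(a$r, a$f, opposite_airborne = TRUE,
                               plate = c(1, 0, 0, 5)), "geometry error")
})

test_that("phase normalisation maps phases onto the 20/60/20 bands", {
  ev <- blade_events(0.00, 0.16, 0.76, 0.92)
  t <- (0:275) / 300
  seg <- segment_phases(ev, t)

  # constant series stays constant on the full grid
  ns <- phase_normalize(rep(1, length(t)), seg)
  expect_true(all(ns$valid))
  expect_equal(ns$values, rep(1, 101), tolerance = 1e-9)

  # the identity series maps the phase boundaries to the event times
  nt <- phase_normalize(t, seg)
  expect_equal(nt$values[nt$pct == 0], 0, tolerance = 1e-9)
  expect_equal(nt$values[nt$pct == 20], 0.16, tolerance = 1e-9)
  expect_equal(nt$values[nt$pct == 80], 0.76, tolerance = 1e-9)
  # linear within each band
  expect_equal(nt$values[nt$pct == 10], 0.08, tolerance = 1e-6)
  expect_equal(nt$values[nt$pct == 50], 0.46, tolerance = 1e-6)
  expect_equal(nt$values[nt$pct == 90], 0.84, tolerance = 1e-6)
  # monotone time mapping
  expect_true(all(diff(nt$values) > 0))

  # masking out the push-off invalidates grid points 81-100 only
  mask <- seg$phase != "push_off"
  nm <- phase_normalize(t, seg, mask)
  expect_true(all(nm$valid[nm$pct <= 80]))
  expect_true(all(!nm$valid[nm$pct >= 81]))
})

test_that("normalisation is idempotent on proportional 101-point series", {
  # a cubic sampled on an already-normalised grid with 20/60/20
  # proportions re-normalises to itself (splines reproduce cubics)
  tt <- 0:100
  vals <- 2 + 0.03 * tt - 4e-4 * tt^2 + 3e-6 * tt^3
  ev <- blade_events(0, 20, 80, 100)
  seg <- segment_phases(ev, tt)
  # frames 0..19 contact, 20..79 single support, 80..99 push-off
  ns <- phase_normalize(vals, seg)
  keep <- ns$valid
  expect_lt(max(abs(ns$values[keep] - vals[keep])), 1e-9)
})

test_that("aggregation tracks per-point sample sizes", {
  ev <- blade_events(0.00, 0.16, 0.76, 0.92)
  t <- (0:275) / 300
  seg <- segment_phases(ev, t)
  full <- phase_normalize(t, seg)
  partial <- phase_normalize(t, seg, seg$phase != "push_off")
  agg <- aggregate_normalized(list(full, partial, full))
  expect_true(all(agg$n <= 3))
  expect_equal(agg$n[agg$pct == 50], 3L)
  expect_equal(agg$n[agg$pct == 95], 2L)
  expect_equal(agg$mean[agg$pct == 20], 0.16, tolerance = 1e-9)
})
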