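# RMSE, regression, ICC(2,1), Bland-Altman, proportional error, the
# correction trigger and leave-one-participant-out validation.

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(0.1, -0.1)), 0.1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_error(rmse(numeric(0), numeric(0)), "insufficient data")
})

test_that("true-on-estimate regression uses the stated axis orientation", {
  expect_equal(regression_true_on_est(c(1, 2, 3), c(1, 2, 3)),
               list(slope = 1, intercept = 0))
  expect_equal(regression_true_on_est(c(0, 2, 4), c(0, 1, 2)),
               list(slope = 2, intercept = 0))
  r <- regression_true_on_est(c(0.1, 1.0, 1.9), c(0, 1, 2))
  expect_equal(r$slope, 0.9, tolerance = 1e-12)
  expect_equal(r$intercept, 0.1, tolerance = 1e-12)
  expect_error(regression_true_on_est(c(1, 2, 3), c(1, 1, 1)), "fit error")
})

test_that("ICC(2,1) matches hand ANOVA and the Koo & Li bands", {
  perfect <- icc21(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(perfect$value, 1)
  expect_identical(perfect$category, "excellent")
  expect_true(perfect$agreement)

  # constant offset 0.1: MSR = 2, MSC = 0.015, MSE = 0 -> 2/2.01
  hand <- icc21(cbind(c(1, 2, 3), c(1.1, 2.1, 3.1)))
  expect_equal(hand$value, 2 / 2.01, tolerance = 1e-12)
  expect_identical(hand$category, "excellent")

  # reversed ratings: constant row means, hence a degenerate warning too
  rev_ <- suppressWarnings(icc21(cbind(c(1, 2, 3), c(3, 2, 1))))
  expect_lt(rev_$value, 0.5)
  expect_identical(rev_$category, "poor")
  expect_false(rev_$agreement)

  expect_error(icc21(cbind(c(1, 2), c(1, 2))), "insufficient data")
  expect_warning(icc21(cbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")

  expect_identical(icc_category(0.49), "poor")
  expect_identical(icc_category(0.5), "moderate")
  expect_identical(icc_category(0.75), "good")
  expect_identical(icc_category(0.9), "excellent")
})

test_that("ICC(2,1) equals an independent ANOVA computation", {
  set.seed(77)
  for (i in 1:100) {
    m <- matrix(rnorm(10), 5, 2)
    expect_equal(suppressWarnings(icc21(m))$value, icc21_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("Bland-Altman statistics follow their closed forms", {
  ba <- bias_precision_loa(c(0.1, 0.1, 0.1))
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$precision, 0)
  expect_equal(unname(ba$loa), c(0.1, 0.1))
  expect_true(ba$fixed_error)

  ba2 <- bias_precision_loa(c(0.2, 0, -0.2))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$precision, 0.2)
  expect_equal(unname(ba2$loa), c(-0.392, 0.392))
  expect_false(ba2$fixed_error)
  # LoA symmetry about the bias
  expect_equal(unname(ba2$loa[2] - ba2$bias),
               unname(ba2$bias - ba2$loa[1]))

  expect_error(bias_precision_loa(0), "insufficient data")
})

test_that("proportional error detects a slope and respects clusters", {
  set.seed(13)
  means <- runif(20, 0, 1)
  diffs <- 0.5 * means + rnorm(20, sd = 1e-6)
  cl <- rep(paste0("P", 1:4), each = 5)
  pe <- proportional_error(means, diffs, cluster = cl, seed = 99)
  expect_true(pe$flag)
  expect_equal(pe$slope, 0.5, tolerance = 1e-3)
  expect_true(pe$ci[1] <= 0.5 && 0.5 <= pe$ci[2])

  flat <- proportional_error(means, rep(0.1, 20), cluster = cl)
  expect_false(flat$flag)
  expect_equal(flat$slope, 0)

  expect_error(proportional_error(c(1, 2, 3), c(1, 2, 3)),
               "insufficient data")
  expect_error(proportional_error(rep(1, 5), rnorm(5)),
               "undefined correlation")
})

test_that("the report pipeline flags constant offsets and missing cells", {
  grid <- seq(5, 95, by = 10)
  base <- expand.grid(trial = 1:6, component = c("X", "Y", "Z"),
                      pct = grid, stringsAsFactors = FALSE)
  base$participant <- paste0("P", (base$trial - 1) %% 3 + 1)
  set.seed(4)
  base$true_bw <- round(runif(nrow(base), 0, 1.5), 3)

  # identical methods: ICC 1, zero bias, no trigger
  ident <- base; ident$est_bw <- ident$true_bw
  rep1 <- timepoint_report(ident, n_boot = 50)
  expect_true(all(rep1$icc > 0.999, na.rm = TRUE))
  expect_true(all(abs(rep1$bias) < 1e-12))
  expect_false(correction_trigger(rep1))

  # constant +0.1 BW offset everywhere: bias 0.1 > 0.08, trigger fires
  off <- base; off$est_bw <- off$true_bw + 0.1
  rep2 <- timepoint_report(off, n_boot = 50)
  expect_true(all(abs(rep2$bias - 0.1) < 1e-12))
  expect_true(all(rep2$fixed_error))
  expect_true(correction_trigger(rep2))

  # missing grid point: its cell is NA, the rest intact
  gone <- ident[ident$pct != 95, ]
  rep3 <- timepoint_report(gone, n_boot = 50)
  cell <- rep3[rep3$component == "X" & rep3$pct == 95, ]
  expect_equal(cell$n, 0L)
  expect_true(is.na(cell$bias))
  expect_true(all(is.finite(rep3$bias[rep3$pct != 95])))
})

test_that("the correction trigger threshold is inclusive at 0.08", {
  grid <- seq(5, 95, by = 10)
  base <- expand.grid(trial = 1:4, component = "X", pct = grid,
                      stringsAsFactors = FALSE)
  base$participant <- "P1"
  base$true_bw <- 1
  at <- base; at$est_bw <- at$true_bw + 0.08
  below <- base; below$est_bw <- below$true_bw + 0.079
  expect_true(correction_trigger(timepoint_report(at, n_boot = 10)))
  expect_false(correction_trigger(timepoint_report(below, n_boot = 10)))
  # monotonicity: any offset >= threshold fires
  for (o in c(0.08, 0.12, 0.3)) {
    d <- base; d$est_bw <- d$true_bw + o
    expect_true(correction_trigger(timepoint_report(d, n_boot = 10)))
  }
})

test_that("leave-one-participant-out removes a shared linear bias", {
  model <- default_correction_model()
  # both participants share the same exact linear true~estimate relation
  distorted <- linear_pairs(model, n_participants = 2, n_trials = 8)
  lopo <- lopo_validate(distorted)
  expect_equal(length(lopo$folds), 2L)
  expect_true(all(lopo$summary$rmse_post < 1e-9))
  expect_true(all(lopo$summary$rmse_post < lopo$summary$rmse_pre))

  single <- distorted[distorted$participant == "P01", ]
  expect_error(lopo_validate(single), "insufficient data")
})

test_that("the worked moment-error arithmetic matches the printed example", {
  err <- bias_moment_error(0.06, moment_arm_m = 0.5)
  expect_equal(err, 0.06 * 9.81 * 0.5, tolerance = 1e-12)
  expect_equal(round(err, 2), 0.29)
  expect_lt(moment_error_fraction(err), 0.10)
})
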