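# Agreement verification between force-plate truth and posture-based
# estimates: RMSE, per-time-point regression, ICC(2,1), Bland-Altman
# bias / precision / limits of agreement, fixed and proportional error
# detection, the correction trigger, and leave-one-participant-out
# validation of the fitted correction.

#' Root mean square error
#'
#' @param true_series,est_series Paired numeric series (equal length,
#'   at least one pair; `NA` pairs are dropped).
#' @return `sqrt(mean((est - true)^2))`.
#' @export
rmse <- function(true_series, est_series) {
  if (length(true_series) != length(est_series))
    stop("paired series must have equal length", call. = FALSE)
  keep <- is.finite(true_series) & is.finite(est_series)
  if (!any(keep))
    stop("insufficient data: no finite pairs", call. = FALSE)
  sqrt(mean((est_series[keep] - true_series[keep])^2))
}

#' Regression of true values on estimates
#'
#' Ordinary least squares with the true (force-plate) values on the
#' vertical axis and the estimates on the horizontal axis.
#'
#' @param true_values,est_values Paired numeric vectors (>= 3 pairs).
#' @return List with `slope` and `intercept`.
#' @export
regression_true_on_est <- function(true_values, est_values) {
  keep <- is.finite(true_values) & is.finite(est_values)
  x <- est_values[keep]; y <- true_values[keep]
  if (length(x) < 3L)
    stop("insufficient data: need at least 3 pairs", call. = FALSE)
  if (var(x) <= 0)
    stop("fit error: zero variance in the estimates", call. = FALSE)
  cf <- lm.fit(cbind(1, x), y)$coefficients
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, where MSR,
#' MSC and MSE are the rows (trials), columns (methods) and residual
#' mean squares of the two-way ANOVA without replication.  The value is
#' banded per Koo & Li: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9
#' good, 0.9 and above excellent (half-open intervals), and agreement is
#' declared at 0.5 (moderate) or higher.
#'
#' @param ratings n x k numeric matrix: n trials (rows) rated by k
#'   methods (columns, typically true and estimated); no missing cells,
#'   n >= 3, k >= 2.
#' @return List with `value`, `category`, `agreement`, `degenerate`
#'   (zero between-trial variance) and the mean squares `ms`.
#' @export
icc21 <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L)
    stop("insufficient data: ICC(2,1) needs at least 3 trials", call. = FALSE)
  if (k < 2L) stop("need at least 2 methods (columns)", call. = FALSE)
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  g <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - g)^2)
  SSC <- n * sum((col_m - g)^2)
  SST <- sum((m - g)^2)
  SSE <- max(SST - SSR - SSC, 0)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  degenerate <- MSR <= .Machine$double.eps * max(SST, 1)
  if (degenerate)
    warning("degenerate ICC: zero between-trial variance")
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  value <- if (denom <= 0) NA_real_ else (MSR - MSE) / denom
  list(value = value,
       category = icc_category(value),
       agreement = is.finite(value) && value >= 0.5,
       degenerate = degenerate,
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}

#' @rdname icc21
#' @param value An ICC value.
#' @export
icc_category <- function(value) {
  if (!is.finite(value)) return(NA_character_)
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.9) "good"
  else "excellent"
}

#' Bland-Altman bias, precision, limits of agreement and fixed error
#'
#' The bias is the mean of the estimate-minus-true differences, the
#' precision their sample standard deviation, and the 95% limits of
#' agreement are `bias +/- 1.96 * precision`.  The 95% confidence
#' interval of the bias uses the t distribution across trials; a fixed
#' error is present when that interval excludes zero.
#'
#' @param diffs Estimate - true differences, one per trial (n >= 2).
#' @return List with `n`, `bias`, `precision`, `loa` (length-2 lower /
#'   upper), `ci` (95% CI of the bias) and `fixed_error`.
#' @export
bias_precision_loa <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2L)
    stop("insufficient data: need at least 2 differences", call. = FALSE)
  bias <- mean(diffs)
  precision <- sd(diffs)
  loa <- c(lower = bias - 1.96 * precision, upper = bias + 1.96 * precision)
  half <- qt(0.975, df = n - 1) * precision / sqrt(n)
  ci <- c(lower = bias - half, upper = bias + half)
  fixed <- !(ci[1] <= 0 && 0 <= ci[2])
  list(n = n, bias = bias, precision = precision, loa = loa, ci = ci,
       fixed_error = unname(fixed))
}

#' Proportional error on a Bland-Altman plot
#'
#' Tests whether the estimate-minus-true differences correlate with the
#' pairwise means (Pearson, alpha = 0.05).  The slope of the differences
#' on the means is reported with a confidence interval that respects
#' repeated measurements: participants (clusters) are resampled with
#' replacement (`n_boot` draws) and the percentile interval of the
#' refitted slopes is returned.  Without cluster ids an ordinary OLS
#' interval is used.
#'
#' @param means Per-point `(est + true) / 2`.
#' @param diffs Per-point `est - true`.
#' @param cluster Participant ids for the repeated-measures bootstrap
#'   (`NULL` for the plain OLS interval).
#' @param alpha Significance level of the correlation test.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @return List with `flag`, `slope`, `ci`, `p_value`.
#' @export
proportional_error <- function(means, diffs, cluster = NULL, alpha = 0.05,
                               n_boot = 2000, seed = NULL) {
  keep <- is.finite(means) & is.finite(diffs)
  means <- means[keep]; diffs <- diffs[keep]
  if (!is.null(cluster)) cluster <- cluster[keep]
  n <- length(means)
  if (n < 4L)
    stop("insufficient data: need at least 4 points", call. = FALSE)
  if (var(means) <= 0)
    stop("undefined correlation: zero variance in the means", call. = FALSE)
  if (sd(diffs) <= 0)
    return(list(flag = FALSE, slope = 0, ci = c(lower = 0, upper = 0),
                p_value = NA_real_))
  ct <- cor.test(means, diffs)
  slope_of <- function(x, y) {
    vx <- sum((x - mean(x))^2)
    if (vx <= 0) return(NA_real_)
    sum((x - mean(x)) * (y - mean(y))) / vx
  }
  slope <- slope_of(means, diffs)
  if (!is.null(cluster) && length(unique(cluster)) >= 2L) {
    if (!is.null(seed)) set.seed(seed)
    ids <- unique(cluster)
    by_id <- split(seq_len(n), cluster)
    boots <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, length(ids), replace = TRUE)
      i <- unlist(by_id[as.character(pick)], use.names = FALSE)
      slope_of(means[i], diffs[i])
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
  } else {
    if (!is.null(cluster))
      warning("only one cluster supplied; using the plain OLS interval")
    fit <- lm(diffs ~ means)
    ci <- unname(stats::confint(fit)[2, ])
  }
  list(flag = unname(ct$p.value < alpha), slope = slope,
       ci = c(lower = ci[1], upper = ci[2]), p_value = unname(ct$p.value))
}

#' Per-time-point agreement report
#'
#' Runs the full verification battery for every component at every grid
#' point of normalised stride time (default 5%-95% at 10% intervals):
#' sample size, means and SDs of both methods, true-on-estimate
#' regression, ICC(2,1) with its category, Bland-Altman bias, precision,
#' limits of agreement, bias CI, fixed-error flag, and proportional
#' error with a repeated-measures slope CI.  Cells without enough trials
#' are reported with `NA` and the run continues.
#'
#' @param pairs Data frame of paired samples with columns `participant`,
#'   `trial`, `component` (`"X"`, `"Y"`, `"Z"`), `pct`, `true_bw`,
#'   `est_bw` (and optionally `motion`).
#' @param grid Grid points (percent) to verify at.
#' @param threshold Bias magnitude (BW) that triggers the correction
#'   recommendation (inclusive).
#' @param n_boot,seed Passed to [proportional_error()].
#' @return A data frame of class `agreement_report`, one row per
#'   component x grid point, with attribute `threshold`.
#' @export
timepoint_report <- function(pairs, grid = seq(5, 95, by = 10),
                             threshold = 0.08, n_boot = 2000, seed = 1) {
  req <- c("trial", "component", "pct", "true_bw", "est_bw")
  if (!all(req %in% names(pairs)))
    stop("`pairs` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!"participant" %in% names(pairs)) pairs$participant <- "P1"
  rows <- list()
  for (comp in intersect(c("X", "Y", "Z"), unique(pairs$component))) {
    for (g in grid) {
      d <- pairs[pairs$component == comp & pairs$pct == g &
                   is.finite(pairs$true_bw) & is.finite(pairs$est_bw), ]
      n <- nrow(d)
      row <- list(component = comp, pct = g, n = n,
                  mean_true = NA_real_, sd_true = NA_real_,
                  mean_est = NA_real_, sd_est = NA_real_,
                  slope = NA_real_, intercept = NA_real_,
                  icc = NA_real_, icc_category = NA_character_,
                  agreement = NA,
                  bias = NA_real_, precision = NA_real_,
                  loa_low = NA_real_, loa_high = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  fixed_error = NA,
                  proportional_error = NA, prop_slope = NA_real_,
                  prop_ci_low = NA_real_, prop_ci_high = NA_real_)
      if (n >= 1L) {
        row$mean_true <- mean(d$true_bw); row$mean_est <- mean(d$est_bw)
        if (n >= 2L) {
          row$sd_true <- sd(d$true_bw); row$sd_est <- sd(d$est_bw)
          ba <- bias_precision_loa(d$est_bw - d$true_bw)
          row$bias <- ba$bias; row$precision <- ba$precision
          row$loa_low <- ba$loa[1]; row$loa_high <- ba$loa[2]
          row$ci_low <- ba$ci[1]; row$ci_high <- ba$ci[2]
          row$fixed_error <- ba$fixed_error
        }
        if (n >= 3L && var(d$est_bw) > 0) {
          reg <- regression_true_on_est(d$true_bw, d$est_bw)
          row$slope <- reg$slope; row$intercept <- reg$intercept
          ic <- suppressWarnings(icc21(cbind(true = d$true_bw,
                                             est = d$est_bw)))
          row$icc <- ic$value; row$icc_category <- ic$category
          row$agreement <- ic$agreement
        }
        if (n >= 4L && var((d$est_bw + d$true_bw) / 2) > 0 &&
            length(unique(d$participant)) >= 1L) {
          pe <- tryCatch(
            proportional_error((d$est_bw + d$true_bw) / 2,
                               d$est_bw - d$true_bw,
                               cluster = d$participant,
                               n_boot = n_boot, seed = seed),
            error = function(e) NULL)
          if (!is.null(pe)) {
            row$proportional_error <- pe$flag
            row$prop_slope <- pe$slope
            row$prop_ci_low <- pe$ci[1]; row$prop_ci_high <- pe$ci[2]
          }
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  attr(rep_, "threshold") <- threshold
  class(rep_) <- c("agreement_report", "data.frame")
  rep_
}

#' Does the bias warrant a regression correction?
#'
#' `TRUE` when the absolute bias reaches `threshold` (8% of body weight
#' by default, inclusive) for any component at any verified time point.
#'
#' @param report An [timepoint_report()] result.
#' @param threshold Bias threshold in BW units.
#' @return Logical scalar.
#' @export
correction_trigger <- function(report,
                               threshold = attr(report, "threshold") %||% 0.08) {
  b <- report$bias
  if (all(!is.finite(b))) {
    warning("empty agreement report: no bias values")
    return(FALSE)
  }
  any(abs(b) >= threshold, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-component RMSE of a paired-sample set
#'
#' @param pairs A paired-sample data frame (see [timepoint_report()]).
#' @return Named numeric vector (X, Y, Z).
#' @export
rmse_by_component <- function(pairs) {
  comps <- c("X", "Y", "Z")
  vapply(setNames(comps, comps), function(co) {
    d <- pairs[pairs$component == co, ]
    if (!nrow(d)) return(NA_real_)
    rmse(d$true_bw, d$est_bw)
  }, numeric(1))
}

#' Fit a correction model from a paired-sample set
#'
#' Pools all rows per component and fits the true-on-estimate
#' regression (see [fit_correction()]).
#'
#' @param pairs Paired-sample data frame.
#' @param scope Scope label for the model.
#' @return A [correction_model()].
#' @export
fit_correction_pairs <- function(pairs, scope = "fitted") {
  slope <- numeric(3); icept <- numeric(3)
  for (j in seq_along(c("X", "Y", "Z"))) {
    co <- c("X", "Y", "Z")[j]
    d <- pairs[pairs$component == co &
                 is.finite(pairs$true_bw) & is.finite(pairs$est_bw), ]
    if (nrow(d) < 3L)
      stop(sprintf("insufficient data for component %s", co), call. = FALSE)
    if (var(d$est_bw) <= 0)
      stop(sprintf("fit error: zero estimate variance for component %s", co),
           call. = FALSE)
    cf <- lm.fit(cbind(1, d$est_bw), d$true_bw)$coefficients
    icept[j] <- cf[1]; slope[j] <- cf[2]
  }
  correction_model(slope, icept, scope = scope)
}

#' Apply a correction model to a paired-sample set
#'
#' @param pairs Paired-sample data frame.
#' @param model A [correction_model()].
#' @return `pairs` with `est_bw` replaced by the corrected value.
#' @export
correct_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "correction_model"))
  idx <- match(pairs$component, c("X", "Y", "Z"))
  pairs$est_bw <- model$slope[idx] * pairs$est_bw + model$intercept[idx]
  pairs
}

#' Leave-one-participant-out validation of the correction
#'
#' For each participant in turn, fits the per-component correction on
#' the remaining participants' data, applies it to the held-out
#' participant's estimates, and reports held-out pre- and
#' post-correction RMSE per component (plus the fitted fold models).
#'
#' @param pairs Paired-sample data frame with a `participant` column and
#'   at least 2 participants.
#' @param grid Grid used for optional per-fold agreement reports
#'   (reports are only built when `reports = TRUE`).
#' @param reports Build a [timepoint_report()] per fold (slower).
#' @param n_boot,seed Passed through to the per-fold reports.
#' @return List of class `lopo_result`: `folds` (per-participant list
#'   with `model`, `rmse_pre`, `rmse_post`, optionally `report`) and
#'   `summary` (data frame of fold RMSEs).
#' @export
lopo_validate <- function(pairs, grid = seq(5, 95, by = 10),
                          reports = FALSE, n_boot = 500, seed = 1) {
  if (!"participant" %in% names(pairs))
    stop("`pairs` must have a `participant` column", call. = FALSE)
  ps <- unique(pairs$participant)
  if (length(ps) < 2L)
    stop("insufficient data: leave-one-participant-out needs at least 2 participants",
         call. = FALSE)
  folds <- list()
  srows <- list()
  for (p in ps) {
    test <- pairs[pairs$participant == p, ]
    train <- pairs[pairs$participant != p, ]
    if (!nrow(test)) {
      warning(sprintf("participant %s has no rows; skipped", p))
      next
    }
    model <- fit_correction_pairs(train, scope = "lopo-train")
    corrected <- correct_pairs(test, model)
    pre <- rmse_by_component(test)
    post <- rmse_by_component(corrected)
    fold <- list(participant = p, model = model,
                 rmse_pre = pre, rmse_post = post)
    if (reports)
      fold$report <- timepoint_report(corrected, grid = grid,
                                      n_boot = n_boot, seed = seed)
    folds[[as.character(p)]] <- fold
    srows[[length(srows) + 1L]] <- data.frame(
      participant = as.character(p),
      component = c("X", "Y", "Z"),
      rmse_pre = unname(pre), rmse_post = unname(post),
      stringsAsFactors = FALSE)
  }
  structure(list(folds = folds, summary = do.call(rbind, srows)),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat("<lopo_result> ", length(x$folds), " fold(s)\n", sep = "")
  agg <- stats::aggregate(cbind(rmse_pre, rmse_post) ~ component,
                          data = x$summary, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Worked moment-error arithmetic for a Y' bias
#'
#' Converts a propulsive-component (Y') force bias, expressed in
#' body-weight units, into the hip joint-moment error it would cause at
#' a given moment arm: `bias * g * arm`, in Nm per kg of body mass.
#' With the largest observed Y' bias (0.06 BW) and the approximately
#' 0.5 m arm from the centre of pressure to the hip joint centre this is
#' about 0.29 Nm/kg.
#'
#' @param bias_bw Force bias in BW units.
#' @param moment_arm_m Moment arm in metres.
#' @param g Gravitational acceleration, m/s^2.
#' @return Moment error in Nm/kg.
#' @export
bias_moment_error <- function(bias_bw, moment_arm_m = 0.5, g = 9.81) {
  bias_bw * g * moment_arm_m
}

#' @rdname bias_moment_error
#' @param moment_error_nm_kg Moment error in Nm/kg.
#' @param joint_range_nm_kg Range of the joint moment the error is
#'   compared against (default 3.0 Nm/kg, the hip flexion-extension
#'   range during skating).
#' @return Fraction of the joint-moment range.
#' @export
moment_error_fraction <- function(moment_error_nm_kg,
                                  joint_range_nm_kg = 3.0) {
  moment_error_nm_kg / joint_range_nm_kg
}

#' Basic Bland-Altman plot
#'
#' @param means,diffs Per-point means and differences.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [bias_precision_loa()] of `diffs`.
#' @export
plot_bland_altman <- function(means, diffs, ...) {
  ba <- bias_precision_loa(diffs)
  graphics::plot(means, diffs, xlab = "mean of methods (BW)",
                 ylab = "estimate - true (BW)", ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}
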