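# End-to-end estimation pipeline: raw trial -> smoothed trajectories ->
# local frame -> estimated direction -> GRF components -> normalised
# paired samples for verification.

#' Run the direction-estimation pipeline on one trial
#'
#' Smooths the marker and CM trajectories (residual-method cutoff per
#' coordinate by default), decimates the force-plate signal to the
#' marker rate, builds the per-frame local frame from the CM velocity,
#' constructs the Est1/Est2 sole-normal direction, and multiplies the
#' body-weight-normalised measured resultant by the estimated unit
#' direction.  For left-leg straight-skating trials both the estimated
#' and the truth components are mirrored (X' negated) so they pool with
#' right-leg data.
#'
#' @param trial A `skate_trial` (from [simulate_stride()] or
#'   [read_trial()]).
#' @param method `"est1"` or `"est2"`.
#' @param filter Smooth markers/CM before estimating (disable for
#'   machine-precision checks on noiseless synthetic data).
#' @param cutoff_policy Passed to [filter_trial()].
#' @param antialias Anti-alias filter in the force decimation (see
#'   [resample_to_rate()]).
#' @param filter_forces Additionally low-pass the decimated force at
#'   15 Hz (off by default; the resultant is used as measured).
#' @param correction Optional [correction_model()] applied to the
#'   estimated components.
#' @return Object of class `trial_estimate`: list with `time`,
#'   `f_sigma` (BW), `e_local`, `est` (`estimated_grf`),
#'   `truth_local` (n x 3 or NULL), `frame`, `mirrored`, `trial`.
#' @export
estimate_trial <- function(trial, method = c("est2", "est1"),
                           filter = TRUE, cutoff_policy = "residual",
                           antialias = TRUE, filter_forces = FALSE,
                           correction = NULL) {
  method <- match.arg(method)
  tr <- if (filter) filter_trial(trial, cutoff_policy = cutoff_policy)
        else trial
  force_m <- resample_to_rate(trial$force, trial$fs_force, trial$fs_marker,
                              antialias = antialias)
  n <- min(nrow(force_m), length(trial$time))
  force_m <- force_m[seq_len(n), , drop = FALSE]
  if (filter_forces)
    force_m <- apply(force_m, 2, butterworth_lowpass, fc = 15,
                     fs = trial$fs_marker)
  f_sigma <- normalize_by_bw(sqrt(rowSums(force_m^2)), trial$body_weight)
  vel <- cm_velocity(tr$cm[seq_len(n), , drop = FALSE], trial$fs_marker)
  frame <- local_frame(vel)
  joint <- if (method == "est1") tr$markers$ankle else tr$markers$knee
  de <- estimate_direction(tr$markers$blade_rear[seq_len(n), , drop = FALSE],
                           tr$markers$blade_front[seq_len(n), , drop = FALSE],
                           joint[seq_len(n), , drop = FALSE],
                           method = method)
  e_local <- to_local(de$z_b, frame)
  est <- grf_components(f_sigma, e_local, method = method)
  truth_local <- trial$truth$components_local
  if (!is.null(truth_local))
    truth_local <- truth_local[seq_len(n), , drop = FALSE]
  mirrored <- identical(trial$side, "left") &&
    identical(trial$motion, "straight")
  if (mirrored) {
    est <- mirror_left(est)
    e_local <- mirror_left(e_local)
    if (!is.null(truth_local)) truth_local <- mirror_left(truth_local)
  }
  if (!is.null(correction))
    est <- apply_correction(est, correction, motion = motion_label(trial))
  structure(list(time = trial$time[seq_len(n)], f_sigma = f_sigma,
                 e_local = e_local, est = est, truth_local = truth_local,
                 frame = frame, direction = de, mirrored = mirrored,
                 trial = trial),
            class = "trial_estimate")
}

#' Normalized paired samples for one trial
#'
#' Segments the supporting-leg period, selects the analyzable frames
#' (analysed blade alone on the plate), time-normalises each estimated
#' and true component onto the 0-100% grid, and returns the paired
#' values at the requested grid points.  Only grid points where both
#' the truth and the estimate are valid are returned.
#'
#' @param te A [estimate_trial()] result (its trial must carry truth).
#' @param grid Grid points (percent of normalised stride).
#' @param use_mask Apply the force-plate analyzability mask (`FALSE`
#'   uses every in-phase frame, e.g. when no plate geometry applies).
#' @return Data frame with columns `component`, `pct`, `true_bw`,
#'   `est_bw`.
#' @export
evaluate_trial <- function(te, grid = seq(5, 95, by = 10),
                           use_mask = TRUE) {
  stopifnot(inherits(te, "trial_estimate"))
  trial <- te$trial
  if (is.null(te$truth_local))
    stop("trial carries no ground truth to pair against", call. = FALSE)
  seg <- segment_phases(trial$events, te$time)
  n <- length(te$time)
  mask <- if (use_mask) {
    analyzable_mask(trial$markers$blade_rear[seq_len(n), , drop = FALSE],
                    trial$markers$blade_front[seq_len(n), , drop = FALSE],
                    trial$opposite$rear[seq_len(n), , drop = FALSE],
                    trial$opposite$front[seq_len(n), , drop = FALSE],
                    trial$opposite$airborne[seq_len(n)],
                    plate = trial$plate)
  } else rep(TRUE, n)
  rows <- list()
  for (j in 1:3) {
    comp <- c("X", "Y", "Z")[j]
    ns_est <- phase_normalize(te$est$components[, j], seg, mask)
    ns_true <- phase_normalize(te$truth_local[, j], seg, mask)
    gi <- match(grid, ns_est$pct)
    okg <- ns_est$valid[gi] & ns_true$valid[gi]
    if (!any(okg)) next
    rows[[length(rows) + 1L]] <- data.frame(
      component = comp, pct = grid[okg],
      true_bw = ns_true$values[gi][okg],
      est_bw = ns_est$values[gi][okg],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(component = character(), pct = numeric(),
                      true_bw = numeric(), est_bw = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired samples for a whole cohort
#'
#' Runs [estimate_trial()] and [evaluate_trial()] over a list of trials
#' and stacks the results with participant / trial / motion metadata,
#' in the layout [timepoint_report()] expects.
#'
#' @param trials List of `skate_trial`s (e.g. from [make_cohort()]).
#' @param method `"est1"` or `"est2"`.
#' @param grid Grid points (percent).
#' @param ... Passed to [estimate_trial()].
#' @return Paired-sample data frame with columns `participant`,
#'   `trial`, `motion`, `component`, `pct`, `true_bw`, `est_bw`.
#' @export
evaluate_cohort <- function(trials, method = "est2",
                            grid = seq(5, 95, by = 10), ...) {
  out <- list()
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    te <- estimate_trial(trial, method = method, ...)
    d <- evaluate_trial(te, grid = grid)
    if (!nrow(d)) next
    d$participant <- if (is.na(trial$participant)) sprintf("P%02d", 1L)
                     else trial$participant
    d$trial <- if (is.na(trial$trial_id)) i else trial$trial_id
    d$motion <- motion_label(trial)
    out[[length(out) + 1L]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("participant", "trial", "motion", "component", "pct",
          "true_bw", "est_bw")]
}
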