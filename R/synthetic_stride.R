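# Synthetic skating-stride generator: marker trajectories, CM path,
# force-plate signal, blade events and ground-truth GRF with
# configurable noise, for straight and 26-m-radius curved strides.

#' Simulation configuration for a synthetic skating stride
#'
#' Defaults reproduce the study conditions of the verification
#' experiment this package models: straight strides at 9.79 m/s with
#' contact / single-support / push-off durations of 0.16 / 0.60 /
#' 0.16 s; curved strides on a 26 m radius at 8.87 m/s with durations
#' 0.15 / 0.48 / 0.14 s (right leg) or 0.14 / 0.56 / 0.15 s (left leg);
#' 300 Hz markers and 900 Hz force; a 0.6 m x 5.4 m force plate.
#' Marker noise defaults to 3 mm isotropic Gaussian, a conventional
#' optical-capture figure.  The shank lean follows a half sine from a
#' base angle to a configurable maximum at push-off (peaking at 30
#' degrees for the left leg on the curve, where the shank is most
#' inclined); a small blade pitch (default 4 degrees) gives the
#' direction a propulsive Y' component confined to roughly 0-0.1 BW.
#' `direction_perturbation_deg` rotates the true force direction away
#' from the sole normal about the blade axis, emulating the real
#' mismatch between shank inclination and force direction; at 0 the
#' true direction coincides with the sole normal of the noiseless
#' markers.
#'
#' @param motion `"straight"` or `"curve"`.
#' @param side Supporting leg analysed, `"right"` or `"left"`.
#' @param curve_radius Curve radius, m.
#' @param cm_speed CM speed, m/s (`NULL` = motion default).
#' @param phase_durations Contact / single-support / push-off durations,
#'   s (`NULL` = motion/side default).
#' @param body_weight_N Body weight, newtons.
#' @param marker_noise_sd Isotropic marker noise SD, m.
#' @param cm_noise_sd CM trajectory noise SD, m (CM comes from many
#'   markers, hence smaller).
#' @param joint_artifact_sd SD of the slowly varying joint-centre
#'   estimation error added to the ankle and knee trajectories, m.
#'   Joint centres are virtual points derived from skin markers and
#'   carry soft-tissue artifact well above optical noise; because it is
#'   low-frequency (see `joint_artifact_hz`) it largely survives the
#'   9-15 Hz smoothing.  The amplitude is identical for both joints, so
#'   only the lever length differentiates its effect on Est1 vs Est2.
#' @param joint_artifact_hz Bandwidth of the joint-centre artifact, Hz.
#' @param direction_perturbation_deg Rotation of the true force
#'   direction away from the sole normal, degrees.
#' @param lean_base_deg,lean_max_deg Shank lean at contact and at
#'   push-off, degrees (`NULL` = motion/side default; positive leans to
#'   the skater's right).
#' @param pitch_max_deg Blade pitch reached at push-off, degrees.
#' @param force_peak_bw Peak resultant force, BW units.
#' @param fs_marker,fs_force Sampling rates, Hz (force must be an
#'   integer multiple of marker).
#' @param blade_length,lever_ankle,lever_knee Blade length and
#'   perpendicular blade-to-joint distances, m.
#' @param cm_height Blade-to-CM distance along the sole normal, m.
#' @param plate_width,plate_length Force plate size, m.
#' @param seed Optional RNG seed for the marker noise.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(motion = c("straight", "curve"),
                       side = c("right", "left"),
                       curve_radius = 26,
                       cm_speed = NULL,
                       phase_durations = NULL,
                       body_weight_N = 630,
                       marker_noise_sd = 0.003,
                       cm_noise_sd = marker_noise_sd / 3,
                       joint_artifact_sd = 0.008,
                       joint_artifact_hz = 2,
                       direction_perturbation_deg = 2,
                       lean_base_deg = NULL,
                       lean_max_deg = NULL,
                       pitch_max_deg = 4,
                       force_peak_bw = 1.8,
                       fs_marker = 300,
                       fs_force = 900,
                       blade_length = 0.3,
                       lever_ankle = 0.2,
                       lever_knee = 0.45,
                       cm_height = 0.95,
                       plate_width = 0.6,
                       plate_length = 5.4,
                       seed = NULL) {
  motion <- match.arg(motion)
  side <- match.arg(side)
  if (is.null(cm_speed))
    cm_speed <- if (motion == "straight") 9.79 else 8.87
  if (is.null(phase_durations))
    phase_durations <- if (motion == "straight") c(0.16, 0.60, 0.16)
      else if (side == "right") c(0.15, 0.48, 0.14)
      else c(0.14, 0.56, 0.15)
  if (is.null(lean_base_deg))
    lean_base_deg <- if (motion == "straight") 0 else 17
  if (is.null(lean_max_deg))
    lean_max_deg <- if (motion == "straight") 15
      else if (side == "left") 30 else 25
  stopifnot(length(phase_durations) == 3L, all(phase_durations > 0),
            curve_radius > 0, cm_speed > 0, marker_noise_sd >= 0,
            cm_noise_sd >= 0, joint_artifact_sd >= 0,
            joint_artifact_hz > 0,
            body_weight_N > 0, force_peak_bw > 0,
            lever_ankle > 0, lever_knee > 0, blade_length > 0)
  k <- fs_force / fs_marker
  if (abs(k - round(k)) > 1e-9)
    stop("`fs_force` must be an integer multiple of `fs_marker`",
         call. = FALSE)
  structure(list(motion = motion, side = side, curve_radius = curve_radius,
                 cm_speed = cm_speed, phase_durations = phase_durations,
                 body_weight_N = body_weight_N,
                 marker_noise_sd = marker_noise_sd,
                 cm_noise_sd = cm_noise_sd,
                 joint_artifact_sd = joint_artifact_sd,
                 joint_artifact_hz = joint_artifact_hz,
                 direction_perturbation_deg = direction_perturbation_deg,
                 lean_base_deg = lean_base_deg,
                 lean_max_deg = lean_max_deg,
                 pitch_max_deg = pitch_max_deg,
                 force_peak_bw = force_peak_bw,
                 fs_marker = fs_marker, fs_force = fs_force,
                 blade_length = blade_length, lever_ankle = lever_ankle,
                 lever_knee = lever_knee, cm_height = cm_height,
                 plate_width = plate_width, plate_length = plate_length,
                 seed = seed),
            class = "sim_config")
}

# Analytic stride geometry at arbitrary times t (vectorised).
stride_geometry <- function(cfg, t) {
  T_ <- sum(cfg$phase_durations)
  v <- cfg$cm_speed
  deg <- pi / 180
  # horizontal CM path and heading
  if (cfg$motion == "straight") {
    cm_h <- cbind(0, v * t)
    tang <- cbind(rep(0, length(t)), rep(1, length(t)))
  } else {
    R <- cfg$curve_radius
    th <- (v * t - v * T_ / 2) / R          # 0 at mid-stride
    C <- c(-R, v * T_ / 2)
    cm_h <- cbind(C[1] + R * cos(th), C[2] + R * sin(th))
    tang <- cbind(-sin(th), cos(th))        # counter-clockwise (left turn)
  }
  # blade pitch: half sine, 0 at contact to max at push-off; negative =
  # heel rising, which tilts the sole normal toward the travel
  # direction and gives the force its small propulsive Y' component
  phi <- -cfg$pitch_max_deg * deg * sin(pi * t / (2 * T_))
  yb <- cbind(cos(phi) * tang[, 1], cos(phi) * tang[, 2], sin(phi))
  # vertical-most direction perpendicular to the blade axis, and lateral
  w0 <- cbind(-sin(phi) * tang[, 1], -sin(phi) * tang[, 2], cos(phi))
  lat <- cross3(yb, w0)                      # skater's right
  # shank lean: half sine from base to max; straight legs lean medially
  # (right leg to the left), curve legs lean into the turn (toward -X
  # at mid-stride since the turn is to the left)
  ramp <- sin(pi * t / (2 * T_))
  if (cfg$motion == "straight") {
    sgn <- if (cfg$side == "right") -1 else 1
    alpha <- sgn * (cfg$lean_base_deg + (cfg$lean_max_deg - cfg$lean_base_deg) * ramp) * deg
  } else {
    alpha <- -(cfg$lean_base_deg + (cfg$lean_max_deg - cfg$lean_base_deg) * ramp) * deg
  }
  n_sole <- cos(alpha) * w0 + sin(alpha) * lat
  # blade midpoint: lowest blade point rides at 10 mm; CM sits on the
  # configured path, cm_height along the sole normal above the blade
  mid_z <- 0.01 + (cfg$blade_length / 2) * abs(sin(phi))
  mid <- cbind(cm_h[, 1] - cfg$cm_height * n_sole[, 1],
               cm_h[, 2] - cfg$cm_height * n_sole[, 2],
               mid_z)
  cm <- cbind(cm_h, mid_z + cfg$cm_height * n_sole[, 3])
  rear <- mid - (cfg$blade_length / 2) * yb
  front <- mid + (cfg$blade_length / 2) * yb
  ankle <- mid + cfg$lever_ankle * n_sole
  knee <- mid + cfg$lever_knee * n_sole
  # true force direction: sole normal rotated about the blade axis
  delta <- cfg$direction_perturbation_deg * deg
  d_true <- cos(delta) * n_sole + sin(delta) * cross3(yb, n_sole)
  f_sigma <- cfg$force_peak_bw * 0.5 * (1 - cos(2 * pi * t / T_))
  list(cm = cm, rear = rear, front = front, ankle = ankle, knee = knee,
       n_sole = n_sole, d_true = d_true, f_sigma = f_sigma, yb = yb,
       lat = lat, mid = mid, T = T_)
}

#' Simulate one skating stride with known ground truth
#'
#' Generates a complete synthetic trial: blade, ankle and knee marker
#' trajectories plus the CM path at the marker rate; the force-plate
#' force vector at the force rate (the true resultant along the true
#' direction, in newtons, global frame); blade events; the plate
#' rectangle (centred on the blade footprint at mid-stride); the
#' opposite-blade footprint (laterally offset, outside the plate, on
#' the ground only during the double-support phases); and the ground
#' truth (resultant in BW, direction, and local-frame components).
#' Observed markers are the noiseless trajectories plus isotropic
#' Gaussian noise.  Truth local components are expressed in the local
#' frame derived from the sampled noiseless CM trajectory by central
#' differences -- the same rule the estimation pipeline uses -- so with
#' zero noise and zero perturbation the Est1/Est2 pipeline reproduces
#' the truth to machine precision.
#'
#' @param config A [sim_config()].
#' @return Object of class `skate_trial`.
#' @export
simulate_stride <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  T_ <- sum(cfg$phase_durations)
  n_m <- round(T_ * cfg$fs_marker)
  n_f <- round(T_ * cfg$fs_force)
  t_m <- (seq_len(n_m) - 1) / cfg$fs_marker
  t_f <- (seq_len(n_f) - 1) / cfg$fs_force
  g_m <- stride_geometry(cfg, t_m)
  g_f <- stride_geometry(cfg, t_f)

  force <- cfg$body_weight_N * g_f$f_sigma * g_f$d_true   # newtons, global

  addnoise <- function(m, sd) {
    if (sd <= 0) return(m)
    m + matrix(rnorm(length(m), sd = sd), nrow(m), ncol(m))
  }
  # slowly varying joint-centre estimation error (soft-tissue artifact
  # on the virtual ankle/knee points); identical amplitude for both
  # joints, so only the lever length differentiates Est1 and Est2
  artifact <- function(m) {
    if (cfg$joint_artifact_sd <= 0) return(m)
    for (j in seq_len(ncol(m))) {
      w <- butterworth_lowpass(rnorm(nrow(m)), cfg$joint_artifact_hz,
                               cfg$fs_marker)
      s <- sd(w)
      if (s > 0) m[, j] <- m[, j] + w / s * cfg$joint_artifact_sd
    }
    m
  }
  markers <- list(blade_rear = addnoise(g_m$rear, cfg$marker_noise_sd),
                  blade_front = addnoise(g_m$front, cfg$marker_noise_sd),
                  ankle = artifact(addnoise(g_m$ankle, cfg$marker_noise_sd)),
                  knee = artifact(addnoise(g_m$knee, cfg$marker_noise_sd)))
  cm_obs <- addnoise(g_m$cm, cfg$cm_noise_sd)

  ev <- blade_events(0, cfg$phase_durations[1],
                     cfg$phase_durations[1] + cfg$phase_durations[2], T_)

  # plate centred on the blade footprint at mid-stride (heading is +Y
  # there for both motions)
  i_mid <- which.min(abs(t_m - T_ / 2))
  ctr <- g_m$mid[i_mid, 1:2]
  plate <- c(ctr[1] - cfg$plate_width / 2, ctr[1] + cfg$plate_width / 2,
             ctr[2] - cfg$plate_length / 2, ctr[2] + cfg$plate_length / 2)

  # opposite blade: offset to the skater's other side, well outside the
  # 0.6 m plate; airborne during single support
  lat_sign <- if (cfg$side == "right") -1 else 1
  off <- 0.9
  o_mid <- cbind(g_m$mid[, 1] + lat_sign * off * g_m$lat[, 1],
                 g_m$mid[, 2] + lat_sign * off * g_m$lat[, 2], 0.01)
  o_rear <- o_mid - (cfg$blade_length / 2) * g_m$yb
  o_front <- o_mid + (cfg$blade_length / 2) * g_m$yb
  seg <- segment_phases(ev, t_m)
  airborne <- seg$phase == "single_support"

  # truth local components via the pipeline's own frame convention
  frame <- local_frame(cm_velocity(g_m$cm, cfg$fs_marker))
  comp_local <- g_m$f_sigma * to_local(g_m$d_true, frame)
  colnames(comp_local) <- c("X", "Y", "Z")

  structure(list(
    time = t_m, fs_marker = cfg$fs_marker,
    markers = markers, cm = cm_obs,
    force = force, time_force = t_f, fs_force = cfg$fs_force,
    body_weight = cfg$body_weight_N,
    side = cfg$side, motion = cfg$motion,
    events = ev, plate = plate,
    opposite = list(rear = o_rear, front = o_front, airborne = airborne),
    truth = list(f_sigma = g_m$f_sigma, dir_global = g_m$d_true,
                 components_local = comp_local,
                 markers = list(blade_rear = g_m$rear,
                                blade_front = g_m$front,
                                ankle = g_m$ankle, knee = g_m$knee),
                 cm = g_m$cm),
    config = cfg, participant = NA_character_, trial_id = NA_integer_),
    class = "skate_trial")
}

#' @export
print.skate_trial <- function(x, ...) {
  cat(sprintf("<skate_trial> %s, %s leg, %d frames @ %g Hz, bw = %g N\n",
              x$motion, x$side, length(x$time), x$fs_marker,
              x$body_weight))
  invisible(x)
}

#' Motion label combining course and analysed side
#'
#' `"straight"` for straight trials (left-leg data are mirrored onto
#' the right), `"curve-right"` / `"curve-left"` for the two legs on the
#' curve, which are asymmetric and analysed separately.
#'
#' @param trial A `skate_trial`.
#' @return Character scalar.
#' @export
motion_label <- function(trial) {
  if (trial$motion == "straight") "straight"
  else paste0("curve-", trial$side)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant random effects (speed, lean amplitude, blade
#' pitch, and a systematic direction perturbation), then simulates
#' `trials_per` strides per participant with fresh marker noise.  Fully
#' reproducible for a given `seed`.  Random effects are normal with SD
#' 5% of the nominal value (0.5 degrees for the perturbation).
#'
#' @param n_participants,trials_per Cohort size.
#' @param config Base [sim_config()] shared by the cohort.
#' @param seed Master seed.
#' @param participant_cv Coefficient of variation of the multiplicative
#'   participant effects.
#' @return List of `skate_trial`s with `participant` and `trial_id`
#'   set.
#' @export
make_cohort <- function(n_participants = 16, trials_per = 7,
                        config = sim_config(), seed = 1,
                        participant_cv = 0.05) {
  stopifnot(n_participants >= 1L, trials_per >= 1L)
  set.seed(seed)
  trials <- list()
  for (p in seq_len(n_participants)) {
    speed_mult <- max(0.7, 1 + rnorm(1, sd = participant_cv))
    lean_mult <- max(0.5, 1 + rnorm(1, sd = participant_cv))
    pitch_mult <- max(0.3, 1 + rnorm(1, sd = 2 * participant_cv))
    pert_p <- if (config$direction_perturbation_deg == 0) 0
      else config$direction_perturbation_deg + rnorm(1, sd = 0.5)
    for (tr in seq_len(trials_per)) {
      cfg <- config
      cfg$cm_speed <- config$cm_speed * speed_mult
      cfg$lean_max_deg <- config$lean_max_deg * lean_mult
      cfg$pitch_max_deg <- config$pitch_max_deg * pitch_mult
      cfg$direction_perturbation_deg <- pert_p
      cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      trial <- simulate_stride(cfg)
      trial$participant <- sprintf("P%02d", p)
      trial$trial_id <- tr
      trials[[length(trials) + 1L]] <- trial
    }
  }
  trials
}

#' Inject a known linear miscalibration into a paired-sample set
#'
#' Replaces the estimates by the inverse linear transform of
#' [distort_components()] (plus optional measurement noise), so that
#' the true values relate to the distorted estimates through the given
#' model: `true ~= slope * est + intercept`.  Used to validate
#' [fit_correction_pairs()] and [lopo_validate()] against known
#' generating coefficients.
#'
#' @param pairs Paired-sample data frame (see [timepoint_report()]).
#' @param model A [correction_model()] holding the generating relation.
#' @param noise_sd Gaussian noise SD added to the distorted estimates
#'   (BW).
#' @param seed Optional seed.
#' @return `pairs` with distorted `est_bw`.
#' @export
inject_distortion <- function(pairs, model = default_correction_model(),
                              noise_sd = 0.003, seed = NULL) {
  stopifnot(inherits(model, "correction_model"))
  if (!is.null(seed)) set.seed(seed)
  idx <- match(pairs$component, c("X", "Y", "Z"))
  est <- (pairs$est_bw - model$intercept[idx]) / model$slope[idx]
  if (noise_sd > 0) est <- est + rnorm(length(est), sd = noise_sd)
  pairs$est_bw <- est
  pairs
}
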