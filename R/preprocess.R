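# Trajectory smoothing, stream synchronisation, local frame construction
# and body-weight normalisation.

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a uniformly sampled series with a Butterworth low-pass filter
#' applied forward and backward (zero phase lag).  The filter is realised
#' as a dual-pass filter of half the requested order, so the default
#' `order = 4` runs a 2nd-order filter twice, the convention for marker
#' trajectories.  The series is extended by odd reflection at both ends
#' before filtering to suppress edge transients.
#'
#' @param x Numeric vector, uniformly sampled at `fs` Hz.
#' @param fc Cutoff frequency in Hz; must lie strictly inside (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @param order Effective filter order after the dual pass (even; default 4).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 300)
#' noisy <- sin(2 * pi * 2 * t) + rnorm(length(t), sd = 0.05)
#' smooth <- butterworth_lowpass(noisy, fc = 10, fs = 300)
#' @export
butterworth_lowpass <- function(x, fc, fs, order = 4) {
  if (!is.numeric(x) || !is.numeric(fc) || !is.numeric(fs))
    stop("`x`, `fc` and `fs` must be numeric", call. = FALSE)
  if (length(fc) != 1L || !is.finite(fc) || fc <= 0 || fc >= fs / 2)
    stop(sprintf(
      "invalid parameter: cutoff %g Hz must lie strictly between 0 and the Nyquist frequency %g Hz",
      fc, fs / 2), call. = FALSE)
  if (order %% 2 != 0 || order < 2)
    stop("`order` must be a positive even number (dual-pass realisation)",
         call. = FALSE)
  n <- length(x)
  if (n < 3L * order)
    stop(sprintf("insufficient data: need at least %d samples, got %d",
                 3L * order, n), call. = FALSE)
  bf <- signal::butter(order / 2, fc / (fs / 2), type = "low")
  # odd reflection padding, ~3x the filter's characteristic length
  pad <- min(n - 1L, 3L * max(ceiling(fs / fc), 4L))
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- ba_filtfilt(bf$b, bf$a, xp)
  yp[(pad + 1L):(pad + n)]
}

# forward-backward ARMA filtering through stats::filter (C level);
# callers are responsible for padding against edge transients
ba_filt1 <- function(b, a, x) {
  # filter the deviation from the first sample so a constant input
  # passes with the exact DC gain and start transients stay tiny
  x0 <- x[1L]
  nb <- length(b)
  xf <- stats::filter(c(numeric(nb - 1L), x - x0), b,
                      method = "convolution", sides = 1)
  xf <- as.numeric(xf)[-seq_len(nb - 1L)]
  if (length(a) > 1L)
    xf <- as.numeric(stats::filter(xf, -a[-1L] / a[1L],
                                   method = "recursive"))
  xf / a[1L] + x0 * sum(b) / sum(a)
}

ba_filtfilt <- function(b, a, x) {
  rev(ba_filt1(b, a, rev(ba_filt1(b, a, x))))
}

# matrix (column-wise) variants; stats::filter handles multivariate
# series in one C call, which matters when scanning a cutoff grid
ba_filt1_m <- function(b, a, m) {
  x0 <- m[1L, ]
  nb <- length(b)
  dev <- sweep(m, 2, x0)
  xf <- stats::filter(rbind(matrix(0, nb - 1L, ncol(m)), dev), b,
                      method = "convolution", sides = 1)
  xf <- unclass(xf)[-seq_len(nb - 1L), , drop = FALSE]
  if (length(a) > 1L)
    xf <- unclass(stats::filter(xf, -a[-1L] / a[1L], method = "recursive"))
  sweep(xf / a[1L], 2, x0 * sum(b) / sum(a), `+`)
}

rev_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

bw_lowpass_mat <- function(m, fc, fs, order = 4) {
  n <- nrow(m)
  bf <- signal::butter(order / 2, fc / (fs / 2), type = "low")
  pad <- min(n - 1L, 3L * max(ceiling(fs / fc), 4L))
  xp <- rbind(2 * m[rep(1L, pad), , drop = FALSE] - m[(pad + 1L):2, , drop = FALSE],
              m,
              2 * m[rep(n, pad), , drop = FALSE] - m[(n - 1L):(n - pad), , drop = FALSE])
  yp <- ba_filt1_m(bf$b, bf$a, xp)
  yp <- rev_rows(ba_filt1_m(bf$b, bf$a, rev_rows(yp)))
  yp[(pad + 1L):(pad + n), , drop = FALSE]
}

# residual-vs-cutoff curves for every column at once
residual_curves <- function(m, fs, grid) {
  vapply(grid, function(fc) {
    sqrt(colMeans((m - bw_lowpass_mat(m, fc, fs))^2))
  }, numeric(ncol(m)))  # ncol(m) x length(grid)
}

# cutoff selection from one residual curve (shared by residual_cutoff
# and the vectorised marker path); returns NA on a degenerate curve
select_cutoff_from_curve <- function(res, grid, scale,
                                     linear_fraction = 1 / 3,
                                     r2_min = 0.8, warn = TRUE) {
  n_lin <- max(3L, ceiling(length(grid) * linear_fraction))
  idx <- seq.int(length(grid) - n_lin + 1L, length(grid))
  fit <- stats::lm(r ~ f, data = data.frame(r = res[idx], f = grid[idx]))
  sfit <- summary(fit)
  b0 <- max(0, unname(coef(fit)[1]))
  r2 <- sfit$r.squared
  # a true noise floor is nearly flat across the fitted region; a
  # residual curve that keeps decaying steeply there (noiseless or
  # signal-only data) has no floor to extrapolate
  decay <- res[idx[length(idx)]] / max(res[idx[1]], 1e-300)
  if (!is.finite(decay) || decay < 0.5 || !is.finite(r2) || r2 < r2_min ||
      b0 <= 1e-10 * max(scale, 1e-12))
    return(NA_real_)
  thr <- b0 + 2 * sfit$sigma
  hit <- which(res <= thr)
  if (!length(hit)) {
    if (warn)
      warning("residual curve never reaches the estimated noise floor; returning the maximum grid frequency")
    return(grid[length(grid)])
  }
  grid[hit[1L]]
}

#' Residual-method cutoff frequency selection
#'
#' Selects a low-pass cutoff frequency by the residual method: the RMS
#' residual between the raw series and its filtered version is computed
#' over a grid of candidate cutoffs; the high-frequency portion of the
#' residual-vs-cutoff curve (where only noise is being removed) is fitted
#' with a straight line whose 0 Hz intercept estimates the noise floor;
#' the chosen cutoff is the lowest grid frequency whose residual falls at
#' or below that floor (plus twice the fit's residual standard error, to
#' account for the uncertainty of the floor estimate).
#'
#' If no linear noise region can be identified (fit R-squared below
#' `r2_min`, or a vanishing noise floor, as for a noiseless signal) a
#' degenerate-signal error is raised.  If the residual curve never
#' reaches the noise floor the maximum grid frequency is returned with a
#' warning.
#'
#' @param x Numeric series (>= 100 samples).
#' @param fs Sampling rate, Hz.
#' @param grid Ascending candidate cutoffs, Hz, all below `fs/2`.
#' @param linear_fraction Fraction of the grid (from the top) treated as
#'   the linear noise region.
#' @param r2_min Minimum R-squared for the noise-region fit.
#' @return A cutoff frequency (scalar, Hz) from `grid`.
#' @export
residual_cutoff <- function(x, fs, grid = seq(1, 30, by = 0.5),
                            linear_fraction = 1 / 3, r2_min = 0.8) {
  if (length(x) < 100L)
    stop("insufficient data: residual method needs at least 100 samples",
         call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly ascending", call. = FALSE)
  if (any(grid <= 0) || any(grid >= fs / 2))
    stop("all grid frequencies must lie strictly inside (0, fs/2)",
         call. = FALSE)
  res <- vapply(grid, function(fc)
    sqrt(mean((x - butterworth_lowpass(x, fc, fs))^2)), numeric(1))
  fc <- select_cutoff_from_curve(res, grid, scale = sqrt(mean(x^2)),
                                 linear_fraction = linear_fraction,
                                 r2_min = r2_min)
  if (is.na(fc))
    stop("degenerate signal: no linear noise region in the residual curve (is the series noiseless?)",
         call. = FALSE)
  fc
}

#' Decimate a force series to the marker rate
#'
#' Anti-alias filters (zero-phase Butterworth, effective order 8, cutoff
#' at 0.4 x the target Nyquist frequency) and decimates a series sampled
#' at `fs_from` Hz down to `fs_to` Hz.  The rate ratio must be an
#' integer; sample 1 is retained so a shared start time stays aligned.
#'
#' @param x Numeric vector or matrix (series in columns) at `fs_from` Hz.
#' @param fs_from,fs_to Source and target sampling rates, Hz.
#' @param antialias Apply the anti-alias filter first (default TRUE).
#'   Disable only when the signal is known to be band-limited, e.g. for
#'   machine-precision checks on synthetic data.
#' @return The decimated vector/matrix at `fs_to` Hz.
#' @export
resample_to_rate <- function(x, fs_from, fs_to, antialias = TRUE) {
  k <- fs_from / fs_to
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf(
      "cannot resample: source rate %g Hz is not an integer multiple of target rate %g Hz",
      fs_from, fs_to), call. = FALSE)
  k <- as.integer(round(k))
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  if (k > 1L) {
    if (antialias) {
      fc <- 0.4 * (fs_to / 2)
      m <- apply(m, 2, butterworth_lowpass, fc = fc, fs = fs_from, order = 8)
    }
    m <- m[seq(1L, nrow(m), by = k), , drop = FALSE]
  }
  if (vec) drop(m) else m
}

#' Synchronize the force stream of a trial to the marker rate
#'
#' Brings the force-plate series of a trial down to the marker sampling
#' rate (see [resample_to_rate()]) and aligns the time bases from the
#' shared start time.
#'
#' @param trial A `skate_trial` (see [simulate_stride()]) or any list
#'   with fields `force`, `fs_force`, `fs_marker`, `time`.
#' @param antialias Passed to [resample_to_rate()].
#' @return The trial with `force` at the marker rate and
#'   `fs_force == fs_marker`.
#' @export
synchronize <- function(trial, antialias = TRUE) {
  trial$force <- resample_to_rate(trial$force, trial$fs_force,
                                  trial$fs_marker, antialias = antialias)
  n <- min(nrow(trial$force), length(trial$time))
  trial$force <- trial$force[seq_len(n), , drop = FALSE]
  trial$time_force <- trial$time[seq_len(n)]
  trial$fs_force <- trial$fs_marker
  trial
}

#' Per-frame local coordinate frame from CM velocity
#'
#' Builds the travel-aligned local frame used for all force components:
#' Y' is the unit horizontal component of the centre-of-mass velocity,
#' Z' is vertical up `(0, 0, 1)`, and X' = Y' x Z' (the skater's right).
#' The frame is undefined when the horizontal speed does not exceed
#' `eps`.
#'
#' @param cm_velocity n x 3 matrix (or length-3 vector) of CM velocity
#'   in m/s, global frame.
#' @param eps Stationarity threshold on horizontal speed, m/s.
#' @return An object of class `local_frame`: list of n x 3 matrices
#'   `X`, `Y`, `Z` of unit axis vectors.
#' @export
local_frame <- function(cm_velocity, eps = 0.1) {
  v <- if (is.null(dim(cm_velocity))) matrix(cm_velocity, nrow = 1)
       else as.matrix(cm_velocity)
  if (ncol(v) != 3L) stop("`cm_velocity` must have 3 columns", call. = FALSE)
  hs <- sqrt(v[, 1]^2 + v[, 2]^2)
  if (any(hs <= eps))
    stop(sprintf(
      "near-stationary: horizontal CM speed <= %g m/s in %d frame(s); local frame undefined",
      eps, sum(hs <= eps)), call. = FALSE)
  n <- nrow(v)
  Y <- cbind(v[, 1] / hs, v[, 2] / hs, 0)
  Z <- cbind(rep(0, n), rep(0, n), rep(1, n))
  X <- cbind(Y[, 2], -Y[, 1], 0)  # Y x Z
  structure(list(X = X, Y = Y, Z = Z, n = n), class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame> ", x$n, " frame(s); Y' = travel, Z' = up, X' = Y' x Z'\n",
      sep = "")
  invisible(x)
}

#' Express global vectors in the local frame
#'
#' @param vec n x 3 matrix (or length-3 vector) in the global frame.
#' @param frame A [local_frame()] with matching number of frames (or a
#'   single frame recycled).
#' @return n x 3 matrix of local components, columns `X`, `Y`, `Z`
#'   (the X', Y', Z' components).
#' @export
to_local <- function(vec, frame) {
  stopifnot(inherits(frame, "local_frame"))
  v <- if (is.null(dim(vec))) matrix(vec, nrow = 1) else as.matrix(vec)
  if (frame$n == 1L && nrow(v) > 1L) {
    frame <- local_frame_rep(frame, nrow(v))
  }
  if (nrow(v) != frame$n)
    stop("frame/vector length mismatch", call. = FALSE)
  out <- cbind(rowSums(v * frame$X), rowSums(v * frame$Y),
               rowSums(v * frame$Z))
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Express local-frame vectors in the global frame
#'
#' Inverse of [to_local()].
#'
#' @param vec_local n x 3 matrix of local components.
#' @param frame A [local_frame()].
#' @return n x 3 matrix in the global frame.
#' @export
to_global <- function(vec_local, frame) {
  stopifnot(inherits(frame, "local_frame"))
  v <- if (is.null(dim(vec_local))) matrix(vec_local, nrow = 1)
       else as.matrix(vec_local)
  if (frame$n == 1L && nrow(v) > 1L) frame <- local_frame_rep(frame, nrow(v))
  v[, 1] * frame$X + v[, 2] * frame$Y + v[, 3] * frame$Z
}

local_frame_rep <- function(frame, n) {
  rep_row <- function(m) m[rep(1L, n), , drop = FALSE]
  structure(list(X = rep_row(frame$X), Y = rep_row(frame$Y),
                 Z = rep_row(frame$Z), n = n), class = "local_frame")
}

#' Normalize forces by body weight
#'
#' Divides a force (vector series or scalar series, newtons) by the body
#' weight in newtons, giving dimensionless body-weight (BW) units.
#'
#' @param force_N Numeric vector or matrix of forces in newtons.
#' @param body_weight Body weight in newtons (> 0).
#' @return `force_N / body_weight`.
#' @export
normalize_by_bw <- function(force_N, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("invalid parameter: `body_weight` must be a positive scalar (newtons)",
         call. = FALSE)
  force_N / body_weight
}

#' Centre-of-mass velocity by central differences
#'
#' Differentiates a sampled position series with central differences
#' (one-sided at the endpoints).
#'
#' @param pos n x 3 matrix of positions (m).
#' @param fs Sampling rate, Hz.
#' @return n x 3 matrix of velocities (m/s).
#' @export
cm_velocity <- function(pos, fs) {
  p <- as.matrix(pos)
  n <- nrow(p)
  if (n < 3L) stop("insufficient data: need at least 3 samples", call. = FALSE)
  v <- matrix(0, n, ncol(p))
  v[2:(n - 1), ] <- (p[3:n, ] - p[1:(n - 2), ]) * fs / 2
  v[1, ] <- (p[2, ] - p[1, ]) * fs
  v[n, ] <- (p[n, ] - p[n - 1, ]) * fs
  v
}

#' Smooth all marker and CM trajectories of a trial
#'
#' Applies the zero-phase Butterworth filter to every coordinate of every
#' marker and of the CM trajectory.  Under the `"residual"` policy a
#' cutoff is selected per coordinate with [residual_cutoff()] and clipped
#' to `clip` (default 9-15 Hz, the range typical for skating marker
#' data); coordinates whose residual curve is degenerate (e.g. noiseless
#' synthetic data) fall back to the upper clip bound, the least
#' aggressive smoothing.  A numeric policy applies that fixed cutoff
#' everywhere.
#'
#' @param trial A `skate_trial`.
#' @param cutoff_policy `"residual"` or a fixed cutoff in Hz.
#' @param clip Length-2 numeric, allowed cutoff range for the residual
#'   policy.
#' @param grid Candidate grid for [residual_cutoff()].
#' @return The trial with smoothed `markers` and `cm`; selected cutoffs
#'   are stored in `trial$cutoffs`.
#' @export
filter_trial <- function(trial, cutoff_policy = "residual",
                         clip = c(9, 15), grid = seq(1, 30, by = 0.5)) {
  fs <- trial$fs_marker
  labels <- c(names(trial$markers), "cm")
  big <- do.call(cbind, c(trial$markers, list(trial$cm)))
  if (is.numeric(cutoff_policy)) {
    fcs <- rep(cutoff_policy, ncol(big))
  } else {
    res <- residual_curves(big, fs, grid)
    fcs <- vapply(seq_len(ncol(big)), function(j) {
      fc <- select_cutoff_from_curve(res[j, ], grid,
                                     scale = sqrt(mean(big[, j]^2)),
                                     warn = FALSE)
      if (is.na(fc)) clip[2] else min(max(fc, clip[1]), clip[2])
    }, numeric(1))
  }
  out <- big
  for (fc in unique(fcs)) {
    cols <- which(fcs == fc)
    out[, cols] <- bw_lowpass_mat(big[, cols, drop = FALSE], fc, fs)
  }
  cutoffs <- lapply(setNames(seq_along(labels), labels),
                    function(i) fcs[(3 * (i - 1) + 1):(3 * i)])
  trial$markers <- lapply(setNames(seq_along(trial$markers),
                                   names(trial$markers)),
                          function(i) out[, (3 * (i - 1) + 1):(3 * i),
                                          drop = FALSE])
  trial$cm <- out[, (3 * (length(labels) - 1) + 1):(3 * length(labels)),
                  drop = FALSE]
  trial$cutoffs <- cutoffs
  trial$filtered <- TRUE
  trial
}
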