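# Sole-normal direction estimators (Est1: blade + ankle, Est2: blade +
# knee), projection of the measured resultant onto the estimated
# direction, left/right mirroring, and the linear per-component
# correction.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(m) sqrt(rowSums(m^2))

unitize <- function(m) m / rownorm(m)

as_mat3 <- function(x, name) {
  m <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(m) != 3L)
    stop(sprintf("`%s` must have 3 columns (x, y, z)", name), call. = FALSE)
  m
}

#' Estimate the sole-normal GRF direction from blade and joint markers
#'
#' Builds the estimated unit direction of the ground reaction force from
#' the supporting-leg posture, assuming the force acts perpendicular to
#' the shoe sole.  The blade axis `y_b` runs from the rear end of the
#' blade to its front end; the lever runs from the rear end to the joint
#' centre (ankle for Est1, knee for Est2); `x_b` is the unit cross
#' product of `y_b` and the lever, and the estimated direction `z_b` is
#' the unit cross product of `y_b` and `x_b`, sign-fixed to point upward
#' (`z_b . (0,0,1) > 0`).  The literal cross-product order yields a
#' downward vector, so the upward sign convention is enforced
#' explicitly; `z_b` is perpendicular to the blade axis by construction.
#'
#' @param rear,front Blade rear/front end positions, n x 3 (m, global).
#' @param joint Joint-centre positions, n x 3: the ankle centre for
#'   `method = "est1"`, the knee centre for `method = "est2"`.
#' @param method `"est1"` (blade + ankle) or `"est2"` (blade + knee).
#' @return An object of class `direction_estimate` with fields `method`,
#'   `z_b` (n x 3 unit directions, global frame) and `y_b` (unit blade
#'   axis).
#' @examples
#' estimate_direction(c(0, 0, 0), c(0.3, 0, 0), c(0.15, 0, 0.40), "est1")$z_b
#' @export
estimate_direction <- function(rear, front, joint, method = c("est2", "est1")) {
  method <- match.arg(method)
  rear <- as_mat3(rear, "rear"); front <- as_mat3(front, "front")
  joint <- as_mat3(joint, "joint")
  if (nrow(rear) != nrow(front) || nrow(rear) != nrow(joint))
    stop("`rear`, `front` and `joint` must have the same number of frames",
         call. = FALSE)
  yb_raw <- front - rear
  bl <- rownorm(yb_raw)
  if (any(bl <= 1e-6))
    stop("geometry error: blade ends coincide (|front - rear| <= 1e-6 m)",
         call. = FALSE)
  yb <- yb_raw / bl
  lever <- joint - rear
  ln <- rownorm(lever)
  xb_raw <- cross3(yb, lever)
  sin_angle <- rownorm(xb_raw) / pmax(ln, .Machine$double.eps)
  if (any(ln <= 1e-6) || any(sin_angle <= 1e-4))
    stop("geometry error: joint centre is collinear with the blade axis",
         call. = FALSE)
  xb <- unitize(xb_raw)
  zb <- unitize(cross3(yb, xb))
  flip <- zb[, 3] < 0
  zb[flip, ] <- -zb[flip, ]
  structure(list(method = method, z_b = zb, y_b = yb, x_b = xb),
            class = "direction_estimate")
}

#' @export
print.direction_estimate <- function(x, ...) {
  cat(sprintf("<direction_estimate> method=%s, %d frame(s)\n",
              x$method, nrow(x$z_b)))
  invisible(x)
}

#' GRF components from the measured resultant and estimated direction
#'
#' The estimated force vector is the measured resultant magnitude
#' multiplied, frame by frame, by the components of the estimated unit
#' direction: `F_est = F_sigma * e`.
#'
#' @param f_sigma Per-frame resultant force magnitude, BW units (>= 0).
#' @param e_local n x 3 per-frame unit direction in the local frame
#'   (columns X', Y', Z').
#' @param method Method tag carried through (`"est1"`/`"est2"`).
#' @return An object of class `estimated_grf`: list with `components`
#'   (n x 3, BW), `method`, `corrected = FALSE`.
#' @export
grf_components <- function(f_sigma, e_local, method = "est2") {
  e <- as_mat3(e_local, "e_local")
  if (length(f_sigma) != nrow(e))
    stop("`f_sigma` and `e_local` must have the same number of frames",
         call. = FALSE)
  if (any(f_sigma < 0))
    stop("`f_sigma` must be non-negative", call. = FALSE)
  dev <- abs(rownorm(e) - 1)
  if (any(dev > 1e-6))
    stop(sprintf("contract error: `e_local` is not a unit vector (max |norm - 1| = %.2e)",
                 max(dev)), call. = FALSE)
  comp <- f_sigma * e
  colnames(comp) <- c("X", "Y", "Z")
  structure(list(components = comp, method = method, corrected = FALSE),
            class = "estimated_grf")
}

#' @export
print.estimated_grf <- function(x, ...) {
  cat(sprintf("<estimated_grf> method=%s%s, %d frame(s), peak |F| = %.3f BW\n",
              x$method, if (x$corrected) " (corrected)" else "",
              nrow(x$components), max(rownorm(x$components))))
  invisible(x)
}

#' Mirror left-leg data onto the right
#'
#' Straight skating is bilaterally symmetric, so left-leg series are
#' pooled with right-leg data after negating the lateral X' component
#' (Y' and Z' unchanged).  Applies to local-frame force components and
#' estimated directions alike.  The operation is an involution.
#'
#' @param x An n x 3 matrix of local components, or an `estimated_grf`.
#' @return Object of the same type with the X' column negated.
#' @export
mirror_left <- function(x) {
  if (inherits(x, "estimated_grf")) {
    x$components[, 1] <- -x$components[, 1]
    return(x)
  }
  m <- as_mat3(x, "x")
  m[, 1] <- -m[, 1]
  if (is.null(dim(x))) drop(m) else m
}

#' Linear per-component correction model
#'
#' A slope/intercept pair per local component, mapping an estimated
#' component to a corrected one: `out_c = slope_c * in_c + intercept_c`.
#' [default_correction_model()] carries the coefficients fitted for the
#' left leg during curve skating (true value regressed on Est2 estimate,
#' all phases pooled): slopes 0.847/0.596/0.987 and intercepts
#' -0.029/-0.025/+0.030 for X'/Y'/Z'.  That model is scoped to
#' curve-left data; applying it elsewhere requires an explicit override.
#'
#' @param slope,intercept Length-3 numeric vectors (X', Y', Z' order),
#'   BW units; slopes must be finite and nonzero.
#' @param scope Motion the model was fitted for (informational;
#'   `"curve-left"` for the default model).
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(slope, intercept, scope = "fitted") {
  slope <- setNames(as.numeric(slope), c("X", "Y", "Z"))
  intercept <- setNames(as.numeric(intercept), c("X", "Y", "Z"))
  if (length(slope) != 3L || length(intercept) != 3L)
    stop("`slope` and `intercept` must each have 3 components", call. = FALSE)
  if (any(!is.finite(slope)) || any(slope == 0))
    stop("slopes must be finite and nonzero", call. = FALSE)
  if (any(!is.finite(intercept)))
    stop("intercepts must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, scope = scope),
            class = "correction_model")
}

#' @rdname correction_model
#' @export
default_correction_model <- function() {
  correction_model(slope = c(0.847, 0.596, 0.987),
                   intercept = c(-0.029, -0.025, 0.030),
                   scope = "curve-left")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model> scope:", x$scope, "\n")
  for (c_ in c("X", "Y", "Z"))
    cat(sprintf("  %s': corrected = %.3f * est %+.3f\n",
                c_, x$slope[c_], x$intercept[c_]))
  invisible(x)
}

#' Apply a linear correction to estimated GRF components
#'
#' Substitutes each estimated component into its regression equation:
#' `out_c = slope_c * in_c + intercept_c`.  After correction the
#' component vector no longer has the measured resultant as its norm.
#' A warning is issued when the input was not produced by Est2 (the
#' method the default model was fitted for) or when the model's motion
#' scope does not match `motion`.
#'
#' @param est An `estimated_grf` or an n x 3 component matrix (BW).
#' @param model A [correction_model()]; default the curve-left model.
#' @param motion Motion label of the data (used for the scope check);
#'   `NULL` skips the check.
#' @return Same type as `est`, corrected (`estimated_grf` gains
#'   `corrected = TRUE` and method tag `"est2c"` when input was est2).
#' @export
apply_correction <- function(est, model = default_correction_model(),
                             motion = NULL) {
  stopifnot(inherits(model, "correction_model"))
  if (!is.null(motion) && !identical(model$scope, "fitted") &&
      !identical(motion, model$scope))
    warning(sprintf(
      "correction model was fitted for '%s' data but is being applied to '%s' data",
      model$scope, motion))
  fix <- function(m) {
    out <- sweep(sweep(m, 2, model$slope, `*`), 2, model$intercept, `+`)
    colnames(out) <- c("X", "Y", "Z")
    out
  }
  if (inherits(est, "estimated_grf")) {
    if (!identical(est$method, "est2"))
      warning(sprintf("correction is intended for est2 estimates, not '%s'",
                      est$method))
    est$components <- fix(est$components)
    est$corrected <- TRUE
    if (identical(est$method, "est2")) est$method <- "est2c"
    return(est)
  }
  fix(as_mat3(est, "est"))
}

#' Fit a linear correction from paired true/estimated components
#'
#' Ordinary least squares per component, with the true (force-plate)
#' value on the vertical axis and the estimate on the horizontal axis,
#' pooled over all supplied frames/time points.
#'
#' @param true_components,est_components n x 3 matrices of paired local
#'   components (BW), columns X', Y', Z'.
#' @param scope Scope label recorded on the returned model.
#' @return A [correction_model()].
#' @export
fit_correction <- function(true_components, est_components,
                           scope = "fitted") {
  tr <- as_mat3(true_components, "true_components")
  es <- as_mat3(est_components, "est_components")
  if (nrow(tr) != nrow(es))
    stop("paired series must have the same number of rows", call. = FALSE)
  if (nrow(tr) < 3L)
    stop("insufficient data: need at least 3 paired frames", call. = FALSE)
  slope <- numeric(3); icept <- numeric(3)
  for (j in 1:3) {
    keep <- is.finite(tr[, j]) & is.finite(es[, j])
    if (sum(keep) < 3L)
      stop("insufficient data: need at least 3 finite pairs per component",
           call. = FALSE)
    x <- es[keep, j]; y <- tr[keep, j]
    if (var(x) <= 0)
      stop("fit error: zero variance in the estimated component", call. = FALSE)
    cf <- lm.fit(cbind(1, x), y)$coefficients
    icept[j] <- cf[1]; slope[j] <- cf[2]
  }
  correction_model(slope, icept, scope = scope)
}

#' Inject a known linear miscalibration into estimated components
#'
#' Inverse of [apply_correction()]: transforms components so that the
#' original values satisfy `original = slope * distorted + intercept`
#' (up to optional Gaussian measurement noise).  Used to build
#' validation datasets in which the true/estimate relation follows a
#' prescribed linear model, e.g. to check that [fit_correction()]
#' recovers known coefficients.
#'
#' @param components n x 3 matrix (BW).
#' @param model A [correction_model()] holding the target relation.
#' @param noise_sd Gaussian noise added after the transform (BW).
#' @return n x 3 distorted matrix.
#' @export
distort_components <- function(components, model = default_correction_model(),
                               noise_sd = 0) {
  m <- as_mat3(components, "components")
  out <- sweep(sweep(m, 2, model$intercept, `-`), 2, model$slope, `/`)
  if (noise_sd > 0) out <- out + matrix(rnorm(length(out), sd = noise_sd),
                                        nrow(out), ncol(out))
  colnames(out) <- c("X", "Y", "Z")
  out
}
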