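# Stride phase segmentation, force-plate analyzability masking, and
# 20/60/20 time normalisation onto the 0-100% grid.

#' Blade contact/off event times
#'
#' The supporting-leg period of the analysed leg is bounded by four
#' events: the analysed blade touching down (`analyzed_on`), the
#' opposite blade leaving the ground (`opposite_off`), the opposite
#' blade touching down again (`opposite_on`), and the analysed blade
#' leaving the ground (`analyzed_off`).  They must satisfy
#' `analyzed_on < opposite_off <= opposite_on < analyzed_off`.
#'
#' @param analyzed_on,opposite_off,opposite_on,analyzed_off Event times
#'   in seconds.
#' @return Object of class `blade_events`.
#' @export
blade_events <- function(analyzed_on, opposite_off, opposite_on,
                         analyzed_off) {
  ev <- c(analyzed_on = analyzed_on, opposite_off = opposite_off,
          opposite_on = opposite_on, analyzed_off = analyzed_off)
  if (!all(is.finite(ev))) stop("event times must be finite", call. = FALSE)
  if (!(analyzed_on < opposite_off))
    stop("event order violated: analyzed_on must precede opposite_off",
         call. = FALSE)
  if (!(opposite_off <= opposite_on))
    stop("event order violated: opposite_off must not follow opposite_on",
         call. = FALSE)
  if (!(opposite_on < analyzed_off))
    stop("event order violated: opposite_on must precede analyzed_off",
         call. = FALSE)
  structure(as.list(ev), class = "blade_events")
}

#' Segment the supporting-leg period into phases
#'
#' Labels every frame as `contact` (analysed blade down, opposite blade
#' still down), `single_support` (only the analysed blade down),
#' `push_off` (opposite blade down again), or `outside` the supporting
#' period.  Each phase runs from its opening event to one frame before
#' the closing event (half-open intervals on the sampled time base).
#'
#' @param events A [blade_events()].
#' @param time Per-frame times, seconds (ascending).
#' @return Object of class `phase_segmentation`: list with `time`,
#'   `phase` (factor) and `events`.
#' @export
segment_phases <- function(events, time) {
  stopifnot(inherits(events, "blade_events"))
  phase <- rep("outside", length(time))
  phase[time >= events$analyzed_on & time < events$opposite_off] <- "contact"
  phase[time >= events$opposite_off & time < events$opposite_on] <- "single_support"
  phase[time >= events$opposite_on & time < events$analyzed_off] <- "push_off"
  phase <- factor(phase,
                  levels = c("contact", "single_support", "push_off", "outside"))
  structure(list(time = time, phase = phase, events = events),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>\n")
  print(table(x$phase))
  invisible(x)
}

#' Select frames in which only the analysed blade loads the force plate
#'
#' A frame can be used for verification only when the force plate
#' measures the analysed blade alone: both endpoints of the analysed
#' blade must lie inside the plate rectangle, and the opposite blade
#' must either be airborne or be in ground contact entirely outside the
#' plate.  Frames where the analysed blade straddles the plate edge, or
#' where any part of the opposite blade is also on the plate, are
#' excluded.
#'
#' @param analyzed_rear,analyzed_front n x 2 matrices of the analysed
#'   blade end positions projected on the course plane (m).  Extra
#'   columns (e.g. z) are ignored.
#' @param opposite_rear,opposite_front Same for the opposite blade; may
#'   be `NULL` when `opposite_airborne` is `TRUE` everywhere.
#' @param opposite_airborne Logical per frame: opposite blade off the
#'   ground.
#' @param plate Axis-aligned plate rectangle
#'   `c(xmin, xmax, ymin, ymax)` in course coordinates (default the
#'   0.6 m x 5.4 m plate).
#' @return Logical vector, `TRUE` for analyzable frames.
#' @export
analyzable_mask <- function(analyzed_rear, analyzed_front,
                            opposite_rear = NULL, opposite_front = NULL,
                            opposite_airborne,
                            plate = c(0, 0.6, 0, 5.4)) {
  if (length(plate) != 4L || plate[1] >= plate[2] || plate[3] >= plate[4])
    stop("geometry error: degenerate plate rectangle", call. = FALSE)
  xy <- function(m) as.matrix(m)[, 1:2, drop = FALSE]
  inside <- function(m) {
    m[, 1] >= plate[1] & m[, 1] <= plate[2] &
      m[, 2] >= plate[3] & m[, 2] <= plate[4]
  }
  ar <- xy(analyzed_rear); af <- xy(analyzed_front)
  n <- nrow(ar)
  opposite_airborne <- rep_len(as.logical(opposite_airborne), n)
  analyzed_ok <- inside(ar) & inside(af)
  if (is.null(opposite_rear) || is.null(opposite_front)) {
    if (!all(opposite_airborne))
      stop("opposite blade positions are required for frames where it is on the ground",
           call. = FALSE)
    opposite_ok <- opposite_airborne
  } else {
    or_ <- xy(opposite_rear); of_ <- xy(opposite_front)
    opposite_ok <- opposite_airborne | (!inside(or_) & !inside(of_))
  }
  analyzed_ok & opposite_ok
}

#' Normalize a per-frame series onto the 20/60/20 percent grid
#'
#' Maps the three phases onto fixed bands of normalised stride time --
#' contact to 0-20%, single support to 20-80%, push-off to 80-100% --
#' and resamples the series at 1% steps (101 grid points, endpoints
#' included) with a cubic spline fitted per phase on the masked-valid
#' frames, so phase boundaries act as knots and no information leaks
#' across support transitions.  A grid point is marked valid only when
#' its phase had at least two valid frames and the nearest valid source
#' frame lies within `max_gap_pct` of stride.
#'
#' @param values Per-frame numeric series.
#' @param seg A [segment_phases()] result for the same frames.
#' @param mask Logical per frame (e.g. from [analyzable_mask()]);
#'   `NULL` means all frames usable.
#' @param max_gap_pct Maximum distance (percent of stride) from a grid
#'   point to the nearest valid source frame.
#' @return Object of class `normalized_series`: list with `pct`
#'   (0:100), `values` (length 101, `NA` where invalid) and `valid`.
#' @export
phase_normalize <- function(values, seg, mask = NULL, max_gap_pct = 2) {
  stopifnot(inherits(seg, "phase_segmentation"))
  n <- length(seg$time)
  if (length(values) != n)
    stop("`values` and segmentation must cover the same frames", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n)
  ev <- seg$events
  bands <- list(contact = c(0, 20), single_support = c(20, 80),
                push_off = c(80, 100))
  tspan <- list(contact = c(ev$analyzed_on, ev$opposite_off),
                single_support = c(ev$opposite_off, ev$opposite_on),
                push_off = c(ev$opposite_on, ev$analyzed_off))
  pct <- 0:100
  out <- rep(NA_real_, 101L)
  ok <- rep(FALSE, 101L)
  for (p in names(bands)) {
    i <- which(seg$phase == p & mask & is.finite(values))
    if (length(i) < 2L) next
    ts <- tspan[[p]]
    if (diff(ts) <= 0) next
    b <- bands[[p]]
    src_pct <- b[1] + diff(b) * (seg$time[i] - ts[1]) / diff(ts)
    gp <- pct[pct >= b[1] & pct <= b[2]]
    f <- if (length(i) >= 4L) splinefun(src_pct, values[i], method = "fmm")
         else approxfun(src_pct, values[i], rule = 2)
    v <- f(gp)
    valid_gp <- vapply(gp, function(g) min(abs(g - src_pct)) <= max_gap_pct,
                       logical(1))
    gi <- gp + 1L
    # later phases own their boundary points, but never clobber a valid
    # value with an invalid one
    take <- valid_gp | !ok[gi]
    out[gi[take]] <- v[take]
    ok[gi] <- ok[gi] | valid_gp
  }
  structure(list(pct = pct, values = out, valid = ok),
            class = "normalized_series")
}

#' Aggregate normalized series across trials
#'
#' Mean, standard deviation and per-grid-point sample size over a list
#' of [phase_normalize()] results.  Because frame selection differs
#' between trials, `n` varies along the grid and is at most the number
#' of trials supplied.
#'
#' @param series_list List of `normalized_series`.
#' @return List with `pct`, `mean`, `sd`, `n` (each length 101).
#' @export
aggregate_normalized <- function(series_list) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "normalized_series")))
  vals <- vapply(series_list, function(s) {
    v <- s$values
    v[!s$valid] <- NA_real_
    v
  }, numeric(101L))
  vals <- matrix(vals, nrow = 101L)
  n <- rowSums(!is.na(vals))
  mean_ <- rowMeans(vals, na.rm = TRUE)
  mean_[n == 0L] <- NA_real_
  sd_ <- apply(vals, 1, function(r) if (sum(!is.na(r)) >= 2L) sd(r, na.rm = TRUE) else NA_real_)
  list(pct = 0:100, mean = mean_, sd = sd_, n = n)
}
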