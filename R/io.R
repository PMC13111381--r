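# Readers and writers for the formats the pipeline touches: TRC marker
# files, force / events / paired-sample CSVs, agreement reports and
# correction models.  All writes are atomic (temp file + rename).

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("I/O error: cannot write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a TRC marker trajectory file
#'
#' Parses the standard TRC layout (header block with `DataRate`,
#' `NumMarkers` and `Units`, a marker-name row, a coordinate-label row,
#' then one row per frame).  Positions are converted to metres; blank
#' cells (marker gaps) become `NA`.
#'
#' @param path File path.
#' @return List with `markers` (named list of n x 3 matrices, metres),
#'   `rate` (Hz), `time` (s) and `units` (as declared in the file).
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hi <- grep("^DataRate\\b", lines)
  if (!length(hi))
    stop(sprintf("parse error in '%s': no DataRate header line", path),
         call. = FALSE)
  hi <- hi[1]
  keys <- strsplit(lines[hi], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[hi + 1L], "\t", fixed = TRUE)[[1]]
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i) || i > length(vals))
      stop(sprintf("parse error in '%s' (line %d): missing %s",
                   path, hi, key), call. = FALSE)
    vals[i]
  }
  rate <- as.numeric(get("DataRate"))
  n_markers <- as.integer(get("NumMarkers"))
  units <- get("Units")
  scale <- switch(units, mm = 1e-3, m = 1,
                  stop(sprintf("unit error in '%s': unknown units '%s'",
                               path, units), call. = FALSE))
  name_row <- strsplit(lines[hi + 2L], "\t", fixed = TRUE)[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[nzchar(marker_names)]
  if (length(marker_names) != n_markers)
    stop(sprintf("parse error in '%s' (line %d): %d marker names but NumMarkers=%d",
                 path, hi + 2L, length(marker_names), n_markers),
         call. = FALSE)
  data_lines <- lines[seq.int(hi + 4L, length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_exp <- 2L + 3L * n_markers
  mat <- t(vapply(fields, function(f) {
    f <- c(f, rep("", max(0L, ncol_exp - length(f))))
    suppressWarnings(as.numeric(f[seq_len(ncol_exp)]))
  }, numeric(ncol_exp)))
  time <- mat[, 2]
  markers <- list()
  for (j in seq_len(n_markers)) {
    cols <- 2L + (3L * (j - 1L) + 1L):(3L * j)
    markers[[marker_names[j]]] <- mat[, cols, drop = FALSE] * scale
  }
  list(markers = markers, rate = rate, time = time, units = units)
}

#' Write marker trajectories to a TRC file
#'
#' @param markers Named list of n x 3 matrices in metres.
#' @param rate Sampling rate, Hz.
#' @param path Output path.
#' @param units `"mm"` or `"m"` for the written coordinates.
#' @return The path, invisibly.
#' @export
write_trc <- function(markers, rate, path, units = "mm") {
  scale <- switch(units, mm = 1e3, m = 1,
                  stop("unknown units", call. = FALSE))
  n <- nrow(markers[[1]])
  nm <- length(markers)
  name_row <- paste(c("Frame#", "Time",
                      unlist(lapply(names(markers), function(s) c(s, "", "")))),
                    collapse = "\t")
  coord_row <- paste(c("", "", unlist(lapply(seq_len(nm), function(j)
    paste0(c("X", "Y", "Z"), j)))), collapse = "\t")
  body <- vapply(seq_len(n), function(i) {
    coords <- unlist(lapply(markers, function(m) m[i, ] * scale))
    paste(c(i, sprintf("%.6f", (i - 1) / rate),
            sprintf("%.6f", coords)), collapse = "\t")
  }, character(1))
  atomic_write(path, function(tmp) {
    writeLines(c(
      paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
      paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
            sep = "\t"),
      paste(rate, rate, n, nm, units, rate, 1, n, sep = "\t"),
      name_row, coord_row, body), tmp)
  })
}

#' Read/write force-plate CSV (`time,fx,fy,fz`, newtons, global frame)
#'
#' @param path File path.
#' @return `read_forces_csv`: list with `time` (s), `force` (n x 3, N).
#' @export
read_forces_csv <- function(path) {
  d <- read.csv(path)
  req <- c("time", "fx", "fy", "fz")
  if (!all(req %in% names(d)))
    stop(sprintf("parse error in '%s': need columns %s", path,
                 paste(req, collapse = ",")), call. = FALSE)
  list(time = d$time, force = as.matrix(d[, c("fx", "fy", "fz")]))
}

#' @rdname read_forces_csv
#' @param time,force Series to write.
#' @export
write_forces_csv <- function(time, force, path) {
  d <- data.frame(time = time, fx = force[, 1], fy = force[, 2],
                  fz = force[, 3])
  atomic_write(path, function(tmp)
    write.csv(d, tmp, row.names = FALSE, quote = FALSE))
}

#' Read/write blade events CSV
#'
#' Columns `trial,analyzed_on,opposite_off,opposite_on,analyzed_off`
#' (seconds).
#'
#' @param path File path.
#' @return `read_events_csv`: list of [blade_events()], named by trial.
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path)
  req <- c("trial", "analyzed_on", "opposite_off", "opposite_on",
           "analyzed_off")
  if (!all(req %in% names(d)))
    stop(sprintf("parse error in '%s': need columns %s", path,
                 paste(req, collapse = ",")), call. = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    blade_events(d$analyzed_on[i], d$opposite_off[i], d$opposite_on[i],
                 d$analyzed_off[i]))
  names(out) <- d$trial
  out
}

#' @rdname read_events_csv
#' @param events Named list of [blade_events()].
#' @export
write_events_csv <- function(events, path) {
  d <- do.call(rbind, lapply(names(events), function(nm) {
    ev <- events[[nm]]
    data.frame(trial = nm, analyzed_on = ev$analyzed_on,
               opposite_off = ev$opposite_off,
               opposite_on = ev$opposite_on,
               analyzed_off = ev$analyzed_off, stringsAsFactors = FALSE)
  }))
  atomic_write(path, function(tmp)
    write.csv(d, tmp, row.names = FALSE, quote = FALSE))
}

#' Write / read an agreement report
#'
#' CSV columns mirror the per-time-point verification layout (n,
#' mean +/- sd of both methods, regression slope/intercept, ICC and
#' category, bias, precision, LoA, bias CI, error flags, proportional
#' slope with CI).  Round-trips field for field.
#'
#' @param report An [timepoint_report()] result.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path (write) / the report (read).
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    atomic_write(path, function(tmp)
      write.csv(df, tmp, row.names = FALSE))
  } else {
    atomic_write(path, function(tmp)
      jsonlite::write_json(list(threshold = attr(report, "threshold"),
                                rows = df),
                           tmp, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null"))
  }
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    thr <- 0.08
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$rows)
    thr <- obj$threshold
  }
  attr(df, "threshold") <- thr
  class(df) <- c("agreement_report", "data.frame")
  df
}

#' Serialize / load a correction model as JSON
#'
#' JSON layout: `{component: {slope, intercept}}` plus a `scope` field.
#'
#' @param model A [correction_model()].
#' @param path File path.
#' @return The path (write) / a [correction_model()] (read).
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  obj <- list(scope = model$scope)
  for (co in c("X", "Y", "Z"))
    obj[[co]] <- list(slope = unname(model$slope[co]),
                      intercept = unname(model$intercept[co]))
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  correction_model(
    slope = c(obj$X$slope, obj$Y$slope, obj$Z$slope),
    intercept = c(obj$X$intercept, obj$Y$intercept, obj$Z$intercept),
    scope = obj$scope %||% "fitted")
}

#' Write / read a full trial bundle
#'
#' A trial is stored as plain-text files sharing a prefix: markers
#' (TRC, including the CM and opposite-blade trajectories), forces
#' (CSV, newtons), events (CSV), metadata (JSON: body weight, side,
#' motion, rates, plate, seed) and, when present, the ground truth
#' (CSV: resultant, direction, local components, opposite-airborne
#' flag).
#'
#' @param trial A `skate_trial`.
#' @param prefix Path prefix (e.g. `"out/trial001"`).
#' @return `write_trial`: the prefix, invisibly.  `read_trial`: a
#'   `skate_trial`.
#' @export
write_trial <- function(trial, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  mk <- c(trial$markers, list(CM = trial$cm,
                              opp_rear = trial$opposite$rear,
                              opp_front = trial$opposite$front))
  write_trc(mk, trial$fs_marker, paste0(prefix, "_markers.trc"))
  write_forces_csv(trial$time_force, trial$force,
                   paste0(prefix, "_forces.csv"))
  write_events_csv(setNames(list(trial$events), basename(prefix)),
                   paste0(prefix, "_events.csv"))
  meta <- list(body_weight_N = trial$body_weight, side = trial$side,
               motion = trial$motion, marker_rate_hz = trial$fs_marker,
               force_rate_hz = trial$fs_force, plate = trial$plate,
               seed = trial$config$seed,
               participant = trial$participant,
               trial_id = trial$trial_id)
  atomic_write(paste0(prefix, "_meta.json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         na = "null"))
  if (!is.null(trial$truth)) {
    tr <- trial$truth
    d <- data.frame(time = trial$time, f_sigma = tr$f_sigma,
                    dir_x = tr$dir_global[, 1], dir_y = tr$dir_global[, 2],
                    dir_z = tr$dir_global[, 3],
                    tX = tr$components_local[, 1],
                    tY = tr$components_local[, 2],
                    tZ = tr$components_local[, 3],
                    opposite_airborne = trial$opposite$airborne)
    atomic_write(paste0(prefix, "_truth.csv"), function(tmp)
      write.csv(d, tmp, row.names = FALSE, quote = FALSE))
  }
  invisible(prefix)
}

#' @rdname write_trial
#' @export
read_trial <- function(prefix) {
  trc <- read_trc(paste0(prefix, "_markers.trc"))
  fr <- read_forces_csv(paste0(prefix, "_forces.csv"))
  ev <- read_events_csv(paste0(prefix, "_events.csv"))[[1]]
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  n <- nrow(trc$markers[[1]])
  truth <- NULL
  airborne <- rep(TRUE, n)
  truth_path <- paste0(prefix, "_truth.csv")
  if (file.exists(truth_path)) {
    td <- read.csv(truth_path)
    airborne <- as.logical(td$opposite_airborne)
    comp <- as.matrix(td[, c("tX", "tY", "tZ")])
    colnames(comp) <- c("X", "Y", "Z")
    truth <- list(f_sigma = td$f_sigma,
                  dir_global = as.matrix(td[, c("dir_x", "dir_y", "dir_z")]),
                  components_local = comp)
  }
  structure(list(
    time = trc$time, fs_marker = trc$rate,
    markers = trc$markers[c("blade_rear", "blade_front", "ankle", "knee")],
    cm = trc$markers$CM,
    force = fr$force, time_force = fr$time,
    fs_force = meta$force_rate_hz,
    body_weight = meta$body_weight_N,
    side = meta$side, motion = meta$motion,
    events = ev, plate = unlist(meta$plate),
    opposite = list(rear = trc$markers$opp_rear,
                    front = trc$markers$opp_front,
                    airborne = airborne),
    truth = truth,
    config = list(seed = meta$seed),
    participant = meta$participant %||% NA_character_,
    trial_id = meta$trial_id %||% NA_integer_),
    class = "skate_trial")
}

#' Read / write paired-sample CSVs
#'
#' Columns `participant,trial,motion,component,pct,true_bw,est_bw`.
#'
#' @param path File path.
#' @return `read_pairs_csv`: the paired-sample data frame.
#' @export
read_pairs_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "trial", "motion", "component", "pct",
           "true_bw", "est_bw")
  if (!all(req %in% names(d)))
    stop(sprintf("parse error in '%s': need columns %s", path,
                 paste(req, collapse = ",")), call. = FALSE)
  d
}

#' @rdname read_pairs_csv
#' @param pairs Paired-sample data frame.
#' @export
write_pairs_csv <- function(pairs, path) {
  atomic_write(path, function(tmp)
    write.csv(pairs, tmp, row.names = FALSE, quote = FALSE))
}
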