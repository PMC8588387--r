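#' @keywords internal
"_PACKAGE"

#' Stimulus identifiers
#'
#' The six graphomotor drawing tasks handled by the package: three tracing
#' circuits (parallel lines, labyrinth, oval), two shape-copying tasks and
#' the cursive loops task.
#'
#' @format Character vector of length 6.
#' @export
GRAPHO_STIMULI <- c("circuit1", "circuit2", "circuit3",
                    "shapes1", "shapes2", "loops")

#' Construct subject metadata
#'
#' @param subject_id Opaque subject identifier.
#' @param age_days Chronological age in days (> 0).
#' @param gender `"F"` or `"M"`.
#' @param laterality `"left"` or `"right"` handedness.
#' @param group Diagnostic group: `"TD"`, `"DYS"` or `"unlabeled"`. A label
#'   is only required for subjects entering the classification step.
#' @param origin Recruitment site, `"school"` or `"hospital"`.
#' @return A list of class `grapho_meta`.
#' @export
subject_meta <- function(subject_id, age_days, gender = c("F", "M"),
                         laterality = c("right", "left"),
                         group = c("unlabeled", "TD", "DYS"),
                         origin = c("school", "hospital")) {
  gender <- match.arg(gender)
  laterality <- match.arg(laterality)
  group <- match.arg(group)
  origin <- match.arg(origin)
  if (!is.numeric(age_days) || length(age_days) != 1L || !is.finite(age_days) ||
      age_days <= 0)
    stop("`age_days` must be a single positive number", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 age_days = as.numeric(age_days),
                 gender = gender, laterality = laterality,
                 group = group, origin = origin),
            class = "grapho_meta")
}

#' Construct a pen recording
#'
#' A recording is one child's trajectory for one stimulus: a uniformly
#' sampled time series of pen-tip position with an on-paper flag, plus
#' acquisition parameters and subject metadata. Coordinates follow the
#' mathematical convention: x grows rightward, y grows upward, origin at
#' the tablet lower-left. `pen_down` is authoritative for stroke
#' segmentation; the pen height `z` (valid up to 10 mm above the surface)
#' is retained but not used to segment.
#'
#' @param stimulus_id One of [GRAPHO_STIMULI].
#' @param samples Data frame with columns `t` (s), `x`, `y`, `z` (mm) and
#'   `pen_down` (logical or 0/1).
#' @param sampling_rate Nominal sampling rate in Hz (default 200).
#' @param spatial_resolution Tablet resolution in mm per count (default 0.25).
#' @param meta A [subject_meta()] object (optional).
#' @param validate Check invariants (strictly increasing time, at least one
#'   pen-down sample)? Default `TRUE`.
#' @return An object of class `grapho_recording`.
#' @export
recording <- function(stimulus_id, samples, sampling_rate = 200,
                      spatial_resolution = 0.25, meta = NULL,
                      validate = TRUE) {
  stimulus_id <- match.arg(stimulus_id, GRAPHO_STIMULI)
  required <- c("t", "x", "y", "z", "pen_down")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples)[required]
  samples$pen_down <- as.logical(samples$pen_down)
  rec <- structure(list(stimulus_id = stimulus_id,
                        samples = samples,
                        sampling_rate = sampling_rate,
                        spatial_resolution = spatial_resolution,
                        meta = meta),
                   class = "grapho_recording")
  if (validate) {
    dt <- diff(samples$t)
    if (any(!is.finite(samples$t)) || any(samples$t < 0))
      stop("timestamps must be finite and non-negative", call. = FALSE)
    if (any(dt <= 0))
      stop("timestamps must be strictly increasing; first violation at index ",
           which(dt <= 0)[1] + 1L, call. = FALSE)
    if (!any(samples$pen_down))
      stop("empty drawing: recording has no pen-down sample", call. = FALSE)
  }
  rec
}

#' @export
print.grapho_recording <- function(x, ...) {
  cat(sprintf("<grapho_recording> %s: %d samples @ %g Hz, %.2f s\n",
              x$stimulus_id, nrow(x$samples), x$sampling_rate,
              diff(range(x$samples$t))))
  if (!is.null(x$meta))
    cat(sprintf("  subject %s, age %.0f days, %s/%s, group %s\n",
                x$meta$subject_id, x$meta$age_days, x$meta$gender,
                x$meta$laterality, x$meta$group))
  invisible(x)
}

#' Convert raw tablet counts to physical units
#'
#' Digitizing tablets report integer counts; positions in millimetres are
#' obtained by multiplying by the tablet's spatial resolution (0.25 mm per
#' count for the supported devices).
#'
#' @param raw_counts Integer (or numeric) coordinate series.
#' @param resolution Millimetres per count, > 0.
#' @return Numeric series in mm.
#' @export
to_physical_units <- function(raw_counts, resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  as.numeric(raw_counts) * resolution
}

#' Segment a recording into strokes and lifts
#'
#' A stroke is a maximal run of consecutive pen-down samples ("continuous
#' writing between two pen lifts"); a lift is a maximal pen-up run strictly
#' between two strokes. Leading or trailing pen-up runs are neither strokes
#' nor lifts. Indices are 1-based and inclusive.
#'
#' @param rec A [recording()].
#' @return List with elements `strokes` and `lifts`, each a list of runs;
#'   a run is a list with `start`, `end` (sample indices) and `samples`
#'   (the corresponding rows of `rec$samples`).
#' @export
segment_strokes <- function(rec) {
  pd <- rec$samples$pen_down
  if (!any(pd))
    stop("empty drawing: recording has no pen-down sample", call. = FALSE)
  r <- rle(pd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- function(i) list(start = starts[i], end = ends[i],
                          samples = rec$samples[starts[i]:ends[i], , drop = FALSE])
  stroke_idx <- which(r$values)
  first_stroke <- min(stroke_idx); last_stroke <- max(stroke_idx)
  lift_idx <- which(!r$values & seq_along(r$values) > first_stroke &
                      seq_along(r$values) < last_stroke)
  list(strokes = lapply(stroke_idx, run),
       lifts = lapply(lift_idx, run))
}

#' Validate a recording and report findings
#'
#' Non-throwing quality control mirroring the study-exclusion checks
#' (children who "did not perform the tasks as asked" are dropped, not
#' crashed on). Findings checked: missing stimulus id, sampling-interval
#' jitter above 10% of nominal, no pen-down samples ("empty drawing") and
#' out-of-range coordinates (negative, or beyond half a metre).
#'
#' @param rec A [recording()] (built with `validate = FALSE` if needed).
#' @return Character vector of findings; empty means acceptable.
#' @export
validate_recording <- function(rec) {
  findings <- character()
  if (is.null(rec$stimulus_id) || !rec$stimulus_id %in% GRAPHO_STIMULI)
    findings <- c(findings, "missing stimulus")
  s <- rec$samples
  if (!any(s$pen_down)) findings <- c(findings, "empty drawing")
  dt <- diff(s$t)
  nominal <- 1 / rec$sampling_rate
  if (length(dt) && max(abs(dt - nominal)) > 0.1 * nominal)
    findings <- c(findings, "sampling jitter")
  if (any(s$x < 0 | s$y < 0 | s$x > 500 | s$y > 500, na.rm = TRUE))
    findings <- c(findings, "out-of-range coordinates")
  findings
}

#' Resample a recording onto the nominal uniform grid
#'
#' Recordings whose timestamp jitter exceeds 10% of the nominal interval
#' are linearly resampled (positions interpolated, `pen_down` by nearest
#' neighbour) onto a uniform grid before feature extraction, since all
#' kinematic formulas assume uniform sampling. Gaps in in-air tracking are
#' treated as pen-up with linearly interpolated positions.
#'
#' @param rec A [recording()].
#' @param force Resample even when jitter is within tolerance.
#' @return A `grapho_recording` on a uniform grid.
#' @export
resample_recording <- function(rec, force = FALSE) {
  s <- rec$samples
  nominal <- 1 / rec$sampling_rate
  dt <- diff(s$t)
  if (!force && (length(dt) == 0 || max(abs(dt - nominal)) <= 0.1 * nominal))
    return(rec)
  grid <- seq(s$t[1], s$t[nrow(s)], by = nominal)
  interp <- function(v) stats::approx(s$t, v, xout = grid, rule = 2)$y
  pen <- stats::approx(s$t, as.numeric(s$pen_down), xout = grid,
                       method = "constant", rule = 2)$y
  recording(rec$stimulus_id,
            data.frame(t = grid, x = interp(s$x), y = interp(s$y),
                       z = interp(s$z), pen_down = pen >= 0.5),
            sampling_rate = rec$sampling_rate,
            spatial_resolution = rec$spatial_resolution,
            meta = rec$meta)
}
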