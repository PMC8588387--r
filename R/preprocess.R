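# Preprocessing: zero-phase Butterworth filtering and kinematic derivatives.
# All features downstream consume filtered coordinates.

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering, so the trajectory is smoothed
#' without the group delay a single pass would introduce; geometric
#' features would otherwise be distorted by lag. The default fourth-order
#' filter at 15 Hz removes tablet noise while keeping the handwriting band
#' (around 5 Hz) intact. The series is reflected at both ends before
#' filtering to suppress edge transients. DC gain is 1: a constant series
#' passes through unchanged.
#'
#' @param series Numeric 1-D signal.
#' @param rate Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff Cutoff frequency in Hz (default 15).
#' @param order Filter order (default 4). Effective attenuation is the
#'   squared single-pass response because of the two passes.
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(series, rate, cutoff = 15, order = 4) {
  n <- length(series)
  if (n < 3 * order)
    stop("series too short to filter: need at least ", 3 * order,
         " samples, got ", n, call. = FALSE)
  if (rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # long reflection padding: signal::filtfilt starts from zero state, so
  # the startup transient must decay inside the pad, not the data
  pad <- min(n - 1L, max(3L * order, ceiling(10 * rate / cutoff)))
  # reflect about the end points so the padded signal is continuous
  head_pad <- 2 * series[1] - series[seq(pad + 1L, 2L)]
  tail_pad <- 2 * series[n] - series[seq(n - 1L, n - pad)]
  # filter around the mean so DC passes through exactly
  mu <- mean(series)
  ext <- c(head_pad, series, tail_pad) - mu
  filt <- signal::filtfilt(bf, ext)
  filt[seq(pad + 1L, pad + n)] + mu
}

#' Low-pass filter the coordinates of a recording
#'
#' Applies [lowpass_filter()] to x and y per stroke (filtering across pen
#' lifts would smooth over artificial discontinuities where the pen jumped
#' in the air). Strokes shorter than `3 * order` samples are left as-is.
#'
#' @param rec A [recording()].
#' @param cutoff,order Passed to [lowpass_filter()].
#' @return The recording with filtered pen-down coordinates.
#' @export
filter_recording <- function(rec, cutoff = 15, order = 4) {
  seg <- segment_strokes(rec)
  s <- rec$samples
  for (st in seg$strokes) {
    idx <- st$start:st$end
    if (length(idx) >= 3 * order) {
      s$x[idx] <- lowpass_filter(s$x[idx], rec$sampling_rate, cutoff, order)
      s$y[idx] <- lowpass_filter(s$y[idx], rec$sampling_rate, cutoff, order)
    }
  }
  rec$samples <- s
  rec
}

# numerical derivative on a uniform grid: central differences inside,
# one-sided at the end points
num_deriv <- function(v, rate) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) * rate
  d[n] <- (v[n] - v[n - 1]) * rate
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate / 2
  d
}

#' Kinematic series for one stroke
#'
#' Velocity, speed, acceleration and jerk on the stroke's uniform time
#' grid, by central differences (one-sided at the end points).
#'
#' @param stroke_samples Data frame with `x`, `y` columns (a stroke's
#'   samples); at least 4 rows.
#' @param rate Sampling rate in Hz.
#' @return List of class `grapho_kinematics` with per-sample `vx`, `vy`,
#'   `speed` (mm/s), `ax`, `ay`, `accel` (mm/s^2), `jx`, `jy`, `jerk`
#'   (mm/s^3) and `n`.
#' @export
compute_kinematics <- function(stroke_samples, rate) {
  n <- nrow(stroke_samples)
  if (n < 4)
    stop("stroke too short for kinematics (need >= 4 samples)", call. = FALSE)
  vx <- num_deriv(stroke_samples$x, rate)
  vy <- num_deriv(stroke_samples$y, rate)
  ax <- num_deriv(vx, rate); ay <- num_deriv(vy, rate)
  jx <- num_deriv(ax, rate); jy <- num_deriv(ay, rate)
  structure(list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
                 ax = ax, ay = ay, accel = sqrt(ax^2 + ay^2),
                 jx = jx, jy = jy, jerk = sqrt(jx^2 + jy^2), n = n),
            class = "grapho_kinematics")
}

# prominence of a local maximum: height above the higher of the two valley
# floors separating it from taller terrain (or the series edge)
peak_prominence <- function(speed, peaks) {
  vapply(peaks, function(p) {
    left <- speed[seq_len(p)]
    higher_l <- which(left > speed[p])
    lmin <- min(left[seq(if (length(higher_l)) max(higher_l) else 1L, p)])
    right <- speed[p:length(speed)]
    higher_r <- which(right > speed[p])
    rmin <- min(right[seq(1L, if (length(higher_r)) min(higher_r) else
      length(right))])
    speed[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Velocity peaks of a speed series
#'
#' Local speed maxima with prominence at least `min_prominence_frac` of the
#' maximum speed, separated by at least `min_separation_s`. When two
#' candidates are closer than the separation, the higher one wins. The
#' prominence and separation rules exist to ignore sensor ripple at 200 Hz.
#'
#' @param speed Numeric speed series (mm/s).
#' @param rate Sampling rate in Hz.
#' @param min_prominence_frac Fraction of max speed (default 0.1).
#' @param min_separation_s Minimum peak separation in seconds (default 0.05).
#' @return List with `indices` and `values`.
#' @export
find_velocity_peaks <- function(speed, rate, min_prominence_frac = 0.1,
                                min_separation_s = 0.05) {
  n <- length(speed)
  if (n == 0) stop("empty speed series", call. = FALSE)
  if (n < 3 || max(speed) <= 0)
    return(list(indices = integer(), values = numeric()))
  i <- 2:(n - 1)
  cand <- i[speed[i] > speed[i - 1] & speed[i] >= speed[i + 1]]
  if (!length(cand)) return(list(indices = integer(), values = numeric()))
  prom <- peak_prominence(speed, cand)
  cand <- cand[prom >= min_prominence_frac * max(speed)]
  if (!length(cand)) return(list(indices = integer(), values = numeric()))
  min_sep <- min_separation_s * rate
  keep <- integer()
  for (p in cand[order(-speed[cand], cand)]) {
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  list(indices = keep, values = speed[keep])
}

# low-velocity flags for a stroke: TRUE where the net displacement over the
# centered `window_s` window (truncated at stroke edges) is below `thresh_mm`
low_velocity_flags <- function(stroke_samples, rate, window_s = 0.15,
                               thresh_mm = 1) {
  n <- nrow(stroke_samples)
  half <- max(1L, round(window_s * rate / 2))
  i <- seq_len(n)
  # keep the window full-length near the stroke ends (shifted, not
  # truncated), so slow-but-steady motion is not flagged at the edges
  lo <- pmax(1L, pmin(i - half, n - 2L * half))
  hi <- pmin(n, lo + 2L * half)
  dx <- stroke_samples$x[hi] - stroke_samples$x[lo]
  dy <- stroke_samples$y[hi] - stroke_samples$y[lo]
  sqrt(dx^2 + dy^2) < thresh_mm
}

#' Low-velocity segments of a stroke
#'
#' A sample is low-velocity when the pen's net displacement over a centered
#' 150 ms window is below 1 mm; segments are maximal runs of such samples.
#'
#' @param stroke_samples Data frame with `x`, `y` columns; at least 2 rows.
#' @param rate Sampling rate in Hz.
#' @param window_s Window length in seconds (default 0.15).
#' @param thresh_mm Displacement threshold in mm (default 1).
#' @return List with `segments` (data frame of `start`, `end` indices),
#'   `total_duration` (s) and `total_length` (mm, path length inside the
#'   segments).
#' @export
find_low_velocity_segments <- function(stroke_samples, rate, window_s = 0.15,
                                       thresh_mm = 1) {
  n <- nrow(stroke_samples)
  if (n < 2) stop("stroke too short (need >= 2 samples)", call. = FALSE)
  flags <- low_velocity_flags(stroke_samples, rate, window_s, thresh_mm)
  r <- rle(flags)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  seg <- data.frame(start = starts[sel], end = ends[sel])
  steps <- sqrt(diff(stroke_samples$x)^2 + diff(stroke_samples$y)^2)
  seg_len <- function(a, b) if (b > a) sum(steps[a:(b - 1)]) else 0
  list(segments = seg,
       total_duration = sum(seg$end - seg$start + 1L) / rate,
       total_length = if (nrow(seg)) sum(mapply(seg_len, seg$start, seg$end))
                      else 0)
}

#' Abnormal stops within a stroke
#'
#' An abnormal stop is a low-velocity segment (see
#' [find_low_velocity_segments()]) lasting at least 150 ms, excluding
#' segments touching the stroke's first or last 50 ms, which are ordinary
#' start/stop transients.
#'
#' @inheritParams find_low_velocity_segments
#' @param min_duration_s Minimum stop duration in seconds (default 0.15).
#' @param transient_s Start/end exclusion zone in seconds (default 0.05).
#' @return List with `count` and `total_duration` (s).
#' @export
find_abnormal_stops <- function(stroke_samples, rate, min_duration_s = 0.15,
                                transient_s = 0.05) {
  n <- nrow(stroke_samples)
  lv <- find_low_velocity_segments(stroke_samples, rate)
  seg <- lv$segments
  if (!nrow(seg)) return(list(count = 0L, total_duration = 0))
  guard <- transient_s * rate
  dur <- (seg$end - seg$start + 1L) / rate
  ok <- dur >= min_duration_s & seg$start > guard & seg$end <= n - guard
  list(count = sum(ok), total_duration = sum(dur[ok]))
}
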