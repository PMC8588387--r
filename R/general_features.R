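# General features, computed identically for every stimulus: timing,
# kinematic aggregates, step-distribution entropy and trajectory SNR.

#' Step-displacement probability distribution of a trajectory
#'
#' Each interior sample i (i = 2..N-1) receives a weight proportional to
#' its step displacement from the previous sample; weights are normalized
#' to sum to 1. Under strictly uniform movement all steps are equal, so
#' the distribution is uniform; pauses and bursts concentrate or dilute
#' probability mass. If the total displacement is zero the distribution is
#' defined as uniform (degenerate rule).
#'
#' @param xy Numeric vector (one axis) or two-column matrix/data frame
#'   (2-D trajectory); at least 3 samples.
#' @return Numeric weight vector of length N - 2 summing to 1.
#' @export
step_distribution <- function(xy) {
  m <- as.matrix(xy)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  steps <- sqrt(rowSums((m[2:(n - 1), , drop = FALSE] -
                           m[1:(n - 2), , drop = FALSE])^2))
  tot <- sum(steps)
  if (tot == 0) rep(1 / length(steps), length(steps)) else steps / tot
}

#' Order-2 Renyi entropy
#'
#' `RE2 = -log(sum(p^2))` in nats. Maximal (`log M`) for the uniform
#' distribution over M atoms; zero for a degenerate one. Applied to step
#' distributions it quantifies how unpredictable the pen's progress along
#' the trace is: chaotic, irregular handwriting concentrates displacement
#' into bursts and shifts the entropy.
#'
#' @param weights Probability vector (non-negative, summing to 1).
#' @return Entropy in nats.
#' @export
renyi_entropy_order2 <- function(weights) {
  if (!length(weights)) stop("undefined entropy: empty distribution",
                             call. = FALSE)
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be a probability distribution", call. = FALSE)
  -log(sum(weights^2))
}

#' Trajectory signal-to-noise ratio
#'
#' Compares a coordinate series to its smoothed version (order-2
#' Butterworth at 5 Hz, zero-phase): `SNR = 10 log10(P_smooth /
#' P_residual)` in dB. Quick, unexpected movements put power into the
#' residual and lower the SNR. When the residual power is below 1e-12 of
#' the signal power the value is capped at +120 dB.
#'
#' @param series Numeric 1-D trajectory signal, length >= 16.
#' @param rate Sampling rate in Hz.
#' @param cutoff Smoother cutoff in Hz (default 5).
#' @return SNR in dB.
#' @export
signal_to_noise_ratio <- function(series, rate, cutoff = 5) {
  if (length(series) < 16) stop("need at least 16 samples", call. = FALSE)
  if (all(series == 0)) stop("undefined SNR: all-zero series", call. = FALSE)
  smooth <- lowpass_filter(series, rate, cutoff = cutoff, order = 2)
  p_sig <- sum(smooth^2)
  p_res <- sum((series - smooth)^2)
  if (p_res < 1e-12 * p_sig || p_res == 0) return(120)
  max(-120, min(120, 10 * log10(p_sig / p_res)))
}

#' Average normalized jerk of a set of strokes
#'
#' Per stroke, the dimensionless smoothness index
#' `sqrt(0.5 * integral(jerk^2 dt) * T^5 / L^2)` with T the stroke
#' duration and L its path length; strokes are averaged weighted by
#' duration. The index is invariant to uniform time- and space-rescaling
#' of the movement, so slow-but-smooth and fast-but-smooth strokes score
#' alike, while tremulous ones score high.
#'
#' @param strokes List of stroke sample data frames (columns `x`, `y`),
#'   as produced by [segment_strokes()]. Strokes shorter than 4 samples
#'   are skipped.
#' @param rate Sampling rate in Hz.
#' @return Dimensionless jerk score (NA if no usable stroke).
#' @export
average_normalized_jerk <- function(strokes, rate) {
  vals <- numeric(); wts <- numeric()
  for (ss in strokes) {
    n <- nrow(ss)
    if (n < 4) next
    kin <- compute_kinematics(ss, rate)
    L <- sum(sqrt(diff(ss$x)^2 + diff(ss$y)^2))
    if (L <= 0) next
    duration <- (n - 1) / rate
    j2 <- kin$jerk^2
    integral <- sum((j2[-1] + j2[-n]) / 2) / rate
    vals <- c(vals, sqrt(0.5 * integral * duration^5 / L^2))
    wts <- c(wts, duration)
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

path_len <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Stroke and lift summary statistics
#'
#' Stimulus duration (last minus first timestamp), writing time (total
#' pen-down time), air/paper time ratio, stroke and lift counts, and
#' mean/median/max durations of strokes and lifts.
#'
#' @param rec A [recording()].
#' @return Named list of scalars.
#' @export
stroke_and_lift_stats <- function(rec) {
  seg <- segment_strokes(rec)
  rate <- rec$sampling_rate
  dur_of <- function(runs) vapply(runs, function(r) (r$end - r$start + 1L) /
                                    rate, numeric(1))
  sd_dur <- dur_of(seg$strokes)
  lf_dur <- if (length(seg$lifts)) dur_of(seg$lifts) else numeric()
  duration <- diff(range(rec$samples$t))
  writing_time <- sum(sd_dur)
  list(duration = duration,
       writing_time = writing_time,
       air_paper_ratio = max(0, duration - writing_time) / writing_time,
       n_strokes = length(seg$strokes),
       n_lifts = length(seg$lifts),
       stroke_duration_mean = mean(sd_dur),
       stroke_duration_median = stats::median(sd_dur),
       stroke_duration_max = max(sd_dur),
       lift_duration_mean = if (length(lf_dur)) mean(lf_dur) else 0,
       lift_duration_median = if (length(lf_dur)) stats::median(lf_dur) else 0,
       lift_duration_max = if (length(lf_dur)) max(lf_dur) else 0)
}

# standardize (centroid at origin) and normalize (isotropic scale to unit
# bounding box) one stroke, then return its RE2 along the requested axes
stroke_re2 <- function(ss, axes) {
  if (nrow(ss) < 4) return(NA_real_)
  x <- ss$x - mean(ss$x); y <- ss$y - mean(ss$y)
  scale <- max(diff(range(x)), diff(range(y)))
  if (scale > 0) { x <- x / scale; y <- y / scale }
  m <- switch(axes, x = cbind(x), y = cbind(y), xy = cbind(x, y))
  renyi_entropy_order2(step_distribution(m))
}

#' Compute the 47 general features of a recording
#'
#' Produces the full per-stimulus general feature block of the canonical
#' registry, in registry order. Constituent failures (e.g. strokes too
#' short for a statistic) yield `NA`, which the table-level pipeline later
#' imputes. Input should already be low-pass filtered
#' (see [filter_recording()]).
#'
#' @param rec A [recording()].
#' @return Named numeric vector of length 47.
#' @export
compute_general_features <- function(rec) {
  rate <- rec$sampling_rate
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  out <- stats::setNames(rep(NA_real_, length(general_feature_names())),
                         general_feature_names())
  st <- stroke_and_lift_stats(rec)
  for (nm in setdiff(names(st), "n_lifts")) out[nm] <- st[[nm]]
  out["n_lifts"] <- st$n_lifts

  # kinematic aggregates over usable strokes (>= 4 samples)
  speeds <- numeric(); peak_vals <- numeric(); n_peaks <- 0L
  lv_count <- 0L; lv_dur <- 0; lv_len <- 0; stop_count <- 0L; stop_dur <- 0
  for (ss in strokes) {
    if (nrow(ss) < 4) next
    kin <- compute_kinematics(ss, rate)
    speeds <- c(speeds, kin$speed)
    pk <- find_velocity_peaks(kin$speed, rate)
    n_peaks <- n_peaks + length(pk$indices)
    peak_vals <- c(peak_vals, pk$values)
    lv <- find_low_velocity_segments(ss, rate)
    lv_count <- lv_count + nrow(lv$segments)
    lv_dur <- lv_dur + lv$total_duration
    lv_len <- lv_len + lv$total_length
    ab <- find_abnormal_stops(ss, rate)
    stop_count <- stop_count + ab$count
    stop_dur <- stop_dur + ab$total_duration
  }
  slen <- vapply(strokes, function(ss) path_len(ss$x, ss$y), numeric(1))
  total_len <- sum(slen)
  out["low_velocity_count"] <- lv_count
  out["low_velocity_duration"] <- lv_dur
  out["low_velocity_length"] <- lv_len
  if (length(speeds)) {
    out["velocity_mean"] <- mean(speeds)
    out["velocity_median"] <- stats::median(speeds)
    out["velocity_max"] <- max(speeds)
    out["velocity_std"] <- stats::sd(speeds)
  }
  out["average_normalized_jerk"] <- average_normalized_jerk(strokes, rate)
  out["abnormal_stop_count"] <- stop_count
  out["abnormal_stop_duration"] <- stop_dur
  out["velocity_peak_count"] <- n_peaks
  out["velocity_peak_std"] <- if (length(peak_vals) >= 2)
    stats::sd(peak_vals) else 0
  # velocity peaks per cm of pen-down path
  out["snvpd"] <- if (total_len > 0) n_peaks / (total_len / 10) else NA_real_

  pd <- rec$samples[rec$samples$pen_down, , drop = FALSE]
  out["snr_x"] <- tryCatch(signal_to_noise_ratio(pd$x, rate),
                           error = function(e) NA_real_)
  out["snr_y"] <- tryCatch(signal_to_noise_ratio(pd$y, rate),
                           error = function(e) NA_real_)

  if (nrow(pd) >= 3) {
    out["re2_x"] <- renyi_entropy_order2(step_distribution(pd$x))
    out["re2_y"] <- renyi_entropy_order2(step_distribution(pd$y))
    out["re2_xy"] <- renyi_entropy_order2(step_distribution(pd[c("x", "y")]))
  }
  for (ax in c("x", "y", "xy")) {
    vals <- vapply(strokes, stroke_re2, numeric(1), axes = ax)
    vals <- vals[is.finite(vals)]
    out[paste0("re2_stroke_mean_", ax)] <- if (length(vals)) mean(vals)
      else NA_real_
    out[paste0("re2_stroke_std_", ax)] <- if (length(vals) >= 2)
      stats::sd(vals) else 0
  }

  out["path_length"] <- total_len
  out["path_length_x"] <- sum(vapply(strokes,
                                     function(ss) sum(abs(diff(ss$x))),
                                     numeric(1)))
  out["path_length_y"] <- sum(vapply(strokes,
                                     function(ss) sum(abs(diff(ss$y))),
                                     numeric(1)))
  out["extent_x"] <- diff(range(pd$x))
  out["extent_y"] <- diff(range(pd$y))
  out["stroke_length_mean"] <- mean(slen)
  out["stroke_length_median"] <- stats::median(slen)
  out["stroke_length_max"] <- max(slen)

  # in-air counterparts over lifts
  lifts <- lapply(seg$lifts, `[[`, "samples")
  if (length(lifts)) {
    air_len <- vapply(lifts, function(ls) path_len(ls$x, ls$y), numeric(1))
    out["air_path_length"] <- sum(air_len)
    air_speed <- unlist(lapply(lifts, function(ls) {
      if (nrow(ls) < 2) return(numeric())
      sqrt(diff(ls$x)^2 + diff(ls$y)^2) * rate
    }))
    out["air_velocity_mean"] <- if (length(air_speed)) mean(air_speed) else 0
    out["air_velocity_max"] <- if (length(air_speed)) max(air_speed) else 0
  } else {
    out["air_path_length"] <- 0
    out["air_velocity_mean"] <- 0
    out["air_velocity_max"] <- 0
  }
  # mean gap between a stroke's end point and the next stroke's start
  out["lift_gap_mean"] <- end_start_gap_mean(strokes)
  out
}

# mean Euclidean distance between the end of one stroke and the start of
# the next; 0 when there is a single stroke
end_start_gap_mean <- function(strokes) {
  if (length(strokes) < 2) return(0)
  gaps <- vapply(seq_len(length(strokes) - 1), function(i) {
    a <- strokes[[i]]; b <- strokes[[i + 1]]
    sqrt((b$x[1] - a$x[nrow(a)])^2 + (b$y[1] - a$y[nrow(a)])^2)
  }, numeric(1))
  mean(gaps)
}
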