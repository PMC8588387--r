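# Stimulus-specific features: template mean-squared errors, slopes, turn
# quality, completion at first lift, shape geometry and loop statistics.

pen_down_xy <- function(rec) {
  pd <- rec$samples[rec$samples$pen_down, , drop = FALSE]
  pd
}

#' Mean squared vertical error of samples against a horizontal model line
#'
#' `MSE = mean((y_i - y_L)^2)` over the samples assigned to the line, in
#' mm^2.
#'
#' @param y Drawn sample heights (mm).
#' @param y_line Model line height (mm).
#' @return MSE in mm^2 (`NA` when no sample is assigned).
#' @export
line_mse <- function(y, y_line) {
  if (!length(y)) return(NA_real_)
  mean((y - y_line)^2)
}

#' Assign samples to the nearest of several horizontal lines
#'
#' Nearest by vertical distance; ties go to the lower-indexed line.
#'
#' @param y Sample heights (mm).
#' @param line_y Model line heights, in line order (index 1 = first line).
#' @return Integer vector of line indices.
#' @export
assign_to_lines <- function(y, line_y) {
  d <- abs(outer(y, line_y, "-"))
  max.col(-d, ties.method = "first")
}

#' Turn quality
#'
#' `Quality = 1 - <v_b, v_a>` for the unit travel directions just before
#' and just after a corner. 1 means a crisp 90 degree turn; 0 a turn that
#' was not made (straight through); 2 a full reversal. Non-unit inputs are
#' normalized with a warning.
#'
#' @param v_b,v_a Direction vectors (length 2) before and after the turn.
#' @return Quality in `[0, 2]`.
#' @export
angle_quality <- function(v_b, v_a) {
  nb <- sqrt(sum(v_b^2)); na_ <- sqrt(sum(v_a^2))
  if (nb == 0 || na_ == 0) stop("zero-length direction vector", call. = FALSE)
  if (abs(nb - 1) > 1e-9 || abs(na_ - 1) > 1e-9) {
    warning("direction vectors normalized internally")
    v_b <- v_b / nb; v_a <- v_a / na_
  }
  1 - sum(v_b * v_a)
}

#' Count general-direction changes of a drawn path
#'
#' The instantaneous heading is quantized into the 4 main directions
#' (right, up, left, down; boundaries at 45 + k*90 degrees). To ignore
#' jitter, the current direction is kept until the heading moves more
#' than `hysteresis_deg` past a boundary and the new direction persists
#' for `min_run_s`. The count is the number of committed label
#' transitions: exactly 4 for one traversal of an ideal oval, more when
#' tremor or corrections zigzag the path.
#'
#' @param x,y Pen-down path coordinates (mm), at least 10 samples.
#' @param rate Sampling rate in Hz.
#' @param hysteresis_deg Hysteresis beyond the quadrant boundary (default 15).
#' @param min_run_s Minimum persistence of a new direction (default 0.05 s).
#' @return Integer count.
#' @export
count_direction_changes <- function(x, y, rate, hysteresis_deg = 15,
                                    min_run_s = 0.05) {
  if (length(x) < 10) stop("need at least 10 samples", call. = FALSE)
  dx <- diff(x); dy <- diff(y)
  moving <- sqrt(dx^2 + dy^2) > 1e-9
  ang <- atan2(dy[moving], dx[moving]) * 180 / pi    # (-180, 180]
  if (!length(ang)) return(0L)
  label_of <- function(a) (((a + 45) %% 360) %/% 90)  # 0=R, 1=U, 2=L, 3=D
  centers <- c(0, 90, 180, 270)
  circ_dist <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  min_run <- max(1L, round(min_run_s * rate))
  cur <- label_of(ang[1])
  count <- 0L; pending <- NA_integer_; pend_len <- 0L
  for (a in ang[-1]) {
    if (circ_dist(a, centers[cur + 1]) <= 45 + hysteresis_deg) {
      pending <- NA_integer_; pend_len <- 0L
      next
    }
    raw <- label_of(a)
    if (!is.na(pending) && raw == pending) pend_len <- pend_len + 1L
    else { pending <- raw; pend_len <- 1L }
    if (pend_len >= min_run) {
      count <- count + 1L
      cur <- pending
      pending <- NA_integer_; pend_len <- 0L
    }
  }
  count
}

# majority-vote stroke-to-class assignment from per-sample assignments;
# ties to the lower index
majority_assign <- function(assignments) {
  tab <- tabulate(assignments)
  which.max(tab)
}

# fraction (0..100) of a line's x extent covered by the first stroke that
# touches it
coverage_first_stroke <- function(stroke, x_start, x_end) {
  covered <- diff(range(stroke$x))
  min(100, 100 * covered / (x_end - x_start))
}

#' Circuit 1 (parallel lines) specific features
#'
#' Per line: vertical-error MSE, stroke count, drawing duration,
#' backtracking count (a stroke starting left of where the previous
#' stroke on that line ended) and the percentage of the line covered
#' before the first pen lift (the x-extent of the first stroke on the
#' line). Plus the standard deviation of the three regression slopes
#' (parallelism) and the mean gap between consecutive stroke end/start
#' points.
#'
#' @param rec A circuit1 [recording()].
#' @param tpl Template from [make_template()] (defaults to the packaged
#'   geometry).
#' @return Named numeric vector of length 17.
#' @export
circuit1_features <- function(rec, tpl = make_template("circuit1")) {
  stopifnot(rec$stimulus_id == "circuit1")
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  rate <- rec$sampling_rate
  pd <- pen_down_xy(rec)
  line_y <- tpl$line_y
  samp_line <- assign_to_lines(pd$y, line_y)
  stroke_line <- vapply(strokes, function(ss)
    majority_assign(assign_to_lines(ss$y, line_y)), integer(1))
  out <- stats::setNames(rep(NA_real_, 17), specific_feature_names("circuit1"))
  slopes <- rep(NA_real_, 3)
  for (L in 1:3) {
    ys <- pd$y[samp_line == L]
    out[sprintf("line%d_mse", L)] <- line_mse(ys, line_y[L])
    on_line <- which(stroke_line == L)
    out[sprintf("line%d_n_strokes", L)] <- length(on_line)
    if (length(on_line)) {
      durs <- vapply(on_line, function(i) nrow(strokes[[i]]) / rate,
                     numeric(1))
      out[sprintf("line%d_duration", L)] <- sum(durs)
      backs <- 0L
      if (length(on_line) > 1) {
        for (k in 2:length(on_line)) {
          prev <- strokes[[on_line[k - 1]]]; cur <- strokes[[on_line[k]]]
          if (cur$x[1] < prev$x[nrow(prev)]) backs <- backs + 1L
        }
      }
      out[sprintf("line%d_backtracks", L)] <- backs
      out[sprintf("line%d_completion_first_lift", L)] <-
        coverage_first_stroke(strokes[[on_line[1]]], tpl$x_start, tpl$x_end)
      xs <- pd$x[samp_line == L]
      if (length(ys) >= 2 && stats::sd(xs) > 0)
        slopes[L] <- stats::coef(stats::lm(ys ~ xs))[2]
    }
  }
  out["slope_std"] <- if (all(is.finite(slopes))) stats::sd(slopes) else
    NA_real_
  out["end_start_gap_mean"] <- end_start_gap_mean(strokes)
  out
}

# assign points to the nearest template part (segment); ties to the lower
# part index; returns index vector and perpendicular distances
assign_to_parts <- function(p, comps) {
  p <- as.matrix(p)
  nd <- matrix(Inf, nrow(p), length(comps))
  for (i in seq_along(comps)) {
    pts <- comps[[i]]$points
    nd[, i] <- dist_to_segment(p, pts[1, ], pts[2, ])$dist
  }
  idx <- max.col(-nd, ties.method = "first")
  list(part = idx, dist = nd[cbind(seq_len(nrow(p)), idx)])
}

# local-frame slope of samples on a template segment: regress the
# perpendicular offset on the along-segment coordinate (0 for a perfect,
# parallel trace regardless of the segment's orientation)
local_frame_slope <- function(p, a, b) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  v <- c(-u[2], u[1])
  rel <- sweep(as.matrix(p), 2, a)
  along <- rel %*% u; offset <- rel %*% v
  if (length(along) < 2 || stats::sd(along) == 0) return(NA_real_)
  stats::coef(stats::lm(offset ~ along))[[2]]
}

# travel direction over a 5 mm window of path before (side = -1) or after
# (side = +1) index i0, skipping the first `skip` mm nearest the anchor
path_direction <- function(xy, i0, side, span = 5, skip = 2) {
  n <- nrow(xy)
  idx <- i0; acc <- 0
  sel <- integer()
  while (TRUE) {
    nxt <- idx + side
    if (nxt < 1 || nxt > n) break
    acc <- acc + sqrt(sum((xy[nxt, ] - xy[idx, ])^2))
    idx <- nxt
    if (acc >= skip) sel <- c(sel, idx)
    if (acc >= skip + span) break
  }
  if (length(sel) < 3) return(NULL)
  pts <- xy[if (side < 0) rev(sel) else sel, , drop = FALSE]
  tls_direction(pts)
}

#' Circuit 2 (labyrinth) specific features
#'
#' Perpendicular-residual MSE separately over the 5 long and the 4 short
#' parts, the standard deviation of the local-frame regression slopes of
#' each group of parts, the percentage of the circuit completed at the
#' first pen lift (arc-length progress along the template path), the
#' number of pen lifts that do not coincide with a turn (flanking stroke
#' directions within 30 degrees), the mean and standard deviation of the
#' per-corner turn [angle_quality()], and the mean end-to-start stroke
#' gap. Corners with fewer than 5 usable samples on either side are
#' skipped in the quality aggregates.
#'
#' @param rec A circuit2 [recording()].
#' @param tpl Template from [make_template()].
#' @return Named numeric vector of length 9.
#' @export
circuit2_features <- function(rec, tpl = make_template("circuit2")) {
  stopifnot(rec$stimulus_id == "circuit2")
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  pd <- pen_down_xy(rec)
  p <- as.matrix(pd[c("x", "y")])
  comps <- tpl$components
  asn <- assign_to_parts(p, comps)
  roles <- vapply(comps, `[[`, "", "role")
  out <- stats::setNames(rep(NA_real_, 9), specific_feature_names("circuit2"))
  for (role in c("long", "short")) {
    sel <- asn$part %in% which(roles == role)
    out[paste0("mse_", role)] <- if (any(sel)) mean(asn$dist[sel]^2) else
      NA_real_
    slopes <- vapply(which(roles == role), function(i) {
      pi_ <- p[asn$part == i, , drop = FALSE]
      if (nrow(pi_) < 2) return(NA_real_)
      local_frame_slope(pi_, comps[[i]]$points[1, ], comps[[i]]$points[2, ])
    }, numeric(1))
    out[paste0("slope_std_", role)] <- if (all(is.finite(slopes)))
      stats::sd(slopes) else NA_real_
  }
  # completion at first lift: arc progress of the first stroke's samples
  path <- tpl$path
  first <- strokes[[1]]
  proj <- project_to_polyline(as.matrix(first[c("x", "y")]), path)
  out["completion_first_lift"] <- if (length(strokes) == 1) 100 else
    min(100, 100 * max(proj$arc) / proj$total)
  # lifts not at a turn: flanking stroke directions differ by < 30 degrees
  off_turn <- 0L
  if (length(strokes) > 1) {
    for (k in seq_len(length(strokes) - 1)) {
      a <- as.matrix(strokes[[k]][c("x", "y")])
      b <- as.matrix(strokes[[k + 1]][c("x", "y")])
      va <- path_direction(a, nrow(a), side = -1, skip = 0)
      vb <- path_direction(b, 1, side = +1, skip = 0)
      if (is.null(va) || is.null(vb)) next
      angle <- acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
      if (angle < 30) off_turn <- off_turn + 1L
    }
  }
  out["lifts_off_turn"] <- off_turn
  # per-corner quality: anchor to the nearest sample within the capture
  # radius, directions from 5 mm of path before/after
  qualities <- numeric()
  for (ci in seq_len(nrow(tpl$corners))) {
    corner <- tpl$corners[ci, ]
    d <- sqrt((p[, 1] - corner[1])^2 + (p[, 2] - corner[2])^2)
    if (min(d) > 10) next
    i0 <- which.min(d)
    vb <- path_direction(p, i0, side = -1)
    va <- path_direction(p, i0, side = +1)
    if (is.null(vb) || is.null(va)) next
    qualities <- c(qualities, angle_quality(vb, va))
  }
  out["quality_mean"] <- if (length(qualities)) mean(qualities) else NA_real_
  out["quality_std"] <- if (length(qualities) >= 2) stats::sd(qualities)
    else 0
  out["end_start_gap_mean"] <- end_start_gap_mean(strokes)
  out
}

# eccentricity-corrected distance to the oval centre: the y axis is
# rescaled by a/b so the ellipse maps to a circle of radius a
oval_radial_distance <- function(x, y, oval) {
  sqrt((x - oval$cx)^2 + ((y - oval$cy) * (oval$a / oval$b))^2)
}

#' Circuit 3 (oval) specific features
#'
#' Radial-residual MSE to the perfect oval (perpendicular in the
#' circle-rescaled frame), the 4-direction change count, completion at
#' first lift, the oval-adapted Renyi entropy (Gaussian weights
#' `exp(-(d_i - r)^2 / 200)` on the radial residuals, renormalized, then
#' order-2 entropy) and the mean end-to-start stroke gap.
#'
#' @param rec A circuit3 [recording()].
#' @param tpl Template from [make_template()].
#' @return Named numeric vector of length 5.
#' @export
circuit3_features <- function(rec, tpl = make_template("circuit3")) {
  stopifnot(rec$stimulus_id == "circuit3")
  oval <- tpl$oval
  if (is.null(oval) || oval$a <= 0 || oval$b <= 0)
    stop("degenerate oval template", call. = FALSE)
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  pd <- pen_down_xy(rec)
  out <- stats::setNames(rep(NA_real_, 5), specific_feature_names("circuit3"))
  d <- oval_radial_distance(pd$x, pd$y, oval)
  res <- d - oval$a
  out["mse_oval"] <- mean(res^2)
  out["direction_changes"] <- count_direction_changes(pd$x, pd$y,
                                                      rec$sampling_rate)
  pts <- tpl$components$oval$points
  first <- strokes[[1]]
  proj <- project_to_polyline(as.matrix(first[c("x", "y")]), pts)
  out["completion_first_lift"] <- if (length(strokes) == 1) 100 else
    min(100, 100 * max(proj$arc) / proj$total)
  w <- exp(-res^2 / 200) / sqrt(200 * pi)
  out["oval_re2"] <- renyi_entropy_order2(w / sum(w))
  out["end_start_gap_mean"] <- end_start_gap_mean(strokes)
  out
}

# assign each stroke to the nearest template shape by centroid distance
assign_strokes_to_shapes <- function(strokes, centroids) {
  vapply(strokes, function(ss) {
    cx <- mean(ss$x); cy <- mean(ss$y)
    which.min((centroids[, 1] - cx)^2 + (centroids[, 2] - cy)^2)
  }, integer(1))
}

#' Shapes 1 (simple shapes) specific features
#'
#' Per shape (vertical line, horizontal line, sloping line, circle):
#' drawing duration and drawn path length. Plus the index of curvature
#' (drawn path length of the three line shapes divided by the summed
#' template chord lengths; 1 for perfectly straight lines), the
#' horizontal and vertical diameters of the drawn circle (x and y
#' extents) and their ratio (1 for a perfect circle).
#'
#' @param rec A shapes1 [recording()].
#' @param tpl Template from [make_template()].
#' @return Named numeric vector of length 12.
#' @export
shapes1_features <- function(rec, tpl = make_template("shapes1")) {
  stopifnot(rec$stimulus_id == "shapes1")
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  rate <- rec$sampling_rate
  centroids <- template_shape_centroids(tpl)
  asn <- assign_strokes_to_shapes(strokes, centroids)
  shapes <- tpl$shapes
  out <- stats::setNames(rep(NA_real_, 12), specific_feature_names("shapes1"))
  for (si in seq_along(shapes)) {
    sel <- which(asn == si)
    if (!length(sel)) next
    out[paste0(shapes[si], "_duration")] <-
      sum(vapply(sel, function(i) nrow(strokes[[i]]) / rate, numeric(1)))
    out[paste0(shapes[si], "_path_length")] <-
      sum(vapply(sel, function(i) path_len(strokes[[i]]$x, strokes[[i]]$y),
                 numeric(1)))
  }
  line_shapes <- c("vline", "hline", "sline")
  chord <- sum(vapply(line_shapes, function(s) {
    pts <- tpl$components[[s]]$points
    sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  }, numeric(1)))
  drawn <- sum(out[paste0(line_shapes, "_path_length")], na.rm = TRUE)
  out["curvature_index"] <- if (drawn > 0) drawn / chord else NA_real_
  circle_sel <- which(asn == which(shapes == "circle"))
  if (length(circle_sel)) {
    cs <- do.call(rbind, lapply(strokes[circle_sel],
                                function(ss) ss[c("x", "y")]))
    out["circle_diameter_h"] <- diff(range(cs$x))
    out["circle_diameter_v"] <- diff(range(cs$y))
    out["circle_diameter_ratio"] <-
      out["circle_diameter_h"] / out["circle_diameter_v"]
  }
  out
}

#' Shapes 2 (complex shapes) specific features
#'
#' Per shape (triangle, plus, square, cross): duration and drawn path
#' length. The crow-flies perimeter of the triangle and of the square is
#' the perimeter of the polygon formed by the detected corners (turning-
#' angle extrema of the drawn path). The plus and cross each yield the
#' ratio of the lengths of their two constituent lines (longer/shorter,
#' from the two longest assigned strokes).
#'
#' @param rec A shapes2 [recording()].
#' @param tpl Template from [make_template()].
#' @return Named numeric vector of length 12.
#' @export
shapes2_features <- function(rec, tpl = make_template("shapes2")) {
  stopifnot(rec$stimulus_id == "shapes2")
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  rate <- rec$sampling_rate
  centroids <- template_shape_centroids(tpl)
  asn <- assign_strokes_to_shapes(strokes, centroids)
  shapes <- tpl$shapes
  out <- stats::setNames(rep(NA_real_, 12), specific_feature_names("shapes2"))
  lens <- lapply(seq_along(shapes), function(si) {
    vapply(which(asn == si),
           function(i) path_len(strokes[[i]]$x, strokes[[i]]$y), numeric(1))
  })
  for (si in seq_along(shapes)) {
    sel <- which(asn == si)
    if (!length(sel)) next
    out[paste0(shapes[si], "_duration")] <-
      sum(vapply(sel, function(i) nrow(strokes[[i]]) / rate, numeric(1)))
    out[paste0(shapes[si], "_path_length")] <- sum(lens[[si]])
  }
  for (poly in c("triangle", "square")) {
    si <- which(shapes == poly)
    sel <- which(asn == si)
    if (!length(sel)) next
    pts <- do.call(rbind, lapply(strokes[sel],
                                 function(ss) as.matrix(ss[c("x", "y")])))
    nc <- tpl$components[[poly]]$n_corners
    corners <- detect_corners(pts, nc)
    if (is.null(corners)) next
    closedp <- rbind(corners, corners[1, ])
    out[paste0(poly, "_corner_perimeter")] <- polyline_length(closedp)
  }
  for (barshape in c("plus", "cross")) {
    si <- which(shapes == barshape)
    ls <- sort(lens[[si]], decreasing = TRUE)
    if (length(ls) >= 2 && ls[2] > 0)
      out[paste0(barshape, "_segment_ratio")] <- ls[1] / ls[2]
  }
  out
}
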