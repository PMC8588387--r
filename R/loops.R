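# Closed-loop detection by self-intersection of the pen-down path, and
# the Loops-stimulus feature set built on it.

# all proper self-intersections of a polyline (matrix n x 2): pairs of
# non-adjacent segment indices i < j with the crossing point. Vectorized
# bounding-box prefilter per segment i.
polyline_self_intersections <- function(pts) {
  n <- nrow(pts) - 1L           # segments
  if (n < 3) return(NULL)
  x1 <- pts[1:n, 1]; y1 <- pts[1:n, 2]
  x2 <- pts[2:(n + 1), 1]; y2 <- pts[2:(n + 1), 2]
  lox <- pmin(x1, x2); hix <- pmax(x1, x2)
  loy <- pmin(y1, y2); hiy <- pmax(y1, y2)
  res <- list()
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    cand <- j[hix[j] >= lox[i] & lox[j] <= hix[i] &
                hiy[j] >= loy[i] & loy[j] <= hiy[i]]
    for (jj in cand) {
      p <- segment_intersection(c(x1[i], y1[i]), c(x2[i], y2[i]),
                                c(x1[jj], y1[jj]), c(x2[jj], y2[jj]))
      if (!is.null(p))
        res[[length(res) + 1L]] <- c(i = i, j = jj, x = p[1], y = p[2])
    }
  }
  if (!length(res)) return(NULL)
  as.data.frame(do.call(rbind, res))
}

#' Detect closed loops in a loops-task recording
#'
#' Closed loops are found as self-intersections of the pen-down path
#' within each stroke (a loop is the path between the two crossings of
#' the same point). When crossings nest or overlap, the tightest loops
#' win (smallest enclosed span first, non-overlapping). For each loop the
#' closed portion is measured: width and height of its bounding box, arc
#' length, and orientation `up`/`down` from the apex position relative to
#' the intersection point.
#'
#' @param rec A [recording()] (any stimulus; normally `loops`).
#' @param min_samples Minimum samples a loop must span (default 5).
#' @param min_size_mm Minimum bounding-box size of a loop (default 1 mm),
#'   rejecting crossing artifacts of pen tremor.
#' @return Data frame of class `grapho_loopset` with one row per loop:
#'   `stroke`, `start`, `end` (sample indices within the stroke),
#'   `orientation`, `width`, `height`, `length`, `apex_y`,
#'   `x_int`, `y_int`; plus attribute `link_samples` (pen-down samples
#'   outside any closed loop, as a data frame).
#' @export
detect_loops <- function(rec, min_samples = 5, min_size_mm = 1) {
  seg <- segment_strokes(rec)
  loops <- list()
  link_rows <- list()
  for (k in seq_along(seg$strokes)) {
    ss <- seg$strokes[[k]]$samples
    pts <- as.matrix(ss[c("x", "y")])
    inter <- polyline_self_intersections(pts)
    in_loop <- rep(FALSE, nrow(ss))
    if (!is.null(inter)) {
      inter$span <- inter$j - inter$i
      inter <- inter[order(inter$span), ]
      taken <- rep(FALSE, nrow(pts))
      for (r in seq_len(nrow(inter))) {
        i <- inter$i[r]; j <- inter$j[r]
        if (j - i + 1L < min_samples) next
        idx <- (i + 1L):j            # samples strictly inside the loop
        if (any(taken[idx])) next
        sub <- pts[idx, , drop = FALSE]
        w <- diff(range(sub[, 1])); h <- diff(range(sub[, 2]))
        if (max(w, h) < min_size_mm) next
        taken[idx] <- TRUE
        in_loop[idx] <- TRUE
        y_int <- inter$y[r]
        apex_y <- sub[which.max(abs(sub[, 2] - y_int)), 2]
        loops[[length(loops) + 1L]] <- data.frame(
          stroke = k, start = i + 1L, end = j,
          orientation = if (apex_y >= y_int) "up" else "down",
          width = w, height = h,
          length = polyline_length(sub),
          apex_y = apex_y, x_int = inter$x[r], y_int = y_int)
      }
    }
    link_rows[[k]] <- ss[!in_loop, , drop = FALSE]
  }
  out <- if (length(loops)) do.call(rbind, loops) else
    data.frame(stroke = integer(), start = integer(), end = integer(),
               orientation = character(), width = numeric(),
               height = numeric(), length = numeric(), apex_y = numeric(),
               x_int = numeric(), y_int = numeric())
  attr(out, "link_samples") <- do.call(rbind, link_rows)
  class(out) <- c("grapho_loopset", class(out))
  out
}

#' The Loops specific features
#'
#' Counts of upward, downward and total closed loops, the 4-direction
#' change count (summed over strokes), the standard deviations of loop
#' widths and heights (shape consistency), the fraction of the pen-down
#' trajectory spent inside closed loops, and the link-only height (y
#' extent of pen-down samples outside any closed loop).
#'
#' @param rec A loops [recording()].
#' @param tpl Template (unused by the measurements; kept for a uniform
#'   interface).
#' @return Named numeric vector of length 8.
#' @export
loops_features <- function(rec, tpl = make_template("loops")) {
  stopifnot(rec$stimulus_id == "loops")
  ls <- detect_loops(rec)
  seg <- segment_strokes(rec)
  strokes <- lapply(seg$strokes, `[[`, "samples")
  out <- stats::setNames(rep(NA_real_, 8), specific_feature_names("loops"))
  out["n_loops_up"] <- sum(ls$orientation == "up")
  out["n_loops_down"] <- sum(ls$orientation == "down")
  out["n_loops_total"] <- nrow(ls)
  out["direction_changes"] <- sum(vapply(strokes, function(ss) {
    if (nrow(ss) < 10) return(0L)
    count_direction_changes(ss$x, ss$y, rec$sampling_rate)
  }, integer(1)))
  if (nrow(ls) >= 2) {
    out["loop_width_std"] <- stats::sd(ls$width)
    out["loop_height_std"] <- stats::sd(ls$height)
  } else if (nrow(ls) == 1) {
    out["loop_width_std"] <- 0
    out["loop_height_std"] <- 0
  }
  total_len <- sum(vapply(strokes, function(ss) path_len(ss$x, ss$y),
                          numeric(1)))
  if (nrow(ls) && total_len > 0)
    out["loop_length_ratio"] <- sum(ls$length) / total_len
  else if (total_len > 0) out["loop_length_ratio"] <- 0
  links <- attr(ls, "link_samples")
  if (!is.null(links) && nrow(links))
    out["link_height"] <- diff(range(links$y))
  out
}
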