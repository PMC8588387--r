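# Plane-geometry helpers shared by the template features.

# resample a polyline to (approximately) uniform spacing by arc length
resample_polyline <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 0)          # drop duplicate vertices
  pts <- pts[keep, , drop = FALSE]
  seg <- seg[seg > 0]
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(pts[1, , drop = FALSE])
  s <- seq(0, total, by = spacing)
  if (s[length(s)] < total) s <- c(s, total)
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# perpendicular distance from points (n x 2) to a segment a-b, plus the
# clamped arc position of the projection along the segment
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) rep(0, nrow(p)) else
    pmin(1, pmax(0, ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2))
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
  list(dist = sqrt((p[, 1] - px)^2 + (p[, 2] - py)^2), t = t)
}

# arc-length position along a polyline of each point's nearest projection
project_to_polyline <- function(p, pts) {
  p <- as.matrix(p)
  nseg <- nrow(pts) - 1L
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  best_d <- rep(Inf, nrow(p)); best_s <- rep(0, nrow(p))
  for (i in seq_len(nseg)) {
    d <- dist_to_segment(p, pts[i, ], pts[i + 1, ])
    upd <- d$dist < best_d
    seg_len <- cum[i + 1] - cum[i]
    best_s[upd] <- cum[i] + d$t[upd] * seg_len
    best_d[upd] <- d$dist[upd]
  }
  list(arc = best_s, dist = best_d, total = cum[length(cum)])
}

# proper (transversal) intersection of segments p1-p2 and p3-p4; returns
# the intersection point or NULL. Shared end points do not count.
segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(NULL)
  s <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
  eps <- 1e-9
  if (s <= eps || s >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + s * d1
}

# principal direction of a point cloud (total least squares), oriented so
# that it points from the first to the last point in time order
tls_direction <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(c(NA_real_, NA_real_))
  centered <- sweep(pts, 2, colMeans(pts))
  v <- svd(centered, nu = 0, nv = 1)$v[, 1]
  disp <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v * disp) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# turning-angle corner detection on a drawn path. The path is resampled to
# uniform spacing; the turning angle at each vertex compares the incoming
# and outgoing directions over a window of `k` resampled steps. The `n`
# strongest local maxima (min separation `min_sep` mm) are returned in
# path order. Closed paths (ends within 2 mm) are handled circularly.
detect_corners <- function(pts, n, spacing = 1, k = 3, min_sep = 5,
                           min_angle_deg = 25) {
  rp <- resample_polyline(as.matrix(pts), spacing)
  m <- nrow(rp)
  if (m < 2 * k + 3) return(NULL)
  closed <- sqrt(sum((rp[m, ] - rp[1, ])^2)) < 2
  idx_at <- function(i) ((i - 1) %% m) + 1L
  angle_at <- function(i) {
    if (!closed && (i - k < 1 || i + k > m)) return(0)
    before <- rp[idx_at(i), ] - rp[idx_at(i - k), ]
    after <- rp[idx_at(i + k), ] - rp[idx_at(i), ]
    nb <- sqrt(sum(before^2)); na_ <- sqrt(sum(after^2))
    if (nb == 0 || na_ == 0) return(0)
    cosang <- max(-1, min(1, sum(before * after) / (nb * na_)))
    acos(cosang) * 180 / pi
  }
  ang <- vapply(seq_len(m), angle_at, numeric(1))
  cand <- which(ang >= min_angle_deg)
  if (!length(cand)) return(NULL)
  keep <- integer()
  for (i in cand[order(-ang[cand])]) {
    sep <- if (closed) pmin(abs(keep - i), m - abs(keep - i)) else abs(keep - i)
    if (!length(keep) || all(sep * spacing >= min_sep)) keep <- c(keep, i)
    if (length(keep) == n) break
  }
  if (length(keep) < n) return(NULL)
  rp[sort(keep), , drop = FALSE]
}
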