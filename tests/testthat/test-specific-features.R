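quiet <- quiet_profile()

test_that("line MSE and line assignment follow their definitions", {
  expect_equal(line_mse(rep(100, 20), 100), 0)
  expect_equal(line_mse(rep(102, 20), 100), 4)
  expect_true(is.na(line_mse(numeric(), 100)))
  set.seed(2)
  y <- 100 + stats::rnorm(50)
  expect_equal(line_mse(y, 100), mean((y - 100)^2))
  # three well-separated bands
  ys <- c(119.5, 120.2, 99.8, 100.1, 80.3)
  expect_identical(assign_to_lines(ys, c(120, 100, 80)),
                   c(1L, 1L, 2L, 2L, 3L))
  # equidistant sample goes to the lower index
  expect_identical(assign_to_lines(110, c(120, 100, 80)), 1L)
  set.seed(4)
  for (i in 1:100) {
    y <- stats::runif(30, 60, 140)
    lines <- sort(stats::runif(3, 60, 140), decreasing = TRUE)
    want <- apply(abs(outer(y, lines, "-")), 1, which.min)
    expect_identical(assign_to_lines(y, lines), as.integer(want))
  }
})

test_that("circuit 1: perfect tracing scores perfectly, backtracks counted", {
  rec <- simulate_drawing(make_template("circuit1"), quiet, seed = 1)
  f <- circuit1_features(rec)
  expect_length(f, 17)
  for (L in 1:3) {
    expect_equal(f[[sprintf("line%d_mse", L)]], 0, tolerance = 1e-9)
    expect_equal(f[[sprintf("line%d_n_strokes", L)]], 1)
    expect_equal(f[[sprintf("line%d_backtracks", L)]], 0)
    expect_equal(f[[sprintf("line%d_completion_first_lift", L)]], 100,
                 tolerance = 0.5)
  }
  expect_equal(f[["slope_std"]], 0, tolerance = 1e-9)
  # hand-built: second stroke on line 1 starts 5 mm left of the first's end
  s1 <- data.frame(t = (0:100) / 200, x = seq(20, 80, length.out = 101),
                   y = 120, z = 0, pen_down = TRUE)
  lift <- data.frame(t = (101:120) / 200, x = 80, y = 120, z = 3,
                     pen_down = FALSE)
  s2 <- data.frame(t = (121:221) / 200, x = seq(75, 140, length.out = 101),
                   y = 120, z = 0, pen_down = TRUE)
  rec2 <- recording("circuit1", rbind(s1, lift, s2))
  f2 <- circuit1_features(rec2)
  expect_equal(f2[["line1_backtracks"]], 1)
  expect_equal(f2[["line1_n_strokes"]], 2)
  # random stroke layouts vs a brute-force start/end comparison
  set.seed(8)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    xs <- stats::runif(k, 20, 140)
    ends <- xs + stats::runif(k, 5, 20)
    pieces <- list()
    tcur <- 0
    for (j in seq_len(k)) {
      n <- 60
      pieces[[2 * j - 1]] <- data.frame(
        t = tcur + (1:n) / 200,
        x = seq(xs[j], ends[j], length.out = n), y = 120, z = 0,
        pen_down = TRUE)
      tcur <- tcur + n / 200
      pieces[[2 * j]] <- data.frame(t = tcur + (1:10) / 200, x = ends[j],
                                    y = 120, z = 3, pen_down = FALSE)
      tcur <- tcur + 10 / 200
    }
    recl <- recording("circuit1", do.call(rbind, pieces), validate = FALSE)
    fl <- circuit1_features(recl)
    want <- sum(xs[-1] < ends[-k])
    expect_equal(fl[["line1_backtracks"]], want)
  }
})

test_that("turn quality is 1 - cosine and bounded", {
  expect_equal(angle_quality(c(1, 0), c(0, 1)), 1)
  expect_equal(angle_quality(c(1, 0), c(1, 0)), 0)
  expect_equal(angle_quality(c(1, 0), c(-1, 0)), 2)
  expect_warning(q <- angle_quality(c(2, 0), c(0, 3)), "normalized")
  expect_equal(q, 1)
  expect_error(angle_quality(c(0, 0), c(1, 0)), "zero-length")
  # monotone decreasing in the cosine of the turn angle, range [0, 2]
  th <- seq(0, pi, length.out = 50)
  qs <- vapply(th, function(a) angle_quality(c(1, 0), c(cos(a), sin(a))),
               numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_true(all(qs >= 0 & qs <= 2))
})

test_that("circuit 2: perfect labyrinth and off-turn lift detection", {
  rec <- simulate_drawing(make_template("circuit2"), quiet, seed = 1)
  f <- circuit2_features(rec)
  expect_length(f, 9)
  expect_equal(f[["mse_long"]], 0, tolerance = 1e-9)
  expect_equal(f[["mse_short"]], 0, tolerance = 1e-9)
  expect_equal(f[["slope_std_long"]], 0, tolerance = 1e-9)
  expect_equal(f[["slope_std_short"]], 0, tolerance = 1e-9)
  expect_equal(f[["completion_first_lift"]], 100)
  expect_equal(f[["lifts_off_turn"]], 0)
  expect_equal(f[["quality_mean"]], 1, tolerance = 1e-6)
  expect_equal(f[["quality_std"]], 0, tolerance = 1e-6)
  # inserting a lift mid-segment (collinear flanks) makes one off-turn lift
  rec2 <- rec
  mid <- which(rec2$samples$x > 80 & rec2$samples$x < 90 &
                 abs(rec2$samples$y - 120) < 0.1)
  rec2$samples$pen_down[mid] <- FALSE
  f2 <- circuit2_features(rec2)
  expect_equal(f2[["lifts_off_turn"]], 1)
  expect_lt(f2[["completion_first_lift"]], 100)
})

test_that("direction changes: straight lines, ovals, zigzag oracle", {
  t <- seq(0, 1, by = 1 / 200)
  expect_equal(count_direction_changes(20 * t, 0 * t, 200), 0)
  # ideal ovals: exactly 4 changes regardless of starting point
  for (start in c(0, 0.8, 2.1, 4)) {
    phi <- seq(start, start + 2 * pi, length.out = 1200)
    expect_equal(count_direction_changes(60 * cos(phi), 30 * sin(phi), 200),
                 4)
  }
  # synthetic zigzag: alternating right / up sweeps, long enough to commit
  n_seg <- 7
  xs <- c(); ys <- c(); x <- 0; y <- 0
  for (k in seq_len(n_seg)) {
    if (k %% 2 == 1) { xs <- c(xs, x + (1:60) / 4); ys <- c(ys, rep(y, 60));
      x <- x + 15 } else { ys <- c(ys, y + (1:60) / 4); xs <- c(xs, rep(x, 60))
      y <- y + 15 }
  }
  expect_equal(count_direction_changes(xs, ys, 200), n_seg - 1)
})

test_that("circuit 3: perfect oval, centre degeneracy, entropy weights", {
  rec <- simulate_drawing(make_template("circuit3"), quiet, seed = 1)
  f <- circuit3_features(rec)
  expect_length(f, 5)
  expect_equal(f[["mse_oval"]], 0, tolerance = 1e-5)
  expect_equal(f[["direction_changes"]], 4)
  expect_equal(f[["completion_first_lift"]], 100)
  M <- sum(rec$samples$pen_down)
  expect_equal(f[["oval_re2"]], log(M), tolerance = 1e-9)
  # all samples at the centre: weights uniform again, radial MSE = a^2
  tpl <- make_template("circuit3")
  n <- 100
  centre <- recording("circuit3",
                      data.frame(t = (0:(n - 1)) / 200,
                                 x = tpl$oval$cx + 1e-9 * (1:n),
                                 y = tpl$oval$cy,
                                 z = 0, pen_down = TRUE))
  fc <- circuit3_features(centre)
  expect_equal(fc[["mse_oval"]], tpl$oval$a^2, tolerance = 1e-6)
  expect_equal(fc[["oval_re2"]], log(n), tolerance = 1e-6)
  # noisy ovals vs the two-step oracle (Gaussian weights, then entropy)
  set.seed(14)
  for (i in 1:20) {
    phi <- seq(0, 2 * pi, length.out = 400)
    r_noise <- 1 + stats::rnorm(400, 0, 0.05)
    x <- tpl$oval$cx + tpl$oval$a * r_noise * cos(phi)
    y <- tpl$oval$cy + tpl$oval$b * r_noise * sin(phi)
    recn <- recording("circuit3",
                      data.frame(t = seq_along(x) / 200, x = x, y = y,
                                 z = 0, pen_down = TRUE))
    d <- sqrt((x - tpl$oval$cx)^2 +
                ((y - tpl$oval$cy) * tpl$oval$a / tpl$oval$b)^2)
    w <- exp(-(d - tpl$oval$a)^2 / 200)
    w <- w / sum(w)
    fn <- circuit3_features(recn)
    expect_equal(fn[["oval_re2"]], -log(sum(w^2)), tolerance = 1e-9)
    expect_equal(fn[["mse_oval"]], mean((d - tpl$oval$a)^2))
  }
})

test_that("shapes 1: diameters, their ratio and the curvature index", {
  rec <- simulate_drawing(make_template("shapes1"), quiet, seed = 1)
  f <- shapes1_features(rec)
  expect_length(f, 12)
  expect_equal(f[["circle_diameter_h"]], 30, tolerance = 0.02)
  expect_equal(f[["circle_diameter_v"]], 30, tolerance = 0.02)
  expect_equal(f[["circle_diameter_ratio"]], 1, tolerance = 1e-3)
  expect_equal(f[["curvature_index"]], 1, tolerance = 1e-3)
  # a 2:1 ellipse drawn in place of the circle
  tpl <- make_template("shapes1")
  phi <- seq(0, 2 * pi, length.out = 500)
  ell <- recording("shapes1",
                   data.frame(t = seq_along(phi) / 200,
                              x = tpl$circle$cx + 20 * cos(phi),
                              y = tpl$circle$cy + 10 * sin(phi),
                              z = 0, pen_down = TRUE))
  fe <- shapes1_features(ell)
  expect_equal(fe[["circle_diameter_ratio"]], 2, tolerance = 1e-3)
  # wavy line: drawn length from the cumulative-segment oracle
  xw <- seq(30, 30, length.out = 300)
  yw <- seq(60, 100, length.out = 300)
  xw <- xw + 0.5 * sin(seq(0, 6 * pi, length.out = 300))
  wavy <- recording("shapes1",
                    data.frame(t = seq_along(xw) / 200, x = xw, y = yw,
                               z = 0, pen_down = TRUE))
  fw <- shapes1_features(wavy)
  expect_equal(fw[["vline_path_length"]],
               sum(sqrt(diff(xw)^2 + diff(yw)^2)))
})

test_that("shapes 2: corner perimeters and bar ratios", {
  rec <- simulate_drawing(make_template("shapes2"), quiet, seed = 1)
  f <- shapes2_features(rec)
  expect_length(f, 12)
  expect_equal(f[["triangle_corner_perimeter"]], 90, tolerance = 1)
  expect_equal(f[["square_corner_perimeter"]], 100, tolerance = 1)
  expect_equal(f[["plus_segment_ratio"]], 1, tolerance = 1e-6)
  expect_equal(f[["cross_segment_ratio"]], 1, tolerance = 1e-6)
  # perturbed polygon: corners still recovered near the true vertices
  set.seed(33)
  tri <- rbind(c(20, 65), c(50, 65), c(35, 90.98), c(20, 65))
  dense <- resample_polyline(tri, 0.5)
  dense <- dense + matrix(stats::rnorm(length(dense), 0, 0.15),
                          ncol = 2)
  found <- detect_corners(dense, 3)
  expect_false(is.null(found))
  for (v in 1:3) {
    gaps <- sqrt((found[, 1] - tri[v, 1])^2 + (found[, 2] - tri[v, 2])^2)
    expect_lt(min(gaps), 3)
  }
})

test_that("feature counts per stimulus sum to the registry total", {
  counts <- vapply(GRAPHO_STIMULI,
                   function(s) length(specific_feature_names(s)),
                   integer(1))
  expect_identical(unname(counts), c(17L, 9L, 5L, 12L, 12L, 8L))
  expect_identical(sum(counts), 63L)
  reg <- feature_registry()
  expect_identical(nrow(reg), 345L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_identical(sum(reg$kind == "general"), 6L * 47L)
})
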