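# Stimulus template geometries, in mm on an A4-scale drawing area.
# Components are polylines (ellipses are discretized); each carries a role
# so the specific features know what it is. Dimensions are package
# constants chosen to a plausible school-workbook scale.

ellipse_points <- function(cx, cy, a, b, from = pi, by = 2 * pi,
                           n = 720) {
  phi <- seq(from, from + by, length.out = n)
  cbind(cx + a * cos(phi), cy + b * sin(phi))
}

# one cursive loop: drift d to the right, lobe width w, height h (signed:
# positive = up loop). Crosses itself once near the baseline.
loop_points <- function(x0, y0, d = 8, w = 5, h = 18, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  cbind(x0 + d * th / (2 * pi) + w * sin(th),
        y0 + h * (1 - cos(th)) / 2)
}

loops_series_points <- function(x0, y0, orientations, d = 8, w = 5, h = 18,
                                link = 6) {
  pts <- cbind(x0 - link, y0)
  x <- x0
  for (o in orientations) {
    lp <- loop_points(x, y0, d = d, w = w, h = if (o == "up") h else -h)
    pts <- rbind(pts, lp)
    x <- x + d + link
    pts <- rbind(pts, cbind(x, y0))
  }
  pts
}

#' Build the template geometry of a stimulus
#'
#' Deterministic, package-versioned geometry for each of the six drawing
#' tasks: Circuit 1 is three parallel horizontal lines (thick to thin,
#' top to bottom); Circuit 2 a boustrophedon labyrinth of 5 long and 4
#' short parts joined by 8 right-angle corners; Circuit 3 an oval
#' (ellipse); Shapes 1 a vertical, horizontal and sloping line plus a
#' circle; Shapes 2 a triangle, plus sign, square and diagonal cross; The
#' Loops two series of six alternated cursive loops (3 up and 3 down per
#' series). The same geometry drives the synthetic simulator and the
#' template-anchored features. An equivalent JSON dump ships in
#' `inst/extdata/templates.json` (see [write_templates_json()]); users may
#' substitute their own geometry with the same schema.
#'
#' @param stimulus_id One of [GRAPHO_STIMULI].
#' @return List of class `grapho_template` with `stimulus_id`,
#'   `components` (named list of polylines with roles) and, per stimulus,
#'   extra template parameters (line heights, corner list, ellipse
#'   parameters, shape inventory, loop layout).
#' @export
make_template <- function(stimulus_id) {
  stimulus_id <- match.arg(stimulus_id, GRAPHO_STIMULI)
  tpl <- switch(stimulus_id,
    circuit1 = {
      ys <- c(120, 100, 80); x0 <- 20; x1 <- 170
      comps <- lapply(1:3, function(i)
        list(name = paste0("line", i), role = "line", index = i,
             points = cbind(c(x0, x1), c(ys[i], ys[i]))))
      names(comps) <- paste0("line", 1:3)
      list(components = comps, line_y = ys, x_start = x0, x_end = x1)
    },
    circuit2 = {
      xl <- 20; xr <- 150; ys <- c(120, 105, 90, 75, 60)
      verts <- rbind(c(xl, ys[1]), c(xr, ys[1]), c(xr, ys[2]), c(xl, ys[2]),
                     c(xl, ys[3]), c(xr, ys[3]), c(xr, ys[4]), c(xl, ys[4]),
                     c(xl, ys[5]), c(xr, ys[5]))
      roles <- rep(c("long", "short"), length.out = 9)
      comps <- lapply(1:9, function(i)
        list(name = sprintf("part%d_%s", i, roles[i]), role = roles[i],
             index = i, points = verts[i:(i + 1), , drop = FALSE]))
      names(comps) <- vapply(comps, `[[`, "", "name")
      list(components = comps, corners = verts[2:9, , drop = FALSE],
           path = verts)
    },
    circuit3 = {
      oval <- list(cx = 95, cy = 90, a = 60, b = 30)
      pts <- ellipse_points(oval$cx, oval$cy, oval$a, oval$b)
      list(components = list(oval = list(name = "oval", role = "oval",
                                         points = pts)),
           oval = oval)
    },
    shapes1 = {
      circ <- list(cx = 160, cy = 80, r = 15)
      comps <- list(
        vline = list(name = "vline", role = "line",
                     points = cbind(c(30, 30), c(60, 100))),
        hline = list(name = "hline", role = "line",
                     points = cbind(c(50, 90), c(80, 80))),
        sline = list(name = "sline", role = "line",
                     points = cbind(c(100, 130), c(60, 100))),
        circle = list(name = "circle", role = "circle",
                      points = ellipse_points(circ$cx, circ$cy, circ$r,
                                              circ$r, from = pi / 2)))
      list(components = comps, circle = circ,
           shapes = c("vline", "hline", "sline", "circle"))
    },
    shapes2 = {
      tri <- rbind(c(20, 65), c(50, 65), c(35, 65 + 30 * sin(pi / 3)),
                   c(20, 65))
      sq <- rbind(c(110, 65), c(135, 65), c(135, 90), c(110, 90), c(110, 65))
      comps <- list(
        triangle = list(name = "triangle", role = "polygon", shape = "triangle",
                        points = tri, n_corners = 3),
        plus_h = list(name = "plus_h", role = "bar", shape = "plus",
                      points = cbind(c(70, 95), c(80, 80))),
        plus_v = list(name = "plus_v", role = "bar", shape = "plus",
                      points = cbind(c(82.5, 82.5), c(67.5, 92.5))),
        square = list(name = "square", role = "polygon", shape = "square",
                      points = sq, n_corners = 4),
        cross_a = list(name = "cross_a", role = "bar", shape = "cross",
                       points = cbind(c(150, 175), c(67.5, 92.5))),
        cross_b = list(name = "cross_b", role = "bar", shape = "cross",
                       points = cbind(c(150, 175), c(92.5, 67.5))))
      list(components = comps,
           shapes = c("triangle", "plus", "square", "cross"))
    },
    loops = {
      orient <- rep(c("up", "down"), 3)
      s1 <- loops_series_points(25, 80, orient)
      s2 <- loops_series_points(120, 80, orient)
      comps <- list(
        series1 = list(name = "series1", role = "loops", points = s1,
                       orientations = orient),
        series2 = list(name = "series2", role = "loops", points = s2,
                       orientations = orient))
      list(components = comps, n_up = 6, n_down = 6,
           loop = list(d = 8, w = 5, h = 18, link = 6, baseline = 80))
    })
  structure(c(list(stimulus_id = stimulus_id), tpl),
            class = "grapho_template")
}

# centroid of each shape of a copying task, for stroke-to-shape assignment
template_shape_centroids <- function(tpl) {
  shapes <- tpl$shapes
  out <- matrix(NA_real_, length(shapes), 2,
                dimnames = list(shapes, c("x", "y")))
  for (s in shapes) {
    pts <- do.call(rbind, lapply(tpl$components, function(cc)
      if (identical(cc$shape, s) || identical(cc$name, s)) cc$points else NULL))
    out[s, ] <- colMeans(pts)
  }
  out
}

#' Export template geometries as JSON
#'
#' Writes all six stimulus templates (components as point arrays with
#' roles, plus template parameters) to a JSON file matching the schema in
#' `inst/extdata/templates.json`.
#'
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_templates_json <- function(path) {
  dump <- lapply(GRAPHO_STIMULI, function(st) {
    tpl <- make_template(st)
    tpl$components <- lapply(tpl$components, function(cc) {
      cc$points <- unname(apply(cc$points, 1, function(r) round(r, 4),
                                simplify = FALSE))
      cc
    })
    unclass(tpl)
  })
  names(dump) <- GRAPHO_STIMULI
  jsonlite::write_json(list(schema_version = 1, templates = dump), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
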