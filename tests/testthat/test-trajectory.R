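test_that("recordings round-trip through CSV + sidecar losslessly", {
  set.seed(11)
  for (i in 1:3) {
    rec <- random_recording(1000)
    path <- file.path(withr::local_tempdir(), "rec.csv")
    write_recording(rec, path)
    back <- read_recording(path)
    expect_equal(back$samples$t, rec$samples$t, tolerance = 1e-9)
    expect_equal(back$samples$x, rec$samples$x, tolerance = 1e-9)
    expect_equal(back$samples$y, rec$samples$y, tolerance = 1e-9)
    expect_identical(back$samples$pen_down, rec$samples$pen_down)
    expect_identical(back$stimulus_id, rec$stimulus_id)
    expect_identical(back$meta$subject_id, rec$meta$subject_id)
    expect_identical(back$meta$group, rec$meta$group)
    expect_equal(back$sampling_rate, rec$sampling_rate)
  }
})

test_that("recording without metadata round-trips with null group", {
  rec <- make_rec(x = c(0, 1, 2, 3), y = rep(0, 4))
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  m <- jsonlite::read_json(sub("\\.csv$", ".meta.json", path))
  expect_null(m$group)
  expect_identical(m$stimulus_id, "circuit1")
  back <- read_recording(path)
  expect_null(back$meta)
})

test_that("malformed inputs are rejected with informative errors", {
  # duplicated timestamp
  expect_error(
    recording("circuit1",
              data.frame(t = c(0, 0.005, 0.005, 0.015), x = 1:4, y = 1:4,
                         z = 0, pen_down = TRUE)),
    "strictly increasing.*index 3")
  # no pen-down sample
  expect_error(
    recording("circuit1",
              data.frame(t = (0:3) / 200, x = 1:4, y = 1:4, z = 3,
                         pen_down = FALSE)),
    "empty drawing")
  # missing column in CSV
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(t = (0:3) / 200, x = 1:4, y = 1:4),
                   path, row.names = FALSE)
  writeLines("{}", file.path(dir, "bad.meta.json"))
  expect_error(read_recording(path), "missing column.*z")
  expect_error(read_recording(file.path(dir, "nope.csv")), "not found")
})

test_that("unit conversion is elementwise multiplication by the resolution", {
  expect_equal(to_physical_units(c(0, 4, 8), 0.25), c(0, 1, 2))
  expect_equal(to_physical_units(rep(0, 5), 0.25), rep(0, 5))
  set.seed(7)
  counts <- sample.int(4000, 50)
  expect_equal(to_physical_units(counts, 0.25), counts * 0.25)
  expect_error(to_physical_units(1:3, 0), "positive")
  expect_error(to_physical_units(1:3, -1), "positive")
})

test_that("stroke segmentation matches a run-length oracle on random patterns", {
  # oracle: scan the boolean vector sample by sample
  oracle <- function(pd) {
    strokes <- list(); lifts <- list(); cur <- NULL
    runs <- list(); val <- pd[1]; start <- 1L
    for (i in seq_along(pd)[-1]) {
      if (pd[i] != val) {
        runs[[length(runs) + 1L]] <- c(val, start, i - 1L)
        val <- pd[i]; start <- i
      }
    }
    runs[[length(runs) + 1L]] <- c(val, start, length(pd))
    m <- do.call(rbind, runs)
    down <- which(m[, 1] == 1)
    lift <- which(m[, 1] == 0 & seq_len(nrow(m)) > min(down) &
                    seq_len(nrow(m)) < max(down))
    list(strokes = m[down, 2:3, drop = FALSE],
         lifts = m[lift, 2:3, drop = FALSE])
  }
  expect_error(segment_strokes(make_rec(1:2, 1:2, pen = c(FALSE, FALSE))),
               "empty drawing")
  simple <- segment_strokes(make_rec(1:4, 1:4,
                                     pen = c(TRUE, TRUE, FALSE, TRUE)))
  expect_length(simple$strokes, 2)
  expect_length(simple$lifts, 1)
  all_down <- segment_strokes(make_rec(1:5, 1:5))
  expect_length(all_down$strokes, 1)
  expect_length(all_down$lifts, 0)

  set.seed(21)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    pd <- stats::runif(n) > 0.4
    if (!any(pd)) pd[sample(n, 1)] <- TRUE
    rec <- make_rec(seq_len(n), seq_len(n), pen = pd)
    seg <- segment_strokes(rec)
    orc <- oracle(as.integer(pd))
    expect_equal(t(vapply(seg$strokes, function(s) c(s$start, s$end),
                          integer(2))),
                 unname(orc$strokes))
    if (length(seg$lifts) || nrow(orc$lifts))
      expect_equal(t(vapply(seg$lifts, function(s) c(s$start, s$end),
                            integer(2))),
                   unname(orc$lifts))
    # partition property: runs cover every sample exactly once
    covered <- sum(vapply(c(seg$strokes, seg$lifts),
                          function(s) s$end - s$start + 1L, integer(1)))
    leading <- which(pd)[1] - 1L
    trailing <- n - max(which(pd))
    expect_identical(covered + leading + trailing, n)
  }
})

test_that("segmentation is idempotent under re-serialization", {
  set.seed(5)
  rec <- random_recording(300)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  seg1 <- segment_strokes(rec)
  seg2 <- segment_strokes(read_recording(path))
  expect_equal(lapply(seg1$strokes, `[[`, "start"),
               lapply(seg2$strokes, `[[`, "start"))
  expect_equal(lapply(seg1$strokes, `[[`, "end"),
               lapply(seg2$strokes, `[[`, "end"))
})

test_that("validation reports findings without throwing", {
  quiet <- quiet_profile()
  clean <- simulate_drawing(make_template("circuit1"), quiet, seed = 1)
  expect_identical(validate_recording(clean), character())

  no_pen <- clean
  no_pen$samples$pen_down <- FALSE
  expect_true("empty drawing" %in% validate_recording(no_pen))

  set.seed(3)
  jit <- clean
  n <- nrow(jit$samples)
  jit$samples$t <- jit$samples$t +
    c(0, cumsum(stats::runif(n - 1, -0.2, 0.2) / 200))
  jit$samples$t <- sort(jit$samples$t)
  expect_true("sampling jitter" %in% validate_recording(jit))
  # and resampling onto the nominal grid clears the finding
  fixed <- resample_recording(jit)
  expect_false("sampling jitter" %in% validate_recording(fixed))
})
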