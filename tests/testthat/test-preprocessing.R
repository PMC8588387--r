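amplitude_of <- function(x, freq, rate = 200) {
  # steady-state amplitude by projection on the sine/cosine pair,
  # ignoring the outer 20% where edge effects live
  n <- length(x)
  keep <- round(0.2 * n):round(0.8 * n)
  t <- (keep - 1) / rate
  fit <- stats::lm(x[keep] ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

test_that("Butterworth filter has unit DC gain and the expected band edges", {
  expect_equal(lowpass_filter(rep(3.7, 100), 200), rep(3.7, 100),
               tolerance = 1e-8)
  t <- seq(0, 2, by = 1 / 200)
  expect_gte(amplitude_of(lowpass_filter(sin(2 * pi * 5 * t), 200), 5), 0.99)
  # analytic zero-phase order-4 digital (bilinear, pre-warped) response
  # at 40 Hz: (1 + (tan(pi 40/200) / tan(pi 15/200))^8)^-1
  att40 <- 1 / (1 + (tan(pi * 40 / 200) / tan(pi * 15 / 200))^8)
  expect_lte(amplitude_of(lowpass_filter(sin(2 * pi * 40 * t), 200), 40),
             0.05)
  expect_equal(amplitude_of(lowpass_filter(sin(2 * pi * 40 * t), 200), 40),
               att40, tolerance = 0.5 * att40)
  # at the cutoff the two passes give -6 dB, i.e. amplitude 0.5 (within 10%)
  expect_equal(amplitude_of(lowpass_filter(sin(2 * pi * 15 * t), 200), 15),
               0.5, tolerance = 0.05)
  expect_error(lowpass_filter(1:5, 200), "too short")
  expect_error(lowpass_filter(stats::rnorm(100), rate = 20, cutoff = 15),
               "twice the cutoff")
})

test_that("filtering is linear", {
  set.seed(42)
  s1 <- stats::rnorm(300); s2 <- stats::rnorm(300)
  lhs <- lowpass_filter(2.5 * s1 - 1.3 * s2, 200)
  rhs <- 2.5 * lowpass_filter(s1, 200) - 1.3 * lowpass_filter(s2, 200)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("kinematics recover closed-form derivatives", {
  # uniform motion: speed v, zero jerk
  ss <- line_stroke(v = 20, duration = 1)
  kin <- compute_kinematics(ss, 200)
  expect_equal(kin$speed, rep(20, nrow(ss)), tolerance = 1e-9)
  expect_equal(max(abs(kin$jerk)), 0, tolerance = 1e-6)
  # stationary pen
  still <- data.frame(x = rep(1, 50), y = rep(2, 50))
  expect_equal(compute_kinematics(still, 200)$speed, rep(0, 50))
  # x(t) = t^2 -> acceleration 2 (interior points)
  t <- (0:400) / 200
  quad <- data.frame(x = t^2, y = 0 * t)
  acc <- compute_kinematics(quad, 200)$accel
  expect_equal(acc[5:395], rep(2, 391), tolerance = 1e-6)
  expect_error(compute_kinematics(still[1:3, ], 200), ">= 4")
})

test_that("velocity peaks match a brute-force scan with the same rules", {
  # oracle: independent quadratic-time implementation
  oracle_peaks <- function(speed, rate, frac = 0.1, sep_s = 0.05) {
    n <- length(speed)
    if (n < 3 || max(speed) <= 0) return(integer())
    cand <- integer()
    for (i in 2:(n - 1))
      if (speed[i] > speed[i - 1] && speed[i] >= speed[i + 1])
        cand <- c(cand, i)
    prom <- vapply(cand, function(p) {
      lmin <- speed[p]; i <- p
      while (i > 1 && speed[i - 1] <= speed[p]) {
        i <- i - 1; lmin <- min(lmin, speed[i])
      }
      if (i == 1) lmin <- min(speed[1:p])
      rmin <- speed[p]; i <- p
      while (i < n && speed[i + 1] <= speed[p]) {
        i <- i + 1; rmin <- min(rmin, speed[i])
      }
      if (i == n) rmin <- min(speed[p:n])
      speed[p] - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= frac * max(speed)]
    keep <- integer()
    for (p in cand[order(-speed[cand], cand)])
      if (!length(keep) || all(abs(keep - p) >= sep_s * rate))
        keep <- c(keep, p)
    sort(keep)
  }
  expect_length(find_velocity_peaks(seq(0, 10, length.out = 100),
                                    200)$indices, 0)
  expect_length(find_velocity_peaks(rep(5, 100), 200)$indices, 0)
  t <- seq(0, 3, by = 1 / 200)
  humps <- abs(sin(pi * t))   # 3 full humps on [0, 3]
  expect_length(find_velocity_peaks(humps, 200)$indices, 3)

  set.seed(13)
  for (i in 1:200) {
    speed <- pmax(0, stats::rnorm(sample(20:80, 1), mean = 2))
    got <- find_velocity_peaks(speed, 200)
    expect_identical(got$indices, oracle_peaks(speed, 200))
  }
  # peak count invariant under uniform speed scaling
  speed <- pmax(0, stats::rnorm(100, 2))
  expect_identical(find_velocity_peaks(speed * 7.3, 200)$indices,
                   find_velocity_peaks(speed, 200)$indices)
})

test_that("low-velocity segments match a sliding-window oracle", {
  # 10 mm/s covers 1.5 mm per 150 ms: never low-velocity
  fast <- line_stroke(v = 10, duration = 1)
  expect_identical(nrow(find_low_velocity_segments(fast, 200)$segments), 0L)
  # a 1 s freeze inside a stroke
  pre <- line_stroke(v = 20, duration = 0.5)
  hold <- pre[rep(nrow(pre), 200), ]
  post <- pre; post$x <- post$x + max(pre$x)
  stroke <- rbind(pre, hold, post)
  lv <- find_low_velocity_segments(stroke, 200)
  expect_identical(nrow(lv$segments), 1L)
  expect_equal(lv$total_duration, 1, tolerance = 0.06)

  oracle_flags <- function(st, rate, win = 0.15, thr = 1) {
    # same full-length shifted-window convention, written sample by sample
    n <- nrow(st); half <- round(win * rate / 2)
    vapply(seq_len(n), function(i) {
      a <- max(1, min(i - half, n - 2 * half))
      b <- min(n, a + 2 * half)
      sqrt((st$x[b] - st$x[a])^2 + (st$y[b] - st$y[a])^2) < thr
    }, logical(1))
  }
  set.seed(31)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    st <- data.frame(x = cumsum(stats::rnorm(n, 0, 0.05)),
                     y = cumsum(stats::rnorm(n, 0, 0.05)))
    got <- find_low_velocity_segments(st, 200)
    flags <- oracle_flags(st, 200)
    r <- rle(flags); ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    expect_equal(got$segments$start, starts[r$values])
    expect_equal(got$segments$end, ends[r$values])
  }
})

test_that("abnormal stops: mid-stroke freezes counted, transients excluded", {
  smooth <- line_stroke(v = 20, duration = 2)
  expect_identical(find_abnormal_stops(smooth, 200)$count, 0L)
  # one 400 ms freeze mid-stroke
  pre <- line_stroke(v = 20, duration = 1)
  hold <- pre[rep(nrow(pre), 80), ]
  post <- pre; post$x <- post$x + max(pre$x)
  st <- rbind(pre, hold, post)
  ab <- find_abnormal_stops(st, 200)
  expect_identical(ab$count, 1L)
  expect_equal(ab$total_duration, 0.4, tolerance = 0.15)
  # several injected freezes vs a brute-force segment scan
  set.seed(17)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    pieces <- list(line_stroke(v = 30, duration = 0.8))
    for (j in seq_len(k)) {
      last <- pieces[[length(pieces)]]
      freeze <- last[rep(nrow(last), sample(70:130, 1)), ]
      nxt <- line_stroke(v = 30, duration = 0.8)
      nxt$x <- nxt$x + max(last$x)
      pieces <- c(pieces, list(freeze, nxt))
    }
    st <- do.call(rbind, pieces)
    expect_identical(find_abnormal_stops(st, 200)$count, k)
  }
})
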