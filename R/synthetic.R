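# Synthetic graphomotor cohort: template-faithful drawings with
# controllable tremor, lifts, stops, backtracking and age-dependent
# skill, so every pipeline stage can run without clinical data.

#' Writer profile for the drawing simulator
#'
#' Parameters of the synthetic pen: cruising speed, band-limited tremor
#' (added orthogonally to the path; the 4-12 Hz band survives the 15 Hz
#' preprocessing filter by design), random pen lifts and freezes,
#' backtracking after lifts and loop-size variability. Skill improves
#' with age: tremor and variability are multiplied by
#' `1 + age_skill_slope * (11 - age_years)`, so younger writers are
#' noisier across the 7-11 year span. `multipliers` scales the noise
#' channels (tremor, lift, stop, backtrack, variability) for the DYS
#' profile; all must be >= 1.
#'
#' @param group `"TD"` or `"DYS"`.
#' @param base_speed Pen speed in mm/s (default 40).
#' @param tremor_amp Tremor standard deviation in mm (default 0.25).
#' @param tremor_band Tremor frequency band in Hz (default c(4, 12)).
#' @param lift_rate Random pen lifts per second (default 0.04).
#' @param stop_rate Mid-stroke freezes per second (default 0.02).
#' @param stop_duration Mean freeze duration in s (default 0.3).
#' @param backtrack_prob Probability that a lift resumes behind the lift
#'   point (default 0.1).
#' @param loop_cv Coefficient of variation of loop sizes (default 0.06).
#' @param age_skill_slope Noise shrinkage per year of age (default 0.15).
#' @param multipliers Named numeric vector with entries `tremor`, `lift`,
#'   `stop`, `backtrack`, `variability`; defaults to 1 (TD) and is
#'   typically c(2.5, 3, 3, 2, 2) for a DYS profile.
#' @return List of class `grapho_profile`.
#' @export
writer_profile <- function(group = c("TD", "DYS"), base_speed = 40,
                           tremor_amp = 0.25, tremor_band = c(4, 12),
                           lift_rate = 0.04, stop_rate = 0.02,
                           stop_duration = 0.3, backtrack_prob = 0.1,
                           loop_cv = 0.06, age_skill_slope = 0.15,
                           multipliers = c(tremor = 1, lift = 1, stop = 1,
                                           backtrack = 1, variability = 1)) {
  group <- match.arg(group)
  stopifnot(all(multipliers >= 1), base_speed > 0, tremor_amp >= 0,
            lift_rate >= 0, stop_rate >= 0)
  structure(list(group = group, base_speed = base_speed,
                 tremor_amp = tremor_amp, tremor_band = tremor_band,
                 lift_rate = lift_rate, stop_rate = stop_rate,
                 stop_duration = stop_duration,
                 backtrack_prob = backtrack_prob, loop_cv = loop_cv,
                 age_skill_slope = age_skill_slope,
                 multipliers = multipliers), class = "grapho_profile")
}

#' Default dysgraphic writer profile
#'
#' The TD profile with every noise channel amplified: more tremor, more
#' lifts and freezes, more backtracking, less consistent loops.
#'
#' @inheritParams writer_profile
#' @return A `grapho_profile` with `group = "DYS"`.
#' @export
dys_profile <- function(multipliers = c(tremor = 2.5, lift = 3, stop = 3,
                                        backtrack = 2, variability = 2)) {
  writer_profile(group = "DYS", multipliers = multipliers)
}

# band-limited Gaussian tremor, sd scaled to `amp` mm
tremor_series <- function(n, rate, band, amp) {
  if (amp <= 0 || n < 30) return(rep(0, n))
  noise <- stats::rnorm(n)
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  shaped <- signal::filtfilt(bf, noise)
  s <- stats::sd(shaped)
  if (s == 0) rep(0, n) else shaped * (amp / s)
}

# rebuild a loops-series component with per-loop size variability
vary_loops_component <- function(comp, tpl, cv) {
  # regenerate from the layout instead of perturbing points
  lay <- tpl$loop
  orient <- comp$orientations
  x0 <- comp$points[1, 1] + lay$link
  pts <- cbind(comp$points[1, 1], lay$baseline)
  x <- x0
  for (o in orient) {
    f <- max(0.3, 1 + stats::rnorm(1, 0, cv))
    h <- lay$h * f
    w <- lay$w * max(0.3, 1 + stats::rnorm(1, 0, cv))
    lp <- loop_points(x, lay$baseline, d = lay$d, w = w,
                      h = if (o == "up") h else -h)
    pts <- rbind(pts, lp)
    x <- x + lay$d + lay$link
    pts <- rbind(pts, cbind(x, lay$baseline))
  }
  pts
}

#' Simulate one drawing
#'
#' Traces a stimulus template at the profile's speed at 200 Hz, adding
#' band-limited tremor orthogonal to the path, random mid-stroke freezes,
#' random pen lifts (optionally resuming behind the lift point:
#' backtracking) and pen-up transitions between template components.
#' Deterministic given the seed; with all noise channels at zero the
#' trace is template-exact.
#'
#' @param tpl A [make_template()] geometry.
#' @param profile A [writer_profile()].
#' @param age_days Subject age (drives the skill factor).
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 200).
#' @param meta Optional [subject_meta()] attached to the recording.
#' @return A [recording()].
#' @export
simulate_drawing <- function(tpl, profile, age_days = 9 * 365, seed = 0,
                             rate = 200, meta = NULL) {
  set.seed(seed)
  mult <- profile$multipliers
  age_years <- age_days / 365.25
  skill <- 1 + profile$age_skill_slope * max(0, 11 - age_years)
  tremor_amp <- profile$tremor_amp * mult[["tremor"]] * skill
  lift_rate <- profile$lift_rate * mult[["lift"]]
  stop_rate <- profile$stop_rate * mult[["stop"]]
  backtrack_prob <- min(1, profile$backtrack_prob * mult[["backtrack"]])
  loop_cv <- profile$loop_cv * mult[["variability"]] * skill

  ds <- profile$base_speed / rate
  xs <- numeric(); ys <- numeric(); pen <- logical()
  prev_end <- NULL
  for (comp in tpl$components) {
    pts <- comp$points
    if (identical(comp$role, "loops") && loop_cv > 0)
      pts <- vary_loops_component(comp, tpl, loop_cv)
    pts <- resample_polyline(as.matrix(pts), ds)
    if (!is.null(prev_end)) {
      gap <- sqrt(sum((pts[1, ] - prev_end)^2))
      if (gap >= ds) {      # contiguous components continue the stroke
        n_air <- max(2L, ceiling(gap / (1.5 * ds)))
        xs <- c(xs, seq(prev_end[1], pts[1, 1], length.out = n_air))
        ys <- c(ys, seq(prev_end[2], pts[1, 2], length.out = n_air))
        pen <- c(pen, rep(FALSE, n_air))
      }
    }
    xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
    pen <- c(pen, rep(TRUE, nrow(pts)))
    prev_end <- pts[nrow(pts), ]
  }
  n <- length(xs)
  duration <- n / rate

  # mid-stroke freezes: repeat a pen-down sample in place
  n_stops <- stats::rpois(1, stop_rate * duration)
  if (n_stops > 0) {
    for (i in sample(which(pen), min(n_stops, sum(pen)))) {
      len <- max(2L, round(profile$stop_duration * rate *
                             stats::runif(1, 0.7, 1.3)))
      xs <- append(xs, rep(xs[i], len), after = i)
      ys <- append(ys, rep(ys[i], len), after = i)
      pen <- append(pen, rep(TRUE, len), after = i)
    }
  }

  # random lifts: a short pen-up window, optionally resuming a few mm back
  n_lifts <- stats::rpois(1, lift_rate * duration)
  if (n_lifts > 0) {
    interior <- which(pen)
    interior <- interior[interior > 20 & interior < length(pen) - 20]
    for (i in sort(sample(interior, min(n_lifts, length(interior))),
                   decreasing = TRUE)) {
      len <- max(3L, round(rate * stats::runif(1, 0.1, 0.3)))
      win <- i:min(length(pen), i + len)
      pen[win] <- FALSE
      if (stats::runif(1) < backtrack_prob) {
        # re-draw the few mm before the lift: the next stroke starts
        # behind where the previous one ended
        b <- min(i - 1L, max(4L, round(4 / ds)))
        idx <- (i - b):i
        at <- max(win)
        xs <- append(xs, xs[idx], after = at)
        ys <- append(ys, ys[idx], after = at)
        pen <- append(pen, rep(TRUE, length(idx)), after = at)
      }
    }
  }

  n <- length(xs)
  # tremor orthogonal to the local path direction, pen-down only
  if (tremor_amp > 0 && n >= 30) {
    tr <- tremor_series(n, rate, profile$tremor_band, tremor_amp)
    dx <- c(diff(xs), 0); dy <- c(diff(ys), 0)
    nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
    xs <- xs + ifelse(pen, -dy / nrm * tr, 0)
    ys <- ys + ifelse(pen, dx / nrm * tr, 0)
  }

  samples <- data.frame(t = (seq_len(n) - 1) / rate, x = xs, y = ys,
                        z = ifelse(pen, 0, 3), pen_down = pen)
  recording(tpl$stimulus_id, samples, sampling_rate = rate, meta = meta)
}

#' Cohort specification for the simulator
#'
#' @param n_td,n_dys Active-cohort group sizes (defaults 43 and 43).
#' @param n_reference Reference (typical) cohort size for Z-scoring
#'   (default 100).
#' @param age_range_days Uniform age range (default 7-11 years).
#' @param female_prop Probability of `gender == "F"` per group: the
#'   defaults reflect the male prevalence among dysgraphic children
#'   (TD 0.46, DYS 0.26).
#' @param left_prop Probability of left-handedness (TD 0.13, DYS 0.05).
#' @param seed Integer seed.
#' @return List of class `grapho_cohort_spec`.
#' @export
cohort_spec <- function(n_td = 43, n_dys = 43, n_reference = 100,
                        age_range_days = round(c(7, 11) * 365.25),
                        female_prop = c(TD = 0.46, DYS = 0.26),
                        left_prop = c(TD = 0.13, DYS = 0.05),
                        seed = 0) {
  stopifnot(n_td > 0, n_dys > 0, n_reference >= 0)
  structure(list(n_td = n_td, n_dys = n_dys, n_reference = n_reference,
                 age_range_days = age_range_days,
                 female_prop = female_prop, left_prop = left_prop,
                 seed = seed), class = "grapho_cohort_spec")
}

simulate_subject <- function(id, group, origin, age, gender, laterality,
                             profile, stimuli, base_seed) {
  meta <- subject_meta(id, age, gender, laterality, group, origin)
  recs <- lapply(seq_along(stimuli), function(si)
    simulate_drawing(make_template(stimuli[si]), profile, age_days = age,
                     seed = (base_seed + si) %% .Machine$integer.max,
                     meta = meta))
  list(meta = meta, recordings = recs)
}

#' Simulate a full cohort of drawings
#'
#' Generates the active cohort (TD and DYS writers from their respective
#' profiles) and a reference cohort of typical writers for the moving
#' Z-score, each subject with one recording per requested stimulus.
#' Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param td_profile,dys_profile Writer profiles (defaults
#'   [writer_profile()] and [dys_profile()]).
#' @param stimuli Stimuli to simulate (default all six).
#' @return List with `active` and `reference`, each a list of subjects
#'   (`meta` + `recordings`) directly consumable by [feature_table()].
#' @export
simulate_cohort <- function(spec, td_profile = writer_profile(),
                            dys_profile = graphomotor::dys_profile(),
                            stimuli = GRAPHO_STIMULI) {
  set.seed(spec$seed)
  draw_group <- function(n, group, prefix, profile, origin) {
    if (n == 0) return(list())
    ages <- round(stats::runif(n, spec$age_range_days[1],
                               spec$age_range_days[2]))
    fp <- if (group == "DYS") spec$female_prop[["DYS"]] else
      spec$female_prop[["TD"]]
    lp <- if (group == "DYS") spec$left_prop[["DYS"]] else
      spec$left_prop[["TD"]]
    genders <- ifelse(stats::runif(n) < fp, "F", "M")
    lats <- ifelse(stats::runif(n) < lp, "left", "right")
    seeds <- sample.int(2^20, n)
    lapply(seq_len(n), function(i)
      simulate_subject(sprintf("%s%03d", prefix, i), group, origin,
                       ages[i], genders[i], lats[i], profile, stimuli,
                       seeds[i] * 64L))
  }
  active <- c(draw_group(spec$n_td, "TD", "TD", td_profile, "school"),
              draw_group(spec$n_dys, "DYS", "DYS", dys_profile, "hospital"))
  reference <- draw_group(spec$n_reference, "TD", "REF", td_profile,
                          "school")
  list(active = active, reference = reference)
}

#' Simulate a feature table with injected group effects
#'
#' Subject-by-feature Gaussian table using the canonical registry names:
#' every feature is standard normal noise except `n_effect` randomly
#' chosen ones, which are shifted by `d` standard deviations in the DYS
#' group (a standardized effect size of `d`). This is the test bed for
#' selector-recovery and permutation-null experiments at the
#' feature-table level.
#'
#' @param n_td,n_dys Group sizes.
#' @param n_effect Number of discriminative features (default 10).
#' @param d Standardized effect size (default 1.2).
#' @param seed Integer seed.
#' @return List with `x` (matrix, 345 registry columns), `y` (factor
#'   TD/DYS) and `effect_features` (the shifted feature names).
#' @export
simulate_feature_table <- function(n_td = 43, n_dys = 43, n_effect = 10,
                                   d = 1.2, seed = 0) {
  set.seed(seed)
  reg <- feature_registry()
  p <- nrow(reg)
  n <- n_td + n_dys
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, reg$name))
  y <- factor(rep(c("TD", "DYS"), c(n_td, n_dys)), levels = c("TD", "DYS"))
  effect <- sample(reg$name, n_effect)
  x[y == "DYS", effect] <- x[y == "DYS", effect] + d
  list(x = x, y = y, effect_features = effect)
}
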