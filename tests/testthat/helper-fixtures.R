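# Shared fixtures: all built in code at test time.

# a noise-free writer: template-exact traces
quiet_profile <- function(...) {
  writer_profile(tremor_amp = 0, lift_rate = 0, stop_rate = 0,
                 backtrack_prob = 0, loop_cv = 0, ...)
}

# minimal hand-built recording from coordinate vectors
make_rec <- function(x, y, pen = rep(TRUE, length(x)), rate = 200,
                     stimulus = "circuit1", meta = NULL) {
  n <- length(x)
  recording(stimulus,
            data.frame(t = (seq_len(n) - 1) / rate, x = x, y = y,
                       z = ifelse(pen, 0, 3), pen_down = pen),
            sampling_rate = rate, meta = meta)
}

# straight-line stroke at constant speed v (mm/s), duration secs
line_stroke <- function(v = 20, duration = 1, rate = 200, y0 = 50) {
  n <- round(duration * rate) + 1
  data.frame(t = (seq_len(n) - 1) / rate,
             x = v * (seq_len(n) - 1) / rate, y = rep(y0, n),
             z = 0, pen_down = TRUE)
}

# random valid recording for round-trip tests
random_recording <- function(n = 1000, rate = 200) {
  pen <- stats::runif(n) > 0.2
  pen[sample(n, 3)] <- TRUE     # guarantee pen-down
  make_rec(x = round(stats::runif(n, 0, 200), 4),
           y = round(stats::runif(n, 0, 200), 4),
           pen = pen, rate = rate,
           meta = subject_meta("S1", 3000, "F", "right", "TD", "school"))
}
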