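# Canonical feature registry. The registry is the single source of truth
# for feature names and ordering: 47 general features per stimulus plus
# stimulus-specific features (17 + 9 + 5 + 12 + 12 + 8 = 63), for a total
# of 6 * 47 + 63 = 345. Full column names are "<stimulus>.<feature>".

general_feature_names <- function() {
  c(# stroke / lift timing
    "duration", "writing_time", "air_paper_ratio", "n_strokes",
    "stroke_duration_mean", "stroke_duration_median", "stroke_duration_max",
    "lift_duration_mean", "lift_duration_median", "lift_duration_max",
    # kinematic aggregates (pen-down)
    "low_velocity_count", "low_velocity_duration", "low_velocity_length",
    "velocity_mean", "velocity_median", "velocity_max", "velocity_std",
    "average_normalized_jerk", "abnormal_stop_count", "abnormal_stop_duration",
    "velocity_peak_count", "velocity_peak_std", "snvpd",
    # trajectory signal quality
    "snr_x", "snr_y",
    # global order-2 Renyi entropy of the step distribution
    "re2_x", "re2_y", "re2_xy",
    # per-stroke Renyi entropy on standardized, normalized strokes
    "re2_stroke_mean_x", "re2_stroke_std_x",
    "re2_stroke_mean_y", "re2_stroke_std_y",
    "re2_stroke_mean_xy", "re2_stroke_std_xy",
    # path statistics and in-air counterparts
    "path_length", "path_length_x", "path_length_y",
    "extent_x", "extent_y",
    "n_lifts", "air_path_length", "air_velocity_mean", "air_velocity_max",
    "stroke_length_mean", "stroke_length_median", "stroke_length_max",
    "lift_gap_mean")
}

specific_feature_names <- function(stimulus_id) {
  switch(stimulus_id,
    circuit1 = c(
      as.vector(outer(paste0("line", 1:3),
                      c("mse", "n_strokes", "duration", "backtracks",
                        "completion_first_lift"),
                      paste, sep = "_")),
      "slope_std", "end_start_gap_mean"),
    circuit2 = c("mse_long", "mse_short", "slope_std_long", "slope_std_short",
                 "completion_first_lift", "lifts_off_turn",
                 "quality_mean", "quality_std", "end_start_gap_mean"),
    circuit3 = c("mse_oval", "direction_changes", "completion_first_lift",
                 "oval_re2", "end_start_gap_mean"),
    shapes1 = c(paste0(c("vline", "hline", "sline", "circle"), "_duration"),
                paste0(c("vline", "hline", "sline", "circle"), "_path_length"),
                "curvature_index", "circle_diameter_h", "circle_diameter_v",
                "circle_diameter_ratio"),
    shapes2 = c(paste0(c("triangle", "plus", "square", "cross"), "_duration"),
                paste0(c("triangle", "plus", "square", "cross"),
                       "_path_length"),
                "triangle_corner_perimeter", "square_corner_perimeter",
                "plus_segment_ratio", "cross_segment_ratio"),
    loops = c("n_loops_up", "n_loops_down", "n_loops_total",
              "direction_changes", "loop_width_std", "loop_height_std",
              "loop_length_ratio", "link_height"),
    stop("unknown stimulus: ", stimulus_id, call. = FALSE))
}

#' The canonical feature registry
#'
#' Enumerates every feature the extractor produces: 47 general features for
#' each of the six stimuli plus the stimulus-specific features (Circuit 1:
#' 17, Circuit 2: 9, Circuit 3: 5, Shapes 1: 12, Shapes 2: 12, The Loops:
#' 8), 345 in total. Feature-table columns follow this order exactly;
#' downstream tie-breaks ("canonical order") refer to it.
#'
#' @return Data frame with columns `stimulus`, `feature`, `name`
#'   (`"<stimulus>.<feature>"`), and `kind` (`"general"` or `"specific"`).
#' @export
feature_registry <- function() {
  rows <- lapply(GRAPHO_STIMULI, function(st) {
    rbind(data.frame(stimulus = st, feature = general_feature_names(),
                     kind = "general"),
          data.frame(stimulus = st, feature = specific_feature_names(st),
                     kind = "specific"))
  })
  reg <- do.call(rbind, rows)
  reg$name <- paste(reg$stimulus, reg$feature, sep = ".")
  reg[c("stimulus", "feature", "name", "kind")]
}
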