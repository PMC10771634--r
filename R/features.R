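## The 61-feature TUG profile.
##
## One feature vector per recording: the total TUG duration, duration and
## vertical velocity of the two transfers, duration and velocity of the
## turn, walking duration, and 54 walking features - gait velocity,
## mean/variability/median triples for 16 step/stride quantities, and step
## and stride counts and frequencies. Variability is the coefficient of
## variation (SD/mean x 100); symmetry and regularity use the similarity
## index 1 - |xR - xL| / max(xR, xL).

TRIPLE_QUANTITIES <- c(
  "stance_time", "swing_time", "double_support_time", "single_support_time",
  "step_length", "step_time", "step_velocity", "step_width", "step_height",
  "step_length_symmetry", "step_time_symmetry",
  "stride_time", "stride_length", "stride_velocity",
  "stride_length_regularity", "stride_time_regularity")

#' Canonical names of the 61 TUG features
#'
#' @return Character vector of length 61, in canonical order (the column
#'   order of feature tables produced by this package).
#' @export
feature_names <- function() {
  c("tug_duration_s",
    "sit_to_stand_duration_s", "sit_to_stand_vertical_velocity_mps",
    "walking_duration_s",
    "turning_duration_s", "turning_velocity_mps",
    "stand_to_sit_duration_s", "stand_to_sit_vertical_velocity_mps",
    "gait_velocity_mps",
    as.vector(t(outer(TRIPLE_QUANTITIES, c("mean", "variability", "median"),
                      paste, sep = "_"))),
    "step_number", "step_frequency_spm",
    "stride_number", "stride_frequency_spm")
}

#' Names of the features derived from the walking subtask
#'
#' @return Character vector of the 54 walking-derived feature names
#'   (walking duration, gait velocity, the 16 triples, counts and
#'   frequencies).
#' @export
walking_feature_names <- function() {
  setdiff(feature_names(),
          c("tug_duration_s", "sit_to_stand_duration_s",
            "sit_to_stand_vertical_velocity_mps",
            "turning_duration_s", "turning_velocity_mps",
            "stand_to_sit_duration_s", "stand_to_sit_vertical_velocity_mps"))
}

#' Total TUG duration
#'
#' Total number of recorded frames over the recording rate.
#'
#' @param frame_count Number of recorded frames (>= 1).
#' @param frame_rate Frames per second (> 0).
#' @return Duration in seconds.
#' @export
#' @examples
#' tug_duration(300, 20)  # 15 s
tug_duration <- function(frame_count, frame_rate) {
  if (frame_rate <= 0) stop_parameter("frame_rate must be positive")
  if (frame_count < 1) stop_parameter("frame_count must be >= 1")
  frame_count / frame_rate
}

#' Vertical velocity of a transfer
#'
#' Rate of change of the shoulder-center height between the start and end of
#' a sit-to-stand or stand-to-sit transfer; signed (negative for descents).
#'
#' @param y_start,y_end Shoulder-center height (m) at start and end.
#' @param t_start,t_end Start and end times (s), \code{t_end > t_start}.
#' @return Velocity in m/s.
#' @export
vertical_velocity <- function(y_start, y_end, t_start, t_end) {
  if (t_end <= t_start) stop_parameter("t_end must exceed t_start")
  (y_end - y_start) / (t_end - t_start)
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, as a percentage.
#'
#' @param values Numeric vector with at least 2 values and non-zero mean.
#' @return CoV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4))  # 47.14%
coefficient_of_variation <- function(values) {
  if (length(values) < 2)
    tug_stop("tug_length_error", "CoV requires at least 2 values")
  m <- mean(values)
  if (abs(m) < .Machine$double.eps * 100)
    tug_stop("tug_undefined_cov_error", "CoV undefined for zero-mean values")
  stats::sd(values) / m * 100
}

#' Similarity index of paired gait quantities
#'
#' \eqn{SI = 1 - |x_R - x_L| / \max(x_R, x_L)}, in [0, 1]; 1 for identical
#' operands. Used for step symmetry (right vs. left step of one stride) and
#' stride regularity (consecutive same-foot strides).
#'
#' @param x_right,x_left Positive paired quantities.
#' @return Unitless index in [0, 1].
#' @export
similarity_index <- function(x_right, x_left) {
  if (any(x_right <= 0) || any(x_left <= 0))
    stop_parameter("similarity_index requires positive operands")
  1 - abs(x_right - x_left) / pmax(x_right, x_left)
}

triple <- function(name, values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    tug_stop("tug_feature_error",
             "insufficient events to compute %s (need >= 2, got %d)",
             name, length(values))
  out <- c(mean(values), coefficient_of_variation(values),
           stats::median(values))
  names(out) <- paste(name, c("mean", "variability", "median"), sep = "_")
  out
}

horizontal_path_length <- function(rec, idx) {
  dx <- diff(rec$xyz[idx, "SpineBase", "x"])
  dz <- diff(rec$xyz[idx, "SpineBase", "z"])
  sum(sqrt(dx^2 + dz^2))
}

# similarity series of consecutive opposite-foot step pairs
step_pair_similarity <- function(steps, column) {
  vals <- unlist(lapply(split(steps, steps$leg), function(st) {
    if (nrow(st) < 2) return(numeric(0))
    v <- st[[column]]
    keep <- which(st$leading_foot[-nrow(st)] != st$leading_foot[-1])
    vapply(keep, function(i) {
      a <- v[i]; b <- v[i + 1L]
      if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(NA_real_)
      similarity_index(a, b)
    }, numeric(1))
  }))
  vals[is.finite(vals)]
}

# similarity series of consecutive same-foot strides
stride_regularity_series <- function(cycles, column) {
  vals <- unlist(lapply(split(cycles, list(cycles$leg, cycles$foot)),
                        function(cy) {
    if (nrow(cy) < 2) return(numeric(0))
    v <- cy[[column]][order(cy$start_s)]
    vapply(seq_len(length(v) - 1L), function(i) {
      if (!is.finite(v[i]) || !is.finite(v[i + 1]) ||
          v[i] <= 0 || v[i + 1] <= 0) return(NA_real_)
      similarity_index(v[i], v[i + 1])
    }, numeric(1))
  }))
  vals[is.finite(vals)]
}

#' Extract the 61-feature TUG profile of one recording
#'
#' @param rec A filtered, quality-passed \code{\link{skeletal_recording}}.
#' @param seg Its \code{\link{segment_tug}} segmentation; computed when
#'   omitted.
#' @return Named numeric vector with exactly the 61
#'   \code{\link{feature_names}} entries. Transfer vertical velocities are
#'   stored as magnitudes; units are seconds, m/s, cm, cm/s, m, percent and
#'   counts/minute as indicated by the name suffixes.
#' @export
#' @examples
#' sim <- generate_recording(tug_profile(), seed = 3)
#' fv <- extract_features(filter_recording(sim$recording))
#' length(fv)  # 61
extract_features <- function(rec, seg = NULL) {
  if (is.null(seg)) seg <- segment_tug(rec)
  fs <- rec$frame_rate
  y <- rec$xyz[, "SpineShoulder", "y"]

  phases <- detect_foot_phases(rec, seg)
  steps <- detect_steps(rec, seg)
  cycles <- build_gait_cycles(phases, steps)
  if (nrow(cycles) < 2)
    tug_stop("tug_feature_error",
             "need at least 2 gait cycles, found %d", nrow(cycles))

  sts <- segment_of(seg, "sit_to_stand")
  turn <- segment_of(seg, "turning")
  st2 <- segment_of(seg, "stand_to_sit")
  walks <- walking_segments(seg)
  walk_dur <- sum(walks$end_s - walks$start_s)
  walk_idx <- unlist(lapply(seq_len(nrow(walks)),
                            function(i) segment_idx(walks[i, ])))

  seg_vv <- function(s) {
    i0 <- s$start_frame + 1L; i1 <- s$end_frame
    abs(vertical_velocity(y[i0], y[i1], s$start_s, s$end_s))
  }

  fv <- c(
    tug_duration_s = tug_duration(n_frames(rec), fs),
    sit_to_stand_duration_s = sts$end_s - sts$start_s,
    sit_to_stand_vertical_velocity_mps = seg_vv(sts),
    walking_duration_s = walk_dur,
    turning_duration_s = turn$end_s - turn$start_s,
    turning_velocity_mps =
      horizontal_path_length(rec, segment_idx(turn)) /
        (turn$end_s - turn$start_s),
    stand_to_sit_duration_s = st2$end_s - st2$start_s,
    stand_to_sit_vertical_velocity_mps = seg_vv(st2),
    gait_velocity_mps = horizontal_path_length(rec, walk_idx) / walk_dur)

  stance <- cycles$stance_s
  swing <- cycles$swing_s
  fv <- c(fv,
    triple("stance_time", stance),
    triple("swing_time", swing),
    triple("double_support_time", cycles$double_support_s),
    triple("single_support_time", cycles$single_support_s),
    triple("step_length", steps$length_cm),
    triple("step_time", steps$duration_s),
    triple("step_velocity", steps$velocity_cmps),
    triple("step_width", steps$width_m),
    triple("step_height", steps$height_m),
    triple("step_length_symmetry", step_pair_similarity(steps, "length_cm")),
    triple("step_time_symmetry", step_pair_similarity(steps, "duration_s")),
    triple("stride_time", cycles$stride_time_s),
    triple("stride_length", cycles$stride_length_cm),
    triple("stride_velocity", cycles$stride_velocity_cmps),
    triple("stride_length_regularity",
           stride_regularity_series(cycles, "stride_length_cm")),
    triple("stride_time_regularity",
           stride_regularity_series(cycles, "stride_time_s")))

  fv <- c(fv,
    step_number = nrow(steps),
    step_frequency_spm = nrow(steps) / walk_dur * 60,
    stride_number = nrow(cycles),
    stride_frequency_spm = nrow(cycles) / walk_dur * 60)

  stopifnot(identical(names(fv), feature_names()))
  class(fv) <- c("tug_features", class(fv))
  fv
}

#' @export
print.tug_features <- function(x, ...) {
  cat("<tug_features> 61-feature TUG profile\n")
  print(round(unclass(x), 3))
  invisible(x)
}
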