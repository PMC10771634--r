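## Low-pass preprocessing and automated quality screening.
##
## Joint signals are filtered with a 6th-order Butterworth low-pass at 3 Hz,
## applied forward and backward (zero phase, effective 12th-order magnitude)
## so that event times are not shifted. Recordings whose filtered right-ankle
## depth signal still shows abrupt transitions are screened out, automating
## the visual rejection step of offline gait pipelines.

#' Low-pass filter specification
#'
#' @param order Butterworth order of the one-pass design (default 6); the
#'   forward-backward application squares the magnitude response.
#' @param cutoff_hz Cut-off frequency in Hz (default 3); must be below the
#'   Nyquist frequency.
#' @param frame_rate_hz Sampling rate in Hz.
#' @return A \code{filter_spec} list.
#' @export
filter_spec <- function(order = 6, cutoff_hz = 3, frame_rate_hz = 20) {
  if (order < 1) stop_parameter("order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= frame_rate_hz / 2)
    stop_parameter("cutoff_hz must lie in (0, frame_rate/2); got %g at %g fps",
                   cutoff_hz, frame_rate_hz)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 frame_rate_hz = frame_rate_hz), class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the Butterworth design of \code{spec} forward and backward, so the
#' output has no group delay, unit DC gain and an effective magnitude
#' response of twice the design order. Both ends are extended by
#' odd-reflection padding long enough for the filter's start-up transient
#' (set by its slowest pole) to decay below 1e-11 before the retained
#' samples begin.
#'
#' @param x Numeric signal; must be longer than \code{3 * order}.
#' @param spec A \code{\link{filter_spec}}.
#' @return Filtered signal of the same length.
#' @export
#' @examples
#' lowpass_filter(sin(2 * pi * 0.5 * (0:99) / 20), filter_spec())
lowpass_filter <- function(x, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop_parameter("spec must be a filter_spec")
  n <- length(x)
  if (n <= 3L * spec$order)
    tug_stop("tug_length_error",
             "signal length %d too short for order-%d filtering", n, spec$order)
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$frame_rate_hz / 2),
                       type = "low")
  r_max <- max(Mod(polyroot(rev(bf$a))))
  pad <- max(3L * (spec$order + 1L),
             ceiling(log(1e-11) / log(min(r_max, 1 - 1e-9))))
  pad <- min(pad, n - 1L)
  # odd (point-reflected) extension keeps the extended signal continuous in
  # value and slope at the joins
  head_ext <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  ext <- c(head_ext, x, tail_ext)
  y <- signal::filter(bf, ext)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[seq(pad + 1L, pad + n)]
}

# Squared (forward-backward) magnitude response of the digital Butterworth
# design at frequency f_hz; the bilinear transform prewarps the axis.
butter_zero_phase_gain <- function(f_hz, spec = filter_spec()) {
  r <- tan(pi * f_hz / spec$frame_rate_hz) /
    tan(pi * spec$cutoff_hz / spec$frame_rate_hz)
  1 / (1 + r^(2 * spec$order))
}

#' Filter every joint-axis series of a recording
#'
#' @param rec A \code{\link{skeletal_recording}}.
#' @param spec A \code{\link{filter_spec}}; its sampling rate is taken from
#'   the recording.
#' @return A recording with all 75 joint-axis series filtered independently;
#'   metadata preserved.
#' @export
filter_recording <- function(rec, spec = NULL) {
  if (is.null(spec))
    spec <- filter_spec(frame_rate_hz = rec$frame_rate)
  else
    spec <- filter_spec(spec$order, spec$cutoff_hz, rec$frame_rate)
  xyz <- rec$xyz
  for (j in seq_len(dim(xyz)[2]))
    for (a in 1:3)
      xyz[, j, a] <- lowpass_filter(xyz[, j, a], spec)
  out <- skeletal_recording(xyz, frame_rate = rec$frame_rate,
                            subject = rec$subject)
  attr(out, "ground_truth") <- attr(rec, "ground_truth")
  attr(out, "filtered") <- TRUE
  out
}

#' Screen a filtered recording for residual signal artifacts
#'
#' Flags frame intervals where the discrete derivative of the right-ankle
#' depth (z) signal exceeds \code{jump_threshold_mps}. Elderly gait keeps
#' ankle speeds well below 3 m/s, so surviving excursions indicate tracking
#' artifacts that the low-pass stage could not remove.
#'
#' @param rec A filtered \code{\link{skeletal_recording}}.
#' @param jump_threshold_mps Rejection threshold in m/s (default 3).
#' @return A \code{quality_report} list with fields \code{pass},
#'   \code{offending_intervals} (data frame of 0-based frame intervals),
#'   \code{max_jump_mps} and \code{criterion}.
#' @export
screen_quality <- function(rec, jump_threshold_mps = 3) {
  z <- rec$xyz[, "AnkleRight", "z"]
  speed <- abs(diff(z)) * rec$frame_rate
  bad <- speed > jump_threshold_mps
  intervals <- if (any(bad)) {
    runs <- logical_runs(bad)
    # derivative sample i spans frames (i-1, i) in 0-based indexing
    data.frame(start_frame = runs$start - 1L, end_frame = runs$end + 1L)
  } else {
    data.frame(start_frame = integer(0), end_frame = integer(0))
  }
  structure(list(pass = nrow(intervals) == 0L,
                 offending_intervals = intervals,
                 max_jump_mps = max(speed),
                 criterion = list(signal = "AnkleRight.z",
                                  jump_threshold_mps = jump_threshold_mps)),
            class = "quality_report")
}
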