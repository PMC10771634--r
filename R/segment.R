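## Subtask segmentation.
##
## The five TUG phases are recovered from three detectors: shoulder-center
## height (sit-to-stand and stand-to-sit transfers), and the lateral
## inter-shoulder distance (turning). The two walking segments are the spans
## between those, so the five segments tile the test.
##
## Frame conventions: segments are half-open [start_frame, end_frame) with
## 0-based frames; times are frame / frame_rate.

PLATEAU_VEL_MPS <- 0.05   # |dy/dt| below this counts as plateau
PLATEAU_MIN_S <- 0.5      # minimum plateau duration
RISE_MIN_M <- 0.10        # minimum seated -> standing shoulder rise

#' Trunk inclination angle series
#'
#' The angle between the hip-center (SpineBase) to shoulder-center
#' (SpineShoulder) vector and the horizontal plane through the hip:
#' \eqn{\alpha = \arcsin(\Delta y / \lVert v \rVert)} in degrees, 90 for a
#' vertical trunk, 0 for a horizontal one.
#'
#' @param rec A \code{\link{skeletal_recording}}.
#' @return Data frame with columns \code{time} and \code{alpha_deg}.
#' @export
trunk_angle <- function(rec) {
  v <- rec$xyz[, "SpineShoulder", ] - rec$xyz[, "SpineBase", ]
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-9))
    stop_segmentation("degenerate pose: zero-length trunk vector at frame %d",
                      which(nrm < 1e-9)[1] - 1L)
  data.frame(time = frame_times(rec),
             alpha_deg = asin(pmin(pmax(v[, "y"] / nrm, -1), 1)) * 180 / pi)
}

# Plateau runs of a signal: contiguous frames whose smoothed derivative
# magnitude stays below PLATEAU_VEL_MPS for at least PLATEAU_MIN_S.
smooth_speed <- function(y, fs) {
  v <- c(0, diff(y)) * fs
  abs(moving_average(v, max(3L, round(fs / 4))))
}

plateau_runs <- function(y, fs) {
  mask <- smooth_speed(y, fs) < PLATEAU_VEL_MPS
  # bridge isolated excursions shorter than 3 frames
  gaps <- logical_runs(!mask)
  if (nrow(gaps) > 0) {
    short <- gaps[gaps$end - gaps$start + 1L <= 3L &
                    gaps$start > 1L & gaps$end < length(y), , drop = FALSE]
    for (i in seq_len(nrow(short))) mask[short$start[i]:short$end[i]] <- TRUE
  }
  runs <- logical_runs(mask)
  runs <- runs[runs$end - runs$start + 1L >= round(PLATEAU_MIN_S * fs), ,
               drop = FALSE]
  if (nrow(runs) > 0)
    runs$level <- vapply(seq_len(nrow(runs)), function(i)
      stats::median(y[runs$start[i]:runs$end[i]]), numeric(1))
  runs
}

# Refine the departure time from a plateau. A smooth transfer leaves its
# plateau with (near) zero velocity, so the displacement from the plateau
# level grows quadratically in time; the crossing times t1, t2 of two
# displacement thresholds with d2 = 4 d1 then satisfy t0 = 2 t1 - t2.
# `y` is the signal, `level` the plateau level, and the search runs over
# 1-based frames [from, to]. Returns a (possibly fractional) frame index.
refine_departure <- function(y, level, from, to, fs,
                             d1 = 0.012, d2 = 0.048) {
  if (to <= from + 4L) return(from)
  dev <- abs(y[from:to] - level)
  n <- length(dev)
  # main flank: first sustained crossing of the outer threshold; the inner
  # crossing is taken on the same flank (walking back to the nearest frame
  # below d1) so that filter-overshoot bumps near the plateau are ignored
  ok <- dev[seq_len(n - 2L)] >= d2 & dev[seq(2L, n - 1L)] >= d2 &
    dev[seq(3L, n)] >= d2
  i2 <- which(ok)[1]
  if (is.na(i2)) return(from)
  c2 <- if (i2 == 1L || dev[i2] <= dev[i2 - 1L]) i2 else
    i2 - 1 + (d2 - dev[i2 - 1L]) / (dev[i2] - dev[i2 - 1L])
  j <- which(dev[seq_len(i2)] < d1)
  if (length(j) == 0) return(from)
  j <- max(j)
  c1_up <- if (j == i2 || dev[j + 1L] <= dev[j]) j else
    j + (d1 - dev[j]) / (dev[j + 1L] - dev[j])
  # first sustained crossing of d1; averaging it with the last-below-d1
  # crossing cancels their opposite noise biases on slow flanks
  ok1 <- dev[seq_len(n - 2L)] >= d1 & dev[seq(2L, n - 1L)] >= d1 &
    dev[seq(3L, n)] >= d1
  i1 <- which(ok1)[1]
  c1_lo <- if (is.na(i1)) c1_up else {
    if (i1 == 1L || dev[i1] <= dev[i1 - 1L]) i1 else
      i1 - 1 + (d1 - dev[i1 - 1L]) / (dev[i1] - dev[i1 - 1L])
  }
  c1 <- (c1_up + max(c1_lo, c1_up - 5)) / 2
  if (c2 <= c1) return(from)
  onset <- from - 1 + 2 * c1 - c2
  as.integer(round(min(max(onset, from - fs / 2, 1), from - 1 + c1)))
}

# Mirror of refine_departure: the time a signal settles onto a plateau.
refine_arrival <- function(y, level, from, to, fs) {
  n <- length(y)
  n + 1L - refine_departure(rev(y), level, n + 1L - to, n + 1L - from, fs)
}

make_segment <- function(label, start_1b, end_1b, fs) {
  # start_1b: 1-based first frame; end_1b: 1-based first frame AFTER the
  # segment. Stored 0-based, half-open.
  data.frame(label = label, start_frame = start_1b - 1L,
             end_frame = end_1b - 1L,
             start_s = (start_1b - 1L) / fs, end_s = (end_1b - 1L) / fs,
             stringsAsFactors = FALSE)
}

#' Detect the sit-to-stand transfer
#'
#' The shoulder-center height stays on a seated plateau, dips through a local
#' minimum as the trunk flexes forward, then rises to the standing plateau.
#' The segment runs from the last seated-plateau frame to the first
#' standing-plateau frame.
#'
#' @param rec A filtered \code{\link{skeletal_recording}} that begins seated.
#' @return One-row segment data frame (label, frames, times).
#' @export
detect_sit_to_stand <- function(rec) {
  y <- rec$xyz[, "SpineShoulder", "y"]
  fs <- rec$frame_rate
  runs <- plateau_runs(y, fs)
  if (nrow(runs) < 2)
    stop_segmentation("sit_to_stand: no seated-to-standing transition found")
  seated <- runs[1, ]
  if (seated$start > round(2 * fs) + 1L)
    stop_segmentation("sit_to_stand: recording does not begin on a seated plateau")
  higher <- which(runs$level > seated$level + RISE_MIN_M &
                    runs$start > seated$end)
  if (length(higher) == 0)
    stop_segmentation("sit_to_stand: no standing plateau above the seated level")
  standing <- runs[higher[1], ]
  start <- refine_departure(y, seated$level, seated$end, standing$start, fs)
  end <- refine_arrival(y, standing$level, start + 1L, standing$start, fs)
  make_segment("sit_to_stand", start, end, fs)
}

#' Detect the stand-to-sit transfer
#'
#' Mirror image of \code{\link{detect_sit_to_stand}}: the shoulder-center
#' height leaves the standing plateau, falls through a local minimum and
#' settles on the final seated plateau.
#'
#' @param rec A filtered \code{\link{skeletal_recording}} that ends seated.
#' @return One-row segment data frame.
#' @export
detect_stand_to_sit <- function(rec) {
  y <- rec$xyz[, "SpineShoulder", "y"]
  fs <- rec$frame_rate
  runs <- plateau_runs(y, fs)
  if (nrow(runs) < 2)
    stop_segmentation("stand_to_sit: no standing-to-seated transition found")
  final <- runs[nrow(runs), ]
  if (final$end < length(y) - round(2 * fs))
    stop_segmentation("stand_to_sit: recording does not end on a seated plateau")
  higher <- which(runs$level > final$level + RISE_MIN_M &
                    runs$end < final$start)
  if (length(higher) == 0)
    stop_segmentation("stand_to_sit: no standing plateau before the final seated one")
  standing <- runs[higher[length(higher)], ]
  start <- refine_departure(y, standing$level, standing$end, final$start, fs)
  end <- refine_arrival(y, final$level, start + 1L, final$start, fs)
  make_segment("stand_to_sit", start, end, fs)
}

#' Detect the turning phase
#'
#' The lateral (x) distance between the two shoulder joints collapses from
#' the full shoulder width to near zero mid-turn and recovers. With a
#' near-constant turning rate the distance follows
#' \eqn{W |\cos(\pi (t - t_0)/T)|}, whose crossings of half the walking
#' median sit at one third and two thirds of the turn, so the segment is
#' extrapolated from the two half-width crossing times around the trough.
#'
#' @param rec A filtered \code{\link{skeletal_recording}} containing one turn.
#' @param trough_fraction Entry/exit threshold as a fraction of the median
#'   inter-shoulder x-distance (default 0.5).
#' @return One-row segment data frame.
#' @export
detect_turning <- function(rec, trough_fraction = 0.5) {
  d <- abs(rec$xyz[, "ShoulderRight", "x"] - rec$xyz[, "ShoulderLeft", "x"])
  fs <- rec$frame_rate
  m <- stats::median(d)
  thr <- trough_fraction * m
  i_min <- which.min(d)
  if (d[i_min] >= thr)
    stop_segmentation("turning: no trough in the inter-shoulder x-distance")
  before <- which(d[seq_len(i_min - 1L)] >= thr)
  after <- which(d[seq(i_min + 1L, length(d))] >= thr) + i_min
  if (length(before) == 0 || length(after) == 0)
    stop_segmentation("turning: trough does not recover on both sides")
  t1 <- max(before)
  t2 <- min(after)
  # sub-frame crossing times by linear interpolation
  c1 <- t1 + (d[t1] - thr) / max(d[t1] - d[t1 + 1L], 1e-9)
  c2 <- t2 - (d[t2] - thr) / max(d[t2] - d[t2 - 1L], 1e-9)
  # |cos| crosses trough_fraction at acos(trough_fraction)/pi of the half
  # period from each end of the turn
  edge <- acos(min(trough_fraction, 1)) / pi
  span <- (c2 - c1) / (1 - 2 * edge)
  mid <- (c1 + c2) / 2
  start <- max(1L, as.integer(round(mid - span / 2)))
  end <- min(length(d) + 1L, as.integer(round(mid + span / 2)) + 1L)
  make_segment("turning", start, end, fs)
}

#' Segment a TUG recording into its five subtasks
#'
#' Runs the three transfer/turn detectors and derives the walking segments
#' as the spans between them: walk-out from sit-to-stand end to turning
#' start, walk-back from turning end to stand-to-sit start. The five
#' segments are ordered, non-overlapping and tile every frame between the
#' start of sit-to-stand and the end of stand-to-sit.
#'
#' @param rec A filtered, quality-passed \code{\link{skeletal_recording}}.
#' @return A \code{tug_segmentation}: a 5-row data frame (label,
#'   start_frame, end_frame, start_s, end_s) in canonical order.
#' @export
#' @examples
#' sim <- generate_recording(tug_profile(), seed = 7)
#' segment_tug(filter_recording(sim$recording))
segment_tug <- function(rec) {
  fs <- rec$frame_rate
  sts <- detect_sit_to_stand(rec)
  turn <- detect_turning(rec)
  st2 <- detect_stand_to_sit(rec)
  if (!(sts$end_frame < turn$start_frame && turn$end_frame < st2$start_frame))
    stop_segmentation(
      "inconsistent phase order: sit_to_stand ends %.2fs, turning [%.2f, %.2f]s, stand_to_sit starts %.2fs",
      sts$end_s, turn$start_s, turn$end_s, st2$start_s)
  walk_out <- make_segment("walk_out", sts$end_frame + 1L,
                           turn$start_frame + 1L, fs)
  walk_back <- make_segment("walk_back", turn$end_frame + 1L,
                            st2$start_frame + 1L, fs)
  seg <- rbind(sts, walk_out, turn, walk_back, st2)
  rownames(seg) <- NULL
  class(seg) <- c("tug_segmentation", "data.frame")
  seg
}

segment_of <- function(seg, label) seg[seg$label == label, , drop = FALSE]

# 1-based frame index range of a segment row
segment_idx <- function(segrow) seq(segrow$start_frame + 1L, segrow$end_frame)
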