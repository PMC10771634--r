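## Gait event detection within the walking segments.
##
## Stance/swing phases come from the numerical derivative of each foot's
## depth (z) signal: a foot on the ground does not move, so frames with a
## small derivative form stance intervals and the remainder swing. Steps are
## the local peaks of the inter-foot sagittal distance signal; strides pair
## consecutive contacts of the same foot.

STANCE_VEL_MPS <- 0.08   # |dz/dt| below this counts as ground contact
STANCE_MIN_S <- 0.1      # minimum phase duration kept after cleanup

walking_segments <- function(seg) {
  seg[seg$label %in% c("walk_out", "walk_back"), , drop = FALSE]
}

#' Detect stance and swing phases of both feet
#'
#' @param rec A filtered \code{\link{skeletal_recording}}.
#' @param seg Its \code{\link{segment_tug}} segmentation (only the walking
#'   segments are analyzed).
#' @return Data frame with one row per phase: \code{leg} ("walk_out" /
#'   "walk_back"), \code{foot}, \code{phase} ("stance"/"swing"),
#'   \code{start_frame}, \code{end_frame} (0-based, half-open),
#'   \code{start_s}, \code{end_s}. Per foot and leg the phases alternate and
#'   tile the walking frames.
#' @export
detect_foot_phases <- function(rec, seg) {
  fs <- rec$frame_rate
  walks <- walking_segments(seg)
  if (nrow(walks) == 0) stop_gait("segmentation contains no walking segments")
  out <- list()
  for (w in seq_len(nrow(walks))) {
    idx <- segment_idx(walks[w, ])
    for (foot in c("left", "right")) {
      jn <- if (foot == "left") "FootLeft" else "FootRight"
      z <- rec$xyz[idx, jn, "z"]
      nz <- length(z)
      # central difference: no half-frame lag on stance/swing transitions
      v <- c(z[2] - z[1], (z[3:nz] - z[seq_len(nz - 2)]) / 2,
             z[nz] - z[nz - 1]) * fs
      stance <- abs(v) < STANCE_VEL_MPS
      # bridge sub-0.15 s excursions: filter ringing around heel strike
      # briefly re-crosses the threshold while the foot is already grounded
      gaps <- logical_runs(!stance)
      if (nrow(gaps) > 0) {
        short <- gaps[gaps$end - gaps$start + 1L <= 3L &
                        gaps$start > 1L & gaps$end < length(stance), ,
                      drop = FALSE]
        for (g in seq_len(nrow(short)))
          stance[short$start[g]:short$end[g]] <- TRUE
      }
      stance <- clean_phase_mask(stance, round(STANCE_MIN_S * fs))
      runs <- rle(stance)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ph <- data.frame(
        leg = walks$label[w], foot = foot,
        phase = ifelse(runs$values, "stance", "swing"),
        start_frame = idx[starts] - 1L,
        end_frame = idx[ends] - 1L + 1L,
        stringsAsFactors = FALSE)
      ph$start_s <- ph$start_frame / fs
      ph$end_s <- ph$end_frame / fs
      out[[length(out) + 1L]] <- ph
    }
  }
  phases <- do.call(rbind, out)
  for (leg in unique(phases$leg)) for (foot in c("left", "right")) {
    k <- phases$leg == leg & phases$foot == foot
    if (sum(phases$phase[k] == "stance") < 2)
      stop_gait("%s/%s: fewer than one full gait cycle detected", leg, foot)
  }
  phases
}

# Remove phase islands shorter than min_len by merging them into their
# neighbours, alternating until stable.
clean_phase_mask <- function(mask, min_len) {
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1L) return(mask)
    short <- which(r$lengths < min_len)
    short <- setdiff(short, c(1L, length(r$lengths)))  # keep edge phases
    if (length(short) == 0L) return(mask)
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mask[starts[i]:ends[i]] <- !r$values[i]
  }
}

#' Detect steps from the inter-foot distance signal
#'
#' One step per local maximum of the sagittal (z) inter-foot distance within
#' each walking segment: at each new foot contact the leading foot is one
#' step length ahead of the trailing one. Step length is the peak distance
#' (cm), width the lateral (x) inter-foot distance at the same peak, height
#' the swing-apex elevation of the stepping foot above its stance baseline,
#' duration the time to the next peak, and velocity length/duration.
#'
#' @param rec A filtered \code{\link{skeletal_recording}}.
#' @param seg Its segmentation.
#' @param min_prominence_m Peak height gate in meters (default 0.05).
#' @param min_step_interval_s Minimum spacing between step peaks (default
#'   0.45 s); suppresses duplicate maxima on noisy double-support plateaus.
#' @return Data frame of step events ordered in time: \code{leg},
#'   \code{time_s}, \code{leading_foot}, \code{length_cm}, \code{width_m},
#'   \code{height_m}, \code{duration_s}, \code{velocity_cmps} (duration and
#'   velocity are \code{NA} for the last step of each walking segment).
#' @export
detect_steps <- function(rec, seg, min_prominence_m = 0.05,
                         min_step_interval_s = 0.45) {
  fs <- rec$frame_rate
  walks <- walking_segments(seg)
  out <- list()
  for (w in seq_len(nrow(walks))) {
    # extend slightly past the segment end: the final foot contact lands at
    # the walking/turn boundary and its distance peak straddles it
    idx <- segment_idx(walks[w, ])
    ext <- round(0.3 * fs)
    idx <- c(idx, seq_len(ext) + idx[length(idx)])
    idx <- idx[idx <= n_frames(rec)]
    zl <- rec$xyz[idx, "FootLeft", "z"]
    zr <- rec$xyz[idx, "FootRight", "z"]
    dist <- abs(zr - zl)
    pk <- pracma::findpeaks(dist, minpeakheight = min_prominence_m,
                            minpeakdistance = max(2L, round(min_step_interval_s * fs)))
    if (is.null(pk) || nrow(pk) < 2)
      stop_gait("%s: fewer than 2 step peaks detected", walks$label[w])
    pk <- pk[order(pk[, 2]), , drop = FALSE]
    peak_i <- pk[, 2]
    # leading foot: the one further along the direction of travel
    travel <- sign(stats::median(diff((zl + zr) / 2)))
    lead <- ifelse(sign(zr[peak_i] - zl[peak_i]) == travel, "right", "left")
    height <- vapply(seq_along(peak_i), function(s) {
      jn <- if (lead[s] == "right") "FootRight" else "FootLeft"
      lo <- if (s == 1L) 1L else peak_i[s - 1L]
      y <- rec$xyz[idx[lo:peak_i[s]], jn, "y"]
      max(y) - stats::quantile(y, 0.1, names = FALSE)
    }, numeric(1))
    st <- data.frame(
      leg = walks$label[w],
      time_s = (idx[peak_i] - 1L) / fs,
      leading_foot = lead,
      length_cm = 100 * pk[, 1],
      width_m = abs(rec$xyz[idx[peak_i], "FootRight", "x"] -
                      rec$xyz[idx[peak_i], "FootLeft", "x"]),
      height_m = height,
      stringsAsFactors = FALSE)
    st$duration_s <- c(diff(st$time_s), NA_real_)
    st$velocity_cmps <- st$length_cm / st$duration_s
    out[[length(out) + 1L]] <- st
  }
  do.call(rbind, out)
}

#' Assemble gait cycles from foot phases and steps
#'
#' One cycle per consecutive pair of same-foot stance onsets within one
#' walking segment. Stance/swing are that foot's phases, single support is
#' the contralateral swing time within the cycle, double support the overlap
#' of both feet's stances, stride length the sum of the two constituent step
#' lengths and stride velocity stride length over stride time.
#'
#' @param phases From \code{\link{detect_foot_phases}}.
#' @param steps From \code{\link{detect_steps}}.
#' @return Data frame with one row per gait cycle: \code{leg}, \code{foot},
#'   \code{start_s}, \code{stride_time_s}, \code{stance_s}, \code{swing_s},
#'   \code{single_support_s}, \code{double_support_s},
#'   \code{stride_length_cm}, \code{stride_velocity_cmps}.
#' @export
build_gait_cycles <- function(phases, steps) {
  out <- list()
  for (leg in unique(phases$leg)) {
    ph <- phases[phases$leg == leg, , drop = FALSE]
    st <- steps[steps$leg == leg, , drop = FALSE]
    for (foot in c("left", "right")) {
      own <- ph[ph$foot == foot, , drop = FALSE]
      other <- ph[ph$foot != foot, , drop = FALSE]
      onsets <- own$start_s[own$phase == "stance"]
      # drop the initial standing stance that starts with the segment
      if (length(onsets) > 0 && onsets[1] <= min(own$start_s) + 1e-9)
        onsets <- onsets[-1]
      if (length(onsets) < 2) next
      for (ci in seq_len(length(onsets) - 1L)) {
        t0 <- onsets[ci]; t1 <- onsets[ci + 1L]
        stance_s <- interval_overlap(own[own$phase == "stance", ], t0, t1)
        swing_s <- interval_overlap(own[own$phase == "swing", ], t0, t1)
        single_s <- interval_overlap(other[other$phase == "swing", ], t0, t1)
        double_s <- stance_overlap(own, other, t0, t1)
        in_cycle <- st$time_s >= t0 - 1e-9 & st$time_s < t1 - 1e-9
        stride_len <- if (sum(in_cycle) > 0) sum(st$length_cm[in_cycle])
                      else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          leg = leg, foot = foot, start_s = t0,
          stride_time_s = t1 - t0, stance_s = stance_s, swing_s = swing_s,
          single_support_s = single_s, double_support_s = double_s,
          stride_length_cm = stride_len,
          stride_velocity_cmps = stride_len / (t1 - t0),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) stop_gait("no complete gait cycles found")
  cycles <- do.call(rbind, out)
  cycles[order(cycles$start_s), , drop = FALSE]
}

# total time the intervals [start_s, end_s) of `ph` overlap [t0, t1)
interval_overlap <- function(ph, t0, t1) {
  if (nrow(ph) == 0) return(0)
  sum(pmax(0, pmin(ph$end_s, t1) - pmax(ph$start_s, t0)))
}

# total time both feet are in stance within [t0, t1)
stance_overlap <- function(own, other, t0, t1) {
  a <- own[own$phase == "stance", , drop = FALSE]
  b <- other[other$phase == "stance", , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$start_s[i], b$start_s[j], t0)
    hi <- min(a$end_s[i], b$end_s[j], t1)
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}
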