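## Skeletal recording data model.
##
## A recording is the per-frame 3-D position (meters, camera space) of the 25
## joints tracked by a Kinect V.2-class depth sensor, sampled at a fixed frame
## rate, plus subject metadata. Coordinate convention: x lateral, y vertical
## (up positive), z depth increasing away from the camera. The camera faces
## the walkway, so z decreases while the subject walks toward it.

#' The 25 tracked skeleton joints
#'
#' Joint names follow the Kinect V.2 skeleton. The "shoulder center" of the
#' clinical-gait literature corresponds to \code{SpineShoulder}, and the "hip"
#' (hip center) to \code{SpineBase}.
#'
#' @return Character vector of the 25 joint names, in canonical order.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight")
}

#' Subject metadata
#'
#' @param subject_id Character scalar, unique within a cohort.
#' @param group Group label: \code{"HC"}, \code{"AD"} or \code{"unknown"}.
#' @param age Age in years (> 0), or \code{NA}.
#' @param gds Geriatric Depression Scale score, 0--15, or \code{NA}.
#' @param sex,height_cm,weight_kg Optional descriptors.
#' @return A \code{subject_meta} list.
#' @export
subject_meta <- function(subject_id, group = "unknown", age = NA_real_,
                         gds = NA_real_, sex = NA_character_,
                         height_cm = NA_real_, weight_kg = NA_real_) {
  group <- match.arg(group, c("HC", "AD", "unknown"))
  if (!is.na(age) && age <= 0) stop_parameter("age must be positive, got %s", age)
  if (!is.na(gds) && (gds < 0 || gds > 15))
    stop_parameter("gds must be within 0-15, got %s", gds)
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = as.numeric(age), gds = as.numeric(gds),
                 sex = as.character(sex), height_cm = as.numeric(height_cm),
                 weight_kg = as.numeric(weight_kg)),
            class = "subject_meta")
}

#' Construct a skeletal recording
#'
#' @param xyz Numeric array \code{[frames, 25, 3]}; the joint dimension must
#'   carry the names of \code{\link{kinect_joints}} and the coordinate
#'   dimension \code{c("x","y","z")}. Units are meters in camera space.
#' @param frame_rate Frames per second (default 20).
#' @param subject A \code{\link{subject_meta}}.
#' @return A \code{skeletal_recording} object.
#' @export
skeletal_recording <- function(xyz, frame_rate = 20, subject = subject_meta("s1")) {
  if (!is.array(xyz) || length(dim(xyz)) != 3L)
    stop_format("xyz must be a [frames, joints, axes] array")
  jn <- dimnames(xyz)[[2]]
  if (is.null(jn)) stop_format("joint dimension must be named")
  missing <- setdiff(kinect_joints(), jn)
  if (length(missing) > 0)
    stop_format("recording is missing joint(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(jn, kinect_joints())
  if (length(extra) > 0)
    stop_format("unknown joint(s): %s", paste(extra, collapse = ", "))
  xyz <- xyz[, kinect_joints(), , drop = FALSE]
  dimnames(xyz)[[3]] <- c("x", "y", "z")
  if (dim(xyz)[1] < 1L) stop_format("recording must contain at least one frame")
  if (!all(is.finite(xyz))) stop_format("coordinates must all be finite")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop_parameter("frame_rate must be a positive scalar")
  if (!inherits(subject, "subject_meta"))
    subject <- do.call(subject_meta, as.list(subject))
  structure(list(xyz = xyz, frame_rate = as.numeric(frame_rate),
                 subject = subject),
            class = "skeletal_recording")
}

#' @export
print.skeletal_recording <- function(x, ...) {
  n <- n_frames(x)
  cat(sprintf("<skeletal_recording> %s [%s]: %d frames @ %g fps (%.2f s)\n",
              x$subject$subject_id, x$subject$group, n, x$frame_rate,
              n / x$frame_rate))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec A \code{skeletal_recording}.
#' @return Integer frame count.
#' @export
n_frames <- function(rec) dim(rec$xyz)[1]

#' Frame timestamps of a recording
#'
#' Frames are indexed from 0; the timestamp of frame \eqn{i} is
#' \eqn{i / \mathrm{frame\ rate}}.
#'
#' @param rec A \code{skeletal_recording}.
#' @return Numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(rec) (seq_len(n_frames(rec)) - 1L) / rec$frame_rate

#' Extract one joint-axis time series
#'
#' @param rec A \code{skeletal_recording}.
#' @param joint One of \code{\link{kinect_joints}}.
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @return Data frame with columns \code{time} (s) and \code{value} (m), one
#'   row per frame.
#' @export
#' @examples
#' rec <- generate_recording(tug_profile(), seed = 1)$recording
#' head(joint_series(rec, "SpineShoulder", "y"))
joint_series <- function(rec, joint, axis = c("x", "y", "z")) {
  if (!joint %in% kinect_joints())
    stop_parameter("unknown joint '%s'", joint)
  if (length(axis) == 1L && !axis %in% c("x", "y", "z"))
    stop_parameter("axis must be one of x, y, z; got '%s'", axis)
  axis <- match.arg(axis)
  data.frame(time = frame_times(rec), value = as.numeric(rec$xyz[, joint, axis]))
}

#' Bundle recordings into a cohort
#'
#' @param recordings List of \code{skeletal_recording} objects with unique
#'   subject ids.
#' @param provenance Free-text source tag.
#' @return A \code{tug_cohort} list.
#' @export
tug_cohort <- function(recordings, provenance = "unspecified") {
  ids <- vapply(recordings, function(r) r$subject$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_parameter("subject ids must be unique; duplicated: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(recordings = recordings, provenance = provenance),
            class = "tug_cohort")
}

#' @export
print.tug_cohort <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$subject$group, character(1))
  cat(sprintf("<tug_cohort> %d recordings (%s) [%s]\n", length(x$recordings),
              paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                    collapse = ", "),
              x$provenance))
  invisible(x)
}
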