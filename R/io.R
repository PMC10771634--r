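## On-disk formats for skeletal TUG recordings.
##
## CSV dialect: long format with header `frame,joint,x,y,z`, frames 0-based,
## joints by name, plus a metadata sidecar `<path>.meta.json` holding
## subject_id, group, age, gds, frame_rate and the optional descriptors.
##
## JSON dialect: a single object {frame_rate, subject, frames} where `frames`
## is a list of {joint: [x, y, z]} maps, one per frame.

meta_sidecar_path <- function(path) paste0(path, ".meta.json")

subject_to_list <- function(s) {
  s <- unclass(s)
  s[!vapply(s, function(v) length(v) == 1L && is.na(v), logical(1))]
}

subject_from_list <- function(l) {
  do.call(subject_meta, l[intersect(names(l), names(formals(subject_meta)))])
}

#' Write a skeletal recording to disk
#'
#' @param rec A validated \code{\link{skeletal_recording}}.
#' @param path Output file path.
#' @param fmt \code{"csv"} (long table plus a \code{<path>.meta.json}
#'   sidecar) or \code{"json"} (single self-contained object).
#' @return The written path, invisibly. Numeric values are stored with at
#'   least 6 significant digits so that a read-back reproduces the recording.
#' @export
write_recording <- function(rec, path, fmt = c("csv", "json")) {
  fmt <- match.arg(fmt)
  if (!inherits(rec, "skeletal_recording"))
    stop_parameter("rec must be a skeletal_recording")
  if (!all(is.finite(rec$xyz)))
    stop_format("recording contains non-finite coordinates; refusing to write")
  if (fmt == "csv") {
    n <- n_frames(rec)
    joints <- kinect_joints()
    df <- data.frame(
      frame = rep(seq_len(n) - 1L, each = length(joints)),
      joint = rep(joints, times = n),
      x = as.vector(t(rec$xyz[, , "x"])),
      y = as.vector(t(rec$xyz[, , "y"])),
      z = as.vector(t(rec$xyz[, , "z"]))
    )
    for (col in c("x", "y", "z")) df[[col]] <- signif(df[[col]], 9)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    meta <- c(subject_to_list(rec$subject), list(frame_rate = rec$frame_rate))
    jsonlite::write_json(meta, meta_sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    frames <- lapply(seq_len(n_frames(rec)), function(i) {
      m <- rec$xyz[i, , , drop = TRUE]
      stats::setNames(lapply(seq_len(nrow(m)), function(j) unname(m[j, ])),
                      rownames(m))
    })
    obj <- list(frame_rate = rec$frame_rate,
                subject = subject_to_list(rec$subject),
                frames = frames)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a skeletal recording from disk
#'
#' @param path File written by \code{\link{write_recording}} (or conforming
#'   to the documented dialect).
#' @param fmt \code{"csv"} or \code{"json"}; defaults to the file extension.
#' @return A validated \code{\link{skeletal_recording}} with frame order
#'   preserved and coordinates in meters.
#' @export
read_recording <- function(path, fmt = c("csv", "json")) {
  if (missing(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("csv", "json")) ext else "csv"
  } else fmt <- match.arg(fmt)
  if (!file.exists(path)) stop_format("no such file: %s", path)
  if (fmt == "csv") read_recording_csv(path) else read_recording_json(path)
}

read_recording_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("unreadable CSV '%s': %s",
                                                 path, conditionMessage(e)))
  if (nrow(df) == 0) stop_format("empty recording file: %s", path)
  need <- c("frame", "joint", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_format("CSV must have columns %s", paste(need, collapse = ","))
  frames <- sort(unique(df$frame))
  if (!identical(frames, seq_along(frames) - 1L) &&
      !isTRUE(all.equal(frames, seq_along(frames) - 1)))
    stop_format("frame index must be contiguous and 0-based")
  # frame order as it appears must be non-decreasing
  if (is.unsorted(df$frame)) stop_format("non-monotone frame index in %s", path)
  joints <- kinect_joints()
  missing <- setdiff(joints, unique(df$joint))
  if (length(missing) > 0)
    stop_format("file is missing joint(s): %s", paste(missing, collapse = ", "))
  n <- length(frames)
  xyz <- array(NA_real_, dim = c(n, length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  fi <- match(df$frame, frames)
  ji <- match(df$joint, joints)
  if (anyNA(ji)) stop_format("unknown joint(s): %s",
                             paste(unique(df$joint[is.na(ji)]), collapse = ", "))
  xyz[cbind(fi, ji, 1L)] <- df$x
  xyz[cbind(fi, ji, 2L)] <- df$y
  xyz[cbind(fi, ji, 3L)] <- df$z
  if (anyNA(xyz)) {
    bad <- joints[unique(which(is.na(xyz), arr.ind = TRUE)[, 2])]
    stop_format("missing joint row(s) for: %s", paste(bad, collapse = ", "))
  }
  mp <- meta_sidecar_path(path)
  frame_rate <- 20
  subject <- subject_meta(tools::file_path_sans_ext(basename(path)))
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(meta$frame_rate)) frame_rate <- meta$frame_rate
    meta$frame_rate <- NULL
    subject <- subject_from_list(meta)
  }
  skeletal_recording(xyz, frame_rate = frame_rate, subject = subject)
}

read_recording_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_format("unreadable JSON '%s': %s",
                                                  path, conditionMessage(e)))
  if (is.null(obj$frames) || length(obj$frames) == 0)
    stop_format("empty recording file: %s", path)
  joints <- kinect_joints()
  n <- length(obj$frames)
  xyz <- array(NA_real_, dim = c(n, length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (i in seq_len(n)) {
    fr <- obj$frames[[i]]
    missing <- setdiff(joints, names(fr))
    if (length(missing) > 0)
      stop_format("frame %d is missing joint(s): %s", i - 1L,
                  paste(missing, collapse = ", "))
    for (j in joints) xyz[i, j, ] <- unlist(fr[[j]])[1:3]
  }
  subject <- if (is.null(obj$subject)) subject_meta("unknown")
             else subject_from_list(lapply(obj$subject, identity))
  frame_rate <- if (is.null(obj$frame_rate)) 20 else obj$frame_rate
  skeletal_recording(xyz, frame_rate = frame_rate, subject = subject)
}

#' Write a cohort to a directory
#'
#' One recording file per subject (named \code{<subject_id>.<fmt>}) plus, when
#' ground truth is attached, one \code{<subject_id>.truth.json}.
#'
#' @param cohort A \code{\link{tug_cohort}}; elements may carry a
#'   \code{ground_truth} attribute as produced by
#'   \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @param fmt Recording dialect, \code{"csv"} or \code{"json"}.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, fmt = c("csv", "json")) {
  fmt <- match.arg(fmt)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    id <- rec$subject$subject_id
    write_recording(rec, file.path(dir, paste0(id, ".", fmt)), fmt = fmt)
    gt <- attr(rec, "ground_truth")
    if (!is.null(gt)) {
      jsonlite::write_json(ground_truth_to_list(gt),
                           file.path(dir, paste0(id, ".truth.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir Directory of recording files written by
#'   \code{\link{write_cohort}}.
#' @return A \code{\link{tug_cohort}}.
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  files <- files[!grepl("\\.meta\\.json$|\\.truth\\.json$", files)]
  if (length(files) == 0) stop_format("no recording files found in %s", dir)
  recs <- lapply(sort(files), read_recording)
  tug_cohort(recs, provenance = dir)
}
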