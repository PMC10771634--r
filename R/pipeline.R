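## End-to-end orchestration: filter -> screen -> segment -> extract ->
## adjust -> select -> classify, with per-stage attrition accounting.

#' Extract the feature table of a whole cohort
#'
#' Filters each recording, screens it for residual artifacts, segments the
#' five subtasks and extracts the 61 features. Failing recordings are
#' dropped and recorded in the attrition table rather than aborting the run.
#'
#' @param cohort A \code{\link{tug_cohort}} or a directory path readable by
#'   \code{\link{read_cohort}}.
#' @param filter A \code{\link{filter_spec}} (rate taken per recording).
#' @param qc_threshold Right-ankle jump threshold in m/s (see
#'   \code{\link{screen_quality}}).
#' @return List with \code{table} (a \code{\link{feature_table}}) and
#'   \code{attrition} (data frame: subject_id, stage, message for each
#'   dropped subject).
#' @export
cohort_features <- function(cohort, filter = filter_spec(),
                            qc_threshold = 3) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  rows <- list(); meta <- list(); attrition <- list()
  for (rec in cohort$recordings) {
    id <- rec$subject$subject_id
    res <- tryCatch({
      frec <- filter_recording(rec, filter)
      qc <- screen_quality(frec, qc_threshold)
      if (!qc$pass)
        tug_stop("tug_quality_error",
                 "failed QC: max right-ankle jump %.2f m/s", qc$max_jump_mps)
      seg <- segment_tug(frec)
      extract_features(frec, seg)
    }, tug_error = function(e) e)
    if (inherits(res, "tug_error")) {
      attrition[[length(attrition) + 1L]] <- data.frame(
        subject_id = id,
        stage = class(res)[1],
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[id]] <- unclass(res)
      meta[[id]] <- rec$subject
    }
  }
  if (length(rows) == 0) stop_parameter("no recording survived extraction")
  tab <- feature_table(
    do.call(rbind, rows),
    group = vapply(meta, `[[`, "", "group"),
    age = vapply(meta, `[[`, 0, "age"),
    gds = vapply(meta, `[[`, 0, "gds"),
    subject_id = names(rows))
  attrition <- if (length(attrition)) do.call(rbind, attrition)
               else data.frame(subject_id = character(0), stage = character(0),
                               message = character(0))
  list(table = tab, attrition = attrition)
}

#' Run the full TUG analysis pipeline
#'
#' Executes filtering, quality screening, segmentation, feature extraction,
#' covariate adjustment, feature selection and cross-validated SVM
#' classification, and returns all stage artifacts plus a run manifest with
#' per-stage subject attrition. Per-subject failures are recorded and the
#' pipeline continues with the survivors, failing only if a class is
#' exhausted.
#'
#' @param cohort A \code{\link{tug_cohort}} or a cohort directory path.
#' @param scheme Cross-validation scheme(s) to run; any of
#'   \code{"five_fold"}, \code{"loso"}.
#' @param seed Integer seed for fold shuffling.
#' @param filter,qc_threshold Preprocessing settings (see
#'   \code{\link{cohort_features}}).
#' @param alpha,corr_threshold,grid,adjust,nested Passed to
#'   \code{\link{select_features}} / \code{\link{cross_validate}}.
#' @return A \code{tug_pipeline_result}: list with \code{table} (raw
#'   features), \code{adjusted} (whole-cohort adjusted features),
#'   \code{selection} (whole-cohort selection on adjusted values),
#'   \code{selection_raw}, \code{cv} (named list of
#'   \code{tug_cv_result}s), and \code{manifest}.
#' @export
run_pipeline <- function(cohort, scheme = "five_fold", seed = 1L,
                         filter = filter_spec(), qc_threshold = 3,
                         alpha = 0.05, corr_threshold = 0.90,
                         grid = hyper_grid(), adjust = TRUE, nested = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  n_in <- length(cohort$recordings)
  ext <- cohort_features(cohort, filter, qc_threshold)
  tab <- ext$table
  if (length(unique(tab$group)) < 2 || any(table(tab$group) < 2))
    stop_parameter("a class was exhausted during extraction")
  adjusted <- ancova_adjust(tab)
  selection <- select_features(adjusted, alpha, corr_threshold)
  selection_raw <- select_features(tab, alpha, corr_threshold)
  cv <- lapply(stats::setNames(scheme, scheme), function(s)
    cross_validate(tab, grid = grid, scheme = s, seed = seed,
                   adjust = adjust, nested = nested, alpha = alpha,
                   corr_threshold = corr_threshold))
  manifest <- list(
    n_subjects_in = n_in,
    n_subjects_analyzed = nrow(tab),
    attrition = ext$attrition,
    groups = as.list(table(tab$group)),
    config = list(filter_order = filter$order, cutoff_hz = filter$cutoff_hz,
                  qc_threshold = qc_threshold, alpha = alpha,
                  corr_threshold = corr_threshold, scheme = scheme,
                  adjust = adjust, nested = nested, seed = seed),
    package_version = tryCatch(
      as.character(utils::packageVersion("tugait")),
      error = function(e) NA_character_))
  structure(list(table = tab, adjusted = adjusted, selection = selection,
                 selection_raw = selection_raw, cv = cv,
                 manifest = manifest),
            class = "tug_pipeline_result")
}

#' @export
print.tug_pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<tug_pipeline_result> %d/%d subjects analyzed (%s)\n",
              m$n_subjects_analyzed, m$n_subjects_in,
              paste(sprintf("%s=%d", names(m$groups), unlist(m$groups)),
                    collapse = ", ")))
  print(x$selection)
  for (cv in x$cv) print(cv)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Feature table and selection report as CSV, cross-validation results and
#' manifest as JSON. Reruns with the same inputs and seed produce identical
#' files.
#'
#' @param result A \code{\link{run_pipeline}} result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$adjusted, file.path(dir, "features_adjusted.csv"),
                   row.names = FALSE)
  utils::write.csv(result$selection$per_feature,
                   file.path(dir, "selection.csv"), row.names = FALSE)
  cvs <- lapply(result$cv, function(cv)
    list(scheme = cv$scheme, metrics = as.list(cv$metrics),
         metric_sd = as.list(cv$metric_sd),
         chosen = cv$chosen, seed = cv$seed))
  jsonlite::write_json(cvs, file.path(dir, "cv_results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
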