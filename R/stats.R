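## Covariate adjustment and feature selection.
##
## Age and depression score (GDS) confound group comparisons in AD/control
## cohorts, so features are adjusted by ANCOVA before testing: each feature
## is regressed on group + age + GDS, and the fitted covariate contribution
## is replaced by its value at the pooled covariate means. Group differences
## are then tested with Student's t (features normal in both groups by
## Shapiro-Wilk) or Mann-Whitney U otherwise, and correlated survivors are
## pruned, keeping the lower-p member of any pair with |r| > 0.90.

#' Assemble a feature table from a cohort's feature vectors
#'
#' @param features Matrix or data frame of feature values, one row per
#'   subject, columns named as \code{\link{feature_names}} (any subset).
#' @param group Factor or character vector of group labels per subject.
#' @param age,gds Numeric covariates per subject.
#' @param subject_id Optional subject identifiers.
#' @return A \code{tug_feature_table}: data frame with columns
#'   \code{subject_id}, \code{group}, \code{age}, \code{gds} followed by the
#'   feature columns.
#' @export
feature_table <- function(features, group, age, gds, subject_id = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (is.null(subject_id)) subject_id <- sprintf("s%03d", seq_len(n))
  stopifnot(length(group) == n, length(age) == n, length(gds) == n)
  if (anyNA(group)) stop_parameter("group labels must not be missing")
  if (!all(is.finite(age)) || !all(is.finite(gds)))
    stop_parameter("covariates must be finite")
  out <- cbind(data.frame(subject_id = as.character(subject_id),
                          group = as.character(group),
                          age = as.numeric(age), gds = as.numeric(gds),
                          stringsAsFactors = FALSE),
               features)
  class(out) <- c("tug_feature_table", "data.frame")
  out
}

table_feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "group", "age", "gds"))
}

#' Adjust features for age and GDS by ANCOVA
#'
#' Per feature, fits \code{feature ~ group + age + gds} by least squares on
#' the fitting subset and replaces the covariate contribution with its value
#' at the pooled covariate means of that subset:
#' \code{adjusted = observed - b_age (age - mean(age)) - b_gds (gds - mean(gds))}.
#' Fitting with the group term prevents group signal from leaking into the
#' covariate slopes. Group labels are untouched. When cross-validating, fit
#' on the training subjects only and apply to all.
#'
#' @param table A \code{\link{feature_table}}.
#' @param fit_subset Logical or integer index of rows used to estimate the
#'   covariate slopes (default: all rows).
#' @return The table with feature columns replaced by adjusted values.
#' @export
ancova_adjust <- function(table, fit_subset = NULL) {
  if (is.null(fit_subset)) fit_subset <- seq_len(nrow(table))
  fit <- table[fit_subset, , drop = FALSE]
  if (length(unique(fit$group)) < 2 || any(table(fit$group) < 2))
    stop_parameter("ancova_adjust needs >= 2 subjects in each of >= 2 groups")
  age_c <- table$age - mean(fit$age)
  gds_c <- table$gds - mean(fit$gds)
  out <- table
  for (col in table_feature_cols(table)) {
    b <- stats::coef(stats::lm(fit[[col]] ~ group + age + gds, data = fit))
    for (cv in c("age", "gds")) {
      if (is.na(b[[cv]])) {
        # a constant covariate contributes nothing (slope 0); a covariate
        # aliased with the group term makes adjustment unidentifiable
        if (stats::sd(fit[[cv]]) > 1e-12)
          tug_stop("tug_adjustment_error",
                   "covariate '%s' is collinear with the design; adjustment is unidentifiable",
                   cv)
        b[[cv]] <- 0
      }
    }
    out[[col]] <- table[[col]] - b[["age"]] * age_c - b[["gds"]] * gds_c
  }
  out
}

#' Shapiro-Wilk normality p-value
#'
#' @param values Numeric vector, 3 to 5000 values, not all equal.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_test <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop_parameter("normality_test requires 3 <= n <= 5000, got %d",
                   length(values))
  if (diff(range(values)) < .Machine$double.eps * 100)
    tug_stop("tug_degenerate_error",
             "normality test undefined for constant values")
  stats::shapiro.test(values)$p.value
}

#' Two-group feature comparison
#'
#' Student's two-sample t test (Welch disabled: classical equal-variance
#' form) when \code{normal}, otherwise the Mann-Whitney U (Wilcoxon rank
#' sum) test; both two-sided.
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @param normal Use the t branch? (Typically: Shapiro-Wilk p >= 0.05 in
#'   both groups.)
#' @return List with \code{statistic}, \code{p}, \code{test} ("t" or
#'   "mann_whitney").
#' @export
group_test <- function(a, b, normal) {
  if (length(a) < 2 || length(b) < 2)
    stop_parameter("group_test requires >= 2 values per group")
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "t")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE,
                                              correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "mann_whitney")
  }
}

#' Significance screening and correlation pruning of features
#'
#' Per feature: Shapiro-Wilk normality in each group gates the test (t if
#' normal in both, Mann-Whitney otherwise); features with p below
#' \code{alpha} are significant. Among the significant features, any pair
#' with |correlation| above \code{corr_threshold} is resolved by keeping the
#' lower-p member: features are visited in ascending p-order (ties broken by
#' canonical column order) and a feature is dropped if it correlates too
#' strongly with an already-kept one. No multiple-testing correction is
#' applied.
#'
#' @param table A \code{\link{feature_table}} (adjusted or raw values).
#' @param alpha Significance level (default 0.05).
#' @param corr_threshold Absolute correlation above which two features are
#'   considered redundant (default 0.90).
#' @param corr_method \code{"pearson"} (default) or \code{"spearman"}.
#' @return A \code{tug_selection_report}: list with \code{per_feature} (data
#'   frame: feature, normality p per group, test used, p, significant,
#'   outcome, dropped_for) and \code{selected} (character vector).
#' @export
select_features <- function(table, alpha = 0.05, corr_threshold = 0.90,
                            corr_method = c("pearson", "spearman")) {
  corr_method <- match.arg(corr_method)
  cols <- table_feature_cols(table)
  groups <- unique(table$group)
  if (length(groups) != 2)
    stop_parameter("select_features requires exactly 2 groups, got %d",
                   length(groups))
  a_rows <- table$group == groups[1]
  per <- lapply(cols, function(col) {
    a <- table[[col]][a_rows]
    b <- table[[col]][!a_rows]
    pa <- tryCatch(normality_test(a), tug_error = function(e) NA_real_)
    pb <- tryCatch(normality_test(b), tug_error = function(e) NA_real_)
    normal <- !is.na(pa) && !is.na(pb) && pa >= 0.05 && pb >= 0.05
    ht <- tryCatch(group_test(a, b, normal),
                   tug_error = function(e)
                     list(statistic = NA_real_, p = NA_real_, test = NA))
    data.frame(feature = col, normality_p_a = pa, normality_p_b = pb,
               test = ht$test, statistic = ht$statistic, p = ht$p,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per$significant <- !is.na(per$p) & per$p < alpha

  sig <- per$feature[per$significant]
  # ascending p, ties by canonical order (the order of `cols`)
  sig <- sig[order(per$p[match(sig, per$feature)], match(sig, cols))]
  kept <- character(0)
  dropped_for <- stats::setNames(rep(NA_character_, length(cols)), cols)
  if (length(sig) > 0) {
    cmat <- suppressWarnings(
      stats::cor(as.matrix(table[, sig, drop = FALSE]), method = corr_method))
    for (f in sig) {
      clash <- kept[!is.na(cmat[f, kept]) &
                      abs(cmat[f, kept]) > corr_threshold]
      if (length(clash) == 0) kept <- c(kept, f)
      else dropped_for[f] <- clash[1]
    }
  }
  per$outcome <- ifelse(!per$significant, "insignificant",
                        ifelse(per$feature %in% kept, "selected",
                               "dropped_for"))
  per$dropped_for <- dropped_for[per$feature]
  rownames(per) <- NULL
  structure(list(per_feature = per,
                 selected = cols[cols %in% kept],
                 alpha = alpha, corr_threshold = corr_threshold,
                 corr_method = corr_method),
            class = "tug_selection_report")
}

#' @export
print.tug_selection_report <- function(x, ...) {
  cat(sprintf(
    "<tug_selection_report> %d features: %d significant (alpha %.2f), %d selected (|r| > %.2f pruned)\n",
    nrow(x$per_feature), sum(x$per_feature$significant), x$alpha,
    length(x$selected), x$corr_threshold))
  invisible(x)
}
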