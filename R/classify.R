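## SVM discrimination of the two groups from selected features.
##
## Linear and Gaussian RBF kernels with C and gamma grid-searched over
## powers of two from 2^-4 to 2^4. Outer validation is stratified five-fold
## or leave-one-subject-out; covariate adjustment, feature selection and
## standardization are all re-fit inside each training fold so no held-out
## information reaches model fitting.

#' Hyper-parameter grid for the SVM
#'
#' @param kernels Subset of \code{c("linear", "rbf")}.
#' @param c_exponents,gamma_exponents Integer exponents of 2 for the
#'   regularization parameter C and (RBF only) kernel width gamma.
#' @return A \code{tug_hyper_grid} data frame with columns \code{kernel},
#'   \code{C}, \code{gamma} (gamma is \code{NA} for the linear kernel).
#' @export
hyper_grid <- function(kernels = c("linear", "rbf"),
                       c_exponents = -4:4, gamma_exponents = -4:4) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  rows <- list()
  if ("linear" %in% kernels)
    rows$linear <- data.frame(kernel = "linear", C = 2^c_exponents,
                              gamma = NA_real_)
  if ("rbf" %in% kernels)
    rows$rbf <- expand.grid(kernel = "rbf", C = 2^c_exponents,
                            gamma = 2^gamma_exponents,
                            stringsAsFactors = FALSE)[, c("kernel", "C", "gamma")]
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  class(g) <- c("tug_hyper_grid", "data.frame")
  g
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity (recall of the positive class), precision,
#' specificity and F-score, reported in percent. Ratios with a zero
#' denominator are reported as \code{NA} (undefined), not as 0.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive The positive-class label.
#' @return Named numeric vector (percent): \code{accuracy},
#'   \code{sensitivity}, \code{precision}, \code{specificity},
#'   \code{f_score}.
#' @export
#' @examples
#' evaluate_metrics(rep(c("AD", "HC"), c(4, 6)),
#'                  rep(c("AD", "HC", "AD", "HC"), c(3, 1, 2, 4)), "AD")
evaluate_metrics <- function(y_true, y_pred, positive = "AD") {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop_parameter("label vectors must be non-empty and of equal length")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  100 * c(accuracy = (tp + tn) / length(y_true), sensitivity = sens,
          precision = prec, specificity = ratio(tn, tn + fp), f_score = f)
}

## internals -----------------------------------------------------------------

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

svm_fit <- function(x, y, row) {
  if (row$kernel == "linear")
    e1071::svm(x, y, kernel = "linear", cost = row$C, scale = FALSE)
  else
    e1071::svm(x, y, kernel = "radial", cost = row$C, gamma = row$gamma,
               scale = FALSE)
}

# stratified fold assignment (1..k per row), deterministic given the RNG
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# inner grid search: mean 3-fold CV accuracy on the training data; ties go
# to the earlier grid row (linear before rbf, smaller C, smaller gamma)
grid_search <- function(x, y, grid, inner_k = 3L) {
  inner <- stratified_folds(y, inner_k)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    correct <- 0L
    for (f in seq_len(inner_k)) {
      tr <- inner != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr], grid[gi, ])
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  if (all(is.na(acc))) stop_parameter("inner folds lost a class")
  grid[which.max(acc), , drop = FALSE]
}

# Fit the full training pipeline (adjust -> select -> standardize -> grid
# search -> SVM) on `train_idx` of `table` and predict the remaining rows.
fit_fold <- function(table, train_idx, grid, adjust, alpha, corr_threshold,
                     nested) {
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  adj <- if (adjust) ancova_adjust(table, fit_subset = train_idx) else table
  if (nested) {
    rep <- select_features(adj[train_idx, , drop = FALSE], alpha = alpha,
                           corr_threshold = corr_threshold)
    selected <- rep$selected
    if (length(selected) == 0) {
      # degenerate under null-like data: fall back to the single lowest-p
      # feature so the fold can still be scored
      pf <- rep$per_feature
      selected <- pf$feature[which.min(pf$p)]
    }
  } else {
    rep <- NULL
    selected <- table_feature_cols(table)
  }
  xtr <- as.matrix(adj[train_idx, selected, drop = FALSE])
  xte <- as.matrix(adj[test_idx, selected, drop = FALSE])
  sc <- standardize_fit(xtr)
  xtr <- standardize_apply(xtr, sc)
  xte <- standardize_apply(xte, sc)
  ytr <- factor(table$group[train_idx])
  best <- grid_search(xtr, ytr, grid)
  fit <- svm_fit(xtr, ytr, best)
  pred <- as.character(stats::predict(fit, xte))
  list(test_idx = test_idx, pred = pred, best = best, selection = rep,
       selected = selected)
}

#' Cross-validated SVM evaluation
#'
#' Per outer fold, covariate adjustment, the significance screen, the
#' correlation pruning and feature standardization are fit on the training
#' subjects only; hyper-parameters are grid-searched by 3-fold inner
#' cross-validation on the training data; the refit model then scores the
#' held-out subjects. Five-fold results are aggregated as mean and SD over
#' folds; leave-one-subject-out results pool all held-out predictions.
#'
#' @param table A \code{\link{feature_table}} with raw (unadjusted) values.
#' @param grid A \code{\link{hyper_grid}}.
#' @param scheme \code{"five_fold"} or \code{"loso"}.
#' @param seed Integer seed controlling fold shuffling and the inner CV.
#' @param adjust Adjust for age and GDS within folds (default TRUE).
#' @param nested Re-select features inside each training fold (default
#'   TRUE); \code{FALSE} uses all features without selection, for
#'   comparison.
#' @param alpha,corr_threshold Passed to \code{\link{select_features}}.
#' @param positive Positive-class label for the metrics (default "AD").
#' @return A \code{tug_cv_result}: list with \code{scheme}, \code{metrics}
#'   (aggregate, %), \code{metric_sd} (five-fold only), \code{fold_metrics},
#'   \code{folds} (assignment per subject), \code{predictions},
#'   \code{chosen} (per-fold kernel/C/gamma), \code{fold_selections} and
#'   \code{seed}.
#' @export
cross_validate <- function(table, grid = hyper_grid(),
                           scheme = c("five_fold", "loso"), seed = 1L,
                           adjust = TRUE, nested = TRUE, alpha = 0.05,
                           corr_threshold = 0.90, positive = "AD") {
  scheme <- match.arg(scheme)
  y <- table$group
  if (any(table(y) < 2) || length(unique(y)) != 2)
    stop_parameter("cross_validate requires 2 classes with >= 2 subjects each")
  with_seed(seed, {
    folds <- if (scheme == "five_fold") stratified_folds(y, 5L)
             else seq_len(nrow(table))
    k <- max(folds)
    fold_res <- lapply(seq_len(k), function(f) {
      train_idx <- which(folds != f)
      if (length(unique(y[train_idx])) < 2)
        stop_parameter("training fold %d lost a class", f)
      fit_fold(table, train_idx, grid, adjust, alpha, corr_threshold, nested)
    })
    preds <- character(nrow(table))
    for (fr in fold_res) preds[fr$test_idx] <- fr$pred
    if (scheme == "five_fold") {
      fm <- t(vapply(seq_len(k), function(f)
        evaluate_metrics(y[fold_res[[f]]$test_idx], fold_res[[f]]$pred,
                         positive), numeric(5)))
      metrics <- colMeans(fm, na.rm = TRUE)
      metric_sd <- apply(fm, 2, stats::sd, na.rm = TRUE)
    } else {
      fm <- NULL
      metrics <- evaluate_metrics(y, preds, positive)
      metric_sd <- NULL
    }
    structure(list(
      scheme = scheme, metrics = metrics, metric_sd = metric_sd,
      fold_metrics = fm, folds = folds, predictions = preds,
      chosen = do.call(rbind, lapply(fold_res, `[[`, "best")),
      fold_selections = lapply(fold_res, `[[`, "selection"),
      fold_selected = lapply(fold_res, `[[`, "selected"),
      seed = seed), class = "tug_cv_result")
  })
}

#' @export
print.tug_cv_result <- function(x, ...) {
  cat(sprintf("<tug_cv_result> %s\n", x$scheme))
  m <- round(x$metrics, 2)
  if (!is.null(x$metric_sd))
    cat(paste(sprintf("  %s: %.2f +/- %.2f%%", names(m), m,
                      x$metric_sd), collapse = "\n"), "\n")
  else
    cat(paste(sprintf("  %s: %.2f%%", names(m), m), collapse = "\n"), "\n")
  invisible(x)
}
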