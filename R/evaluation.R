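#' Confusion counts from predicted and actual labels
#'
#' @param predicted,actual 0/1 vectors of equal length.
#' @return List with integer fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  stopifnot(length(predicted) == length(actual), length(actual) >= 1L)
  list(
    tp = sum(predicted == 1L & actual == 1L),
    tn = sum(predicted == 0L & actual == 0L),
    fp = sum(predicted == 1L & actual == 0L),
    fn = sum(predicted == 0L & actual == 1L)
  )
}

#' Sensitivity, specificity, accuracy and MCC from a confusion table
#'
#' Exact evaluation of the standard two-class formulas:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/n`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' Metrics are returned as fractions in `[0,1]` (`[-1,1]` for MCC); multiply
#' by 100 for the percentage convention. When the MCC denominator is zero the
#' value is 0 by the usual degenerate-table convention. When a class is absent
#' (`TP+FN = 0` or `TN+FP = 0`) the corresponding rate is `NaN` with a
#' warning.
#'
#' @param counts A list with fields `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]); alternatively pass the four counts directly.
#' @param tp,tn,fp,fn Individual counts, used when `counts` is missing.
#' @return An object of class `m6a_metrics`: list with `sn`, `sp`, `acc`,
#'   `mcc`, `counts`, `n`, and `auc`/`protocol` slots filled by the evaluation
#'   protocols.
#' @export
compute_metrics <- function(counts = NULL, tp = NULL, tn = NULL, fp = NULL,
                            fn = NULL) {
  if (is.null(counts)) counts <- list(tp = tp, tn = tn, fp = fp, fn = fn)
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  stopifnot(!anyNA(c(tp, tn, fp, fn)), all(c(tp, tn, fp, fn) >= 0))
  n <- tp + tn + fp + fn
  if (n < 1) stop("empty confusion table", call. = FALSE)

  sn <- if (tp + fn == 0) {
    warning("no positive samples: sensitivity undefined", call. = FALSE)
    NaN
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("no negative samples: specificity undefined", call. = FALSE)
    NaN
  } else tn / (tn + fp)
  acc <- (tp + tn) / n
  mcc_den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)

  structure(
    list(sn = sn, sp = sp, acc = acc, mcc = mcc, auc = NA_real_,
         counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
         n = n, protocol = "holdout"),
    class = "m6a_metrics"
  )
}

#' @export
print.m6a_metrics <- function(x, digits = 4L, ...) {
  cat("m6a_metrics (", x$protocol, ", n=", x$n, ")\n", sep = "")
  cat(sprintf("  Sn = %.*f  Sp = %.*f  Acc = %.*f  MCC = %.*f",
              digits, x$sn, digits, x$sp, digits, x$acc, digits, x$mcc))
  if (!is.na(x$auc)) cat(sprintf("  AUC = %.*f", digits, x$auc))
  cat("\n")
  invisible(x)
}

#' Metrics report as a JSON string
#'
#' @param metrics An `m6a_metrics`.
#' @param percent Render Sn/Sp/Acc on the 0-100% scale?
#' @return A JSON character scalar.
#' @export
metrics_json <- function(metrics, percent = FALSE) {
  scale <- if (isTRUE(percent)) 100 else 1
  jsonlite::toJSON(list(
    protocol = metrics$protocol, n = metrics$n,
    sn = metrics$sn * scale, sp = metrics$sp * scale,
    acc = metrics$acc * scale, mcc = metrics$mcc, auc = metrics$auc,
    counts = metrics$counts
  ), auto_unbox = TRUE, digits = NA, na = "null")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores (samples predicted
#' positive when `score >= threshold`), producing a curve from (0,0) to (1,1)
#' with non-decreasing FPR and TPR; tied scores cross the threshold
#' simultaneously. The area is computed by trapezoidal integration, which
#' equals the Mann-Whitney pair-counting statistic `P(score+ > score-) +
#' 0.5 P(tie)` normalized by `n+ * n-`.
#'
#' @param scores Numeric prediction scores (larger = more site-like).
#' @param labels Parallel 0/1 truth labels; both classes must be present.
#' @return An object of class `m6a_roc`: list with `points` (data frame of
#'   `threshold`, `fpr`, `tpr`; the first row's threshold is `Inf`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("ROC requires both classes to be present (", npos, " positive, ",
         nneg, " negative)", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each distinct-score boundary
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  ctp <- cumsum(y == 1L)[last_of_tie]
  cfp <- cumsum(y == 0L)[last_of_tie]
  points <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cfp / nneg),
    tpr = c(0, ctp / npos)
  )
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "m6a_roc")
}

#' @export
print.m6a_roc <- function(x, ...) {
  cat("m6a_roc:", nrow(x$points), "points, AUC =", sprintf("%.4f", x$auc), "\n")
  invisible(x)
}

#' Write a ROC curve as TSV
#'
#' @param roc An `m6a_roc`.
#' @param path Output path (columns threshold, fpr, tpr).
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration for the evaluation protocols
#'
#' Describes what happens inside each training fold of [cross_validate()] /
#' [jackknife()]: optional feature selection (F-score ranking + SFS, fitted on
#' the training rows only, so the evaluation is nested and leak-free) and the
#' classifier settings. When `grid` is supplied a full grid search runs inside
#' every fold; otherwise `params` is used directly. When `selected_columns` is
#' supplied the matrix is simply restricted to those columns ("flat" mode:
#' selection was performed beforehand on the full data — the reference
#' protocol, but one that leaks selection information into the evaluation; see
#' the vignette).
#'
#' @param params List with `max_depth`, `learning_rate`, `n_estimators` for a
#'   direct fit.
#' @param grid Optional [m6a_grid()] searched inside each fold.
#' @param selection Run F-score + SFS inside each training fold?
#' @param selected_columns Optional fixed column set (flat mode).
#' @param sfs_folds,sfs_stride Inner-CV folds and stride for the in-fold SFS.
#' @param grid_folds Inner-CV folds for the in-fold grid search.
#' @return A list of class `m6a_config`.
#' @export
m6a_config <- function(params = list(max_depth = 3L, learning_rate = 0.3,
                                     n_estimators = 10L),
                       grid = NULL, selection = FALSE,
                       selected_columns = NULL,
                       sfs_folds = 5L, sfs_stride = 1L, grid_folds = 5L) {
  if (!is.null(grid)) stopifnot(inherits(grid, "m6a_grid"))
  structure(list(params = params, grid = grid, selection = isTRUE(selection),
                 selected_columns = selected_columns,
                 sfs_folds = as.integer(sfs_folds),
                 sfs_stride = as.integer(sfs_stride),
                 grid_folds = as.integer(grid_folds)),
            class = "m6a_config")
}

# Fit the configured pipeline on a training matrix; returns a scoring closure
# over the full column space. Selection and tuning see only the rows given.
.fit_pipeline <- function(mat, labels, config, seed) {
  cols <- colnames(mat)
  if (!is.null(config$selected_columns)) {
    cols <- config$selected_columns
  } else if (config$selection) {
    sel <- sfs_select(mat, labels,
                      trainer = xgb_trainer(seed = seed),
                      folds = config$sfs_folds, seed = seed,
                      stride = config$sfs_stride)
    cols <- sel$optimal_columns
  }
  sub <- mat[, cols, drop = FALSE]
  if (!is.null(config$grid)) {
    fold_assign <- make_folds(labels, config$grid_folds, seed)
    pts <- .grid_points(config$grid)
    accs <- vapply(seq_len(nrow(pts)), function(i) {
      tr <- xgb_trainer(pts$max_depth[i], pts$learning_rate[i],
                        pts$n_estimators[i], seed = seed)
      .cv_pooled_accuracy(sub, labels, tr, fold_assign)
    }, numeric(1L))
    b <- which.max(accs)
    params <- list(max_depth = pts$max_depth[b],
                   learning_rate = pts$learning_rate[b],
                   n_estimators = pts$n_estimators[b])
  } else {
    params <- config$params
  }
  fit <- xgb_trainer(params$max_depth, params$learning_rate,
                     params$n_estimators, seed = seed)(sub, labels)
  function(newmat) fit(newmat[, cols, drop = FALSE])
}

# shared pooling logic for cross_validate / jackknife
.pooled_report <- function(mat, labels, config, fold_assign, seed, protocol) {
  scores <- rep(NA_real_, length(labels))
  for (f in sort(unique(fold_assign))) {
    test <- fold_assign == f
    if (length(unique(labels[!test])) < 2L) {
      stop("a training fold lost one class entirely; use stratified folds ",
           "or a larger dataset", call. = FALSE)
    }
    scorer <- .fit_pipeline(mat[!test, , drop = FALSE], labels[!test],
                            config, seed)
    scores[test] <- scorer(mat[test, , drop = FALSE])
  }
  predicted <- as.integer(scores >= 0.5)
  report <- compute_metrics(confusion_counts(predicted, labels))
  roc <- roc_auc(scores, labels)
  report$auc <- roc$auc
  report$protocol <- protocol
  report$scores <- scores
  report$roc <- roc
  report
}

#' Stratified k-fold cross-validation with pooled metrics
#'
#' Splits the data into stratified folds, fits the configured pipeline on each
#' training portion, predicts the held-out fold, and computes one metrics
#' report from the union of all out-of-fold predictions (pooled confusion
#' table and pooled scores), rather than averaging per-fold metrics. Fold
#' assignment and every downstream source of randomness derive from `seed`,
#' so reports are reproducible.
#'
#' @param x An `m6a_dataset`, or a feature matrix (then `labels` is required).
#' @param config An [m6a_config()].
#' @param folds Number of folds (default 10).
#' @param seed Master seed.
#' @param labels Row labels when `x` is a matrix.
#' @return An `m6a_metrics` with `protocol = "cv<folds>"`, pooled out-of-fold
#'   `scores`, and the pooled `roc`.
#' @export
cross_validate <- function(x, config = m6a_config(), folds = 10L, seed = 1L,
                           labels = NULL) {
  if (inherits(x, "m6a_dataset")) {
    labels <- x$labels
    mat <- encode_dataset(x)
  } else {
    mat <- x
    if (is.null(labels)) stop("labels required with a matrix input", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (nrow(mat) < folds) {
    stop("n = ", nrow(mat), " < folds = ", folds,
         "; consider the jackknife protocol instead", call. = FALSE)
  }
  fold_assign <- make_folds(labels, folds, seed)
  .pooled_report(mat, labels, config, fold_assign, seed,
                 protocol = paste0("cv", folds))
}

#' Jackknife (leave-one-out) evaluation
#'
#' Trains `n` models, each predicting the one held-out sample; metrics are
#' computed from the `n` pooled predictions. Deterministic given `seed`.
#' Because the cost grows linearly in `n` trainings, datasets larger than
#' `cap` are refused unless `force = TRUE`.
#'
#' @inheritParams cross_validate
#' @param cap Refuse n above this size unless forced (default 5000).
#' @param force Override the cap.
#' @return An `m6a_metrics` with `protocol = "jackknife"`.
#' @export
jackknife <- function(x, config = m6a_config(), seed = 1L, labels = NULL,
                      cap = 5000L, force = FALSE) {
  if (inherits(x, "m6a_dataset")) {
    labels <- x$labels
    mat <- encode_dataset(x)
  } else {
    mat <- x
    if (is.null(labels)) stop("labels required with a matrix input", call. = FALSE)
  }
  labels <- as.integer(labels)
  n <- nrow(mat)
  if (n < 2L) stop("jackknife needs at least 2 samples", call. = FALSE)
  if (min(table(labels)) < 2L) {
    stop("each class needs >= 2 samples so every leave-one-out training set ",
         "keeps both classes", call. = FALSE)
  }
  if (n > cap && !isTRUE(force)) {
    stop("jackknife over n = ", n, " exceeds the runtime cap (", cap,
         "); pass force = TRUE to run anyway or use cross_validate()",
         call. = FALSE)
  }
  .pooled_report(mat, labels, config, fold_assign = seq_len(n), seed,
                 protocol = "jackknife")
}
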