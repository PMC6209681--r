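# Stratified fold assignment: within each class, samples are shuffled under
# the seed and dealt round-robin into folds, so class balance is preserved
# per fold (the benchmark datasets are exactly class-balanced).
make_folds <- function(labels, folds, seed) {
  labels <- as.integer(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds) {
        stop("class ", cl, " has only ", length(idx),
             " samples for ", folds, "-fold CV; use fewer folds or jackknife",
             call. = FALSE)
      }
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Two-class F-score of one feature column
#'
#' The filter score
#' \deqn{F = \frac{(\bar{x}^{+} - \bar{x})^2 + (\bar{x}^{-} - \bar{x})^2}
#'            {\frac{1}{n^{+}-1}\sum_i (x_i^{+} - \bar{x}^{+})^2 +
#'             \frac{1}{n^{-}-1}\sum_i (x_i^{-} - \bar{x}^{-})^2}}
#' where \eqn{\bar{x}}, \eqn{\bar{x}^{+}}, \eqn{\bar{x}^{-}} are the overall,
#' positive-class and negative-class means. Larger scores indicate stronger
#' between-class separation relative to within-class spread. This is the
#' filter-sense F-score used throughout sequence-predictor work, not the F1
#' classification metric.
#'
#' A feature constant within each class but differing between classes has a
#' zero denominator and nonzero numerator; it is maximally discriminative and
#' receives `Inf` so it ranks first. A feature constant everywhere (0/0)
#' scores 0.
#'
#' @param x Numeric feature column.
#' @param labels Parallel 0/1 labels; both classes must have >= 2 samples.
#' @return A non-negative scalar (possibly `Inf`).
#' @export
f_score <- function(x, labels) {
  labels <- as.integer(labels)
  stopifnot(length(x) == length(labels))
  pos <- x[labels == 1L]
  neg <- x[labels == 0L]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("both classes need >= 2 samples to compute an F-score (got ",
         length(pos), " positive, ", length(neg), " negative)", call. = FALSE)
  }
  m <- mean(x)
  num <- (mean(pos) - m)^2 + (mean(neg) - m)^2
  den <- stats::var(pos) + stats::var(neg)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Rank feature columns by descending F-score
#'
#' Ties are broken by ascending original column index (stable ranking).
#'
#' @param mat Numeric feature matrix (e.g. from [encode_dataset()]).
#' @param labels 0/1 labels, one per row.
#' @return An object of class `m6a_ranking`: list with `order` (permutation of
#'   column indices, best first), `scores` (F-scores along `order`) and
#'   `columns` (column names along `order`).
#' @export
rank_features <- function(mat, labels) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    tryCatch(f_score(mat[, j], labels), error = function(e) {
      nm <- colnames(mat)[j]
      stop("f_score failed for column ", if (is.null(nm)) j else nm, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }, numeric(1L))
  ord <- order(-scores, seq_along(scores))
  structure(
    list(order = ord, scores = scores[ord],
         columns = if (is.null(colnames(mat))) as.character(ord)
                   else colnames(mat)[ord]),
    class = "m6a_ranking"
  )
}

#' @export
print.m6a_ranking <- function(x, ...) {
  cat("m6a_ranking over", length(x$order), "features; top 5:\n")
  print(utils::head(data.frame(column = x$columns, f_score = x$scores), 5L))
  invisible(x)
}

# Pooled CV accuracy of `trainer` on x/labels under a precomputed fold
# assignment. Used by SFS and grid search so every candidate sees the
# identical partition.
.cv_pooled_accuracy <- function(x, labels, trainer, fold_assign) {
  correct <- 0L
  for (f in sort(unique(fold_assign))) {
    test <- fold_assign == f
    fit <- trainer(x[!test, , drop = FALSE], labels[!test])
    sc <- fit(x[test, , drop = FALSE])
    correct <- correct + sum(as.integer(sc >= 0.5) == labels[test])
  }
  correct / length(labels)
}

#' Gradient-boosted tree trainer factory
#'
#' Returns a trainer satisfying the classifier contract used by
#' [sfs_select()], [grid_search_train()] and [cross_validate()]: a function
#' `trainer(x, y)` that fits on a numeric matrix and 0/1 labels and returns a
#' scoring closure `function(newx)` emitting the class-1 probability per row.
#' Any compliant implementation may replace it; this default backs the
#' contract with xgboost (binary logistic objective, single thread, seeded
#' tree construction). Exact greedy split finding is used, with no
#' minimum-hessian constraint on the leaves: the benchmark datasets of this
#' field are small (hundreds to a few thousand windows), where histogram
#' binning and the default hessian floor of the library distort splits on
#' tiny training folds (notably under jackknife evaluation); model complexity
#' is still controlled by depth, shrinkage and the L2 penalty.
#'
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage (eta).
#' @param n_estimators Number of boosting rounds.
#' @param seed Seed passed to the tree builder.
#' @return A trainer function.
#' @export
xgb_trainer <- function(max_depth = 3L, learning_rate = 0.3,
                        n_estimators = 10L, seed = 1L) {
  force(max_depth); force(learning_rate); force(n_estimators); force(seed)
  function(x, y) {
    train_once <- function() {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = learning_rate, tree_method = "exact",
                      min_child_weight = 0, nthread = 1L, seed = seed),
        data = dtrain, nrounds = n_estimators, verbose = 0L
      )
    }
    booster <- train_once()
    function(newx) {
      # explicit DMatrix: the dense inplace-predict path is unreliable after
      # many sequential trainings in this xgboost build
      dnew <- xgboost::xgb.DMatrix(newx, nthread = 1L)
      p <- tryCatch(predict(booster, dnew), error = function(e) e)
      if (inherits(p, "error")) {
        # rarely, a long-lived booster handle is invalidated under heavy
        # allocation churn; training is fully deterministic (fixed data,
        # params and seed), so rebuilding yields the identical model
        booster <<- train_once()
        p <- predict(booster, dnew)
      }
      stats::setNames(p, rownames(newx))
    }
  }
}

#' Sequential forward search over an F-score ranking
#'
#' Grows nested feature subsets along the ranking (sizes `1, 1 + stride, ...`,
#' always including the full set), evaluates each by pooled stratified
#' cross-validated accuracy under one fixed fold assignment, and returns the
#' accuracy-maximizing subset. On ties the smallest subset wins, preferring
#' compact models.
#'
#' @param mat Feature matrix.
#' @param labels 0/1 labels per row.
#' @param ranking An `m6a_ranking` from [rank_features()]; computed internally
#'   when `NULL`.
#' @param trainer Classifier factory (see [xgb_trainer()]).
#' @param folds Number of stratified CV folds for the inner evaluation.
#' @param seed Seed for the fold assignment.
#' @param stride Step between evaluated subset sizes. 1 adds features one by
#'   one (the reference procedure); larger strides are an explicit
#'   coarse-search deviation for wide matrices.
#' @return An object of class `m6a_selection`: list with `trace` (data frame
#'   of `k`, `accuracy`), `optimal_size`, `optimal_columns` (names of the
#'   selected columns, ranking order), `optimal_accuracy`, and the `ranking`.
#' @export
sfs_select <- function(mat, labels, ranking = NULL, trainer = xgb_trainer(),
                       folds = 10L, seed = 1L, stride = 1L) {
  stopifnot(is.matrix(mat))
  labels <- as.integer(labels)
  if (is.null(ranking)) ranking <- rank_features(mat, labels)
  d <- ncol(mat)
  if (length(ranking$order) != d) {
    stop("ranking covers ", length(ranking$order), " columns but the matrix has ",
         d, call. = FALSE)
  }
  stride <- max(1L, as.integer(stride))
  ks <- unique(c(seq(1L, d, by = stride), d))
  fold_assign <- make_folds(labels, folds, seed)

  acc <- vapply(ks, function(k) {
    cols <- ranking$order[seq_len(k)]
    tryCatch(
      .cv_pooled_accuracy(mat[, cols, drop = FALSE], labels, trainer,
                          fold_assign),
      error = function(e) {
        stop("trainer failed at subset size k=", k, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }, numeric(1L))

  best <- ks[which.max(acc)]  # which.max takes the first (smallest k) on ties
  structure(
    list(
      trace = data.frame(k = ks, accuracy = acc),
      optimal_size = best,
      optimal_columns = ranking$columns[seq_len(best)],
      optimal_accuracy = max(acc),
      ranking = ranking,
      folds = as.integer(folds), seed = as.integer(seed), stride = stride
    ),
    class = "m6a_selection"
  )
}

#' @export
print.m6a_selection <- function(x, ...) {
  cat("m6a_selection: optimal subset of", x$optimal_size, "features,",
      "CV accuracy", sprintf("%.4f", x$optimal_accuracy), "\n")
  invisible(x)
}

#' Export a selection result
#'
#' Writes the accuracy trace as TSV (columns `k`, `accuracy`) and, optionally,
#' the selected column names as a plain-text list (one per line).
#'
#' @param selection An `m6a_selection`.
#' @param trace_path Output TSV path for the trace.
#' @param columns_path Optional output path for the selected column names.
#' @return `trace_path`, invisibly.
#' @export
write_selection <- function(selection, trace_path, columns_path = NULL) {
  utils::write.table(selection$trace, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(columns_path)) {
    writeLines(selection$optimal_columns, columns_path)
  }
  invisible(trace_path)
}
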