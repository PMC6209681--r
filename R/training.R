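#' Hyperparameter grid for the gradient-boosted tree classifier
#'
#' Defaults are the reference search ranges: `max_depth` 2..10, learning rate
#' 0.1..0.8 in steps of 0.1, and 1..10 boosting rounds. The 1..10 round range
#' is unusually small for gradient boosting; it is kept as the default search
#' space but every component is overridable (e.g. `n_estimators = c(50, 100,
#' 200)` for real-world use).
#'
#' @param max_depth Integer vector of tree depths.
#' @param learning_rate Numeric vector of shrinkage values.
#' @param n_estimators Integer vector of boosting-round counts.
#' @return An object of class `m6a_grid`.
#' @export
m6a_grid <- function(max_depth = 2:10,
                     learning_rate = seq(0.1, 0.8, by = 0.1),
                     n_estimators = 1:10) {
  max_depth <- as.integer(max_depth)
  n_estimators <- as.integer(n_estimators)
  if (length(max_depth) == 0L || length(learning_rate) == 0L ||
      length(n_estimators) == 0L) {
    stop("every grid dimension must be non-empty", call. = FALSE)
  }
  if (any(max_depth < 1L) || any(learning_rate <= 0) || any(n_estimators < 1L)) {
    stop("all grid values must be positive", call. = FALSE)
  }
  structure(list(max_depth = sort(max_depth),
                 learning_rate = sort(learning_rate),
                 n_estimators = sort(n_estimators)),
            class = "m6a_grid")
}

# canonical enumeration: n_estimators varies slowest is irrelevant --
# candidates are sorted by the tie-break key (n_estimators, max_depth,
# learning_rate) so "first max" is the canonical winner regardless of
# enumeration order.
.grid_points <- function(grid) {
  pts <- expand.grid(learning_rate = grid$learning_rate,
                     max_depth = grid$max_depth,
                     n_estimators = grid$n_estimators,
                     KEEP.OUT.ATTRS = FALSE)
  pts[order(pts$n_estimators, pts$max_depth, pts$learning_rate), , drop = FALSE]
}

#' Exhaustive grid search and final model fit
#'
#' Evaluates every grid point by pooled stratified k-fold cross-validated
#' accuracy under one fixed fold assignment, picks the best point (ties broken
#' toward smaller `n_estimators`, then smaller `max_depth`, then smaller
#' `learning_rate`, making the result invariant to enumeration order), and
#' refits it on all rows. All stochasticity derives from `seed`.
#'
#' @param mat Feature matrix, already restricted to the selected columns.
#' @param labels 0/1 labels per row; both classes must be present.
#' @param grid An [m6a_grid()].
#' @param folds Stratified CV folds for the grid objective.
#' @param seed Master seed (fold shuffling and tree building).
#' @param encoding_config List describing the feature space the model expects;
#'   see [m6a_encoding_config()]. Required so the bundle can re-encode raw
#'   sequences at prediction time.
#' @return An object of class `m6a_model`: the trained booster plus
#'   `selected_columns`, `encoding_config`, `best_params`, the full
#'   `grid_results` table, `cv_accuracy` at the optimum, and `seed`.
#' @export
grid_search_train <- function(mat, labels, grid = m6a_grid(), folds = 10L,
                              seed = 1L, encoding_config = NULL) {
  stopifnot(is.matrix(mat), inherits(grid, "m6a_grid"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train", call. = FALSE)
  }
  if (is.null(encoding_config)) {
    wl <- attr(mat, "window_length")
    encoding_config <- m6a_encoding_config(
      window_length = if (is.null(wl)) NA_integer_ else wl
    )
  }
  fold_assign <- make_folds(labels, folds, seed)
  pts <- .grid_points(grid)
  pts$accuracy <- vapply(seq_len(nrow(pts)), function(i) {
    tr <- xgb_trainer(max_depth = pts$max_depth[i],
                      learning_rate = pts$learning_rate[i],
                      n_estimators = pts$n_estimators[i],
                      seed = seed)
    .cv_pooled_accuracy(mat, labels, tr, fold_assign)
  }, numeric(1L))

  best <- pts[which.max(pts$accuracy), , drop = FALSE]
  best_params <- list(max_depth = best$max_depth[[1L]],
                      learning_rate = best$learning_rate[[1L]],
                      n_estimators = best$n_estimators[[1L]])

  final_trainer <- xgb_trainer(max_depth = best_params$max_depth,
                               learning_rate = best_params$learning_rate,
                               n_estimators = best_params$n_estimators,
                               seed = seed)
  dtrain <- xgboost::xgb.DMatrix(mat, label = labels, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = best_params$max_depth,
                  eta = best_params$learning_rate,
                  tree_method = "exact", min_child_weight = 0,
                  nthread = 1L, seed = seed),
    data = dtrain, nrounds = best_params$n_estimators, verbose = 0L
  )

  structure(
    list(
      booster = booster,
      selected_columns = colnames(mat),
      encoding_config = encoding_config,
      best_params = best_params,
      cv_accuracy = best$accuracy[[1L]],
      grid_results = pts,
      folds = as.integer(folds),
      seed = as.integer(seed),
      trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_train = nrow(mat)
    ),
    class = "m6a_model"
  )
}

#' Encoding configuration stored inside a model bundle
#'
#' @param window_length Window length the model was trained on.
#' @param descriptors Descriptor concatenation order.
#' @param code_table Version tag of the dinucleotide code table.
#' @return A list of class `m6a_encoding_config`.
#' @export
m6a_encoding_config <- function(window_length,
                                descriptors = c("DBE", "LPSDF"),
                                code_table = code_table_version()) {
  structure(list(window_length = as.integer(window_length),
                 descriptors = descriptors,
                 code_table = code_table),
            class = "m6a_encoding_config")
}

#' @export
print.m6a_model <- function(x, ...) {
  cat("m6a_model:", length(x$selected_columns), "features, window length",
      x$encoding_config$window_length, "nt\n")
  cat("  best params: max_depth=", x$best_params$max_depth,
      ", learning_rate=", x$best_params$learning_rate,
      ", n_estimators=", x$best_params$n_estimators,
      " (CV accuracy ", sprintf("%.4f", x$cv_accuracy), ")\n", sep = "")
  invisible(x)
}

#' Predict m6A sites for new sequences
#'
#' Encodes the query sequences with the model's stored encoding configuration,
#' restricts the matrix to the model's selected columns and scores every row.
#' A window scoring at least 0.5 is called a site (label 1); the raw score is
#' returned alongside.
#'
#' @param object An `m6a_model`.
#' @param newdata Named character vector of sequences, an `m6a_dataset`, or a
#'   pre-encoded feature matrix carrying the model's columns.
#' @param ... Unused.
#' @return Data frame with columns `id`, `score` (class-1 probability) and
#'   `label` (0/1).
#' @export
predict.m6a_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    mat <- newdata
  } else {
    if (inherits(newdata, "m6a_dataset")) {
      newdata <- stats::setNames(newdata$sequences, newdata$ids)
    }
    expected <- object$encoding_config$window_length
    lens <- nchar(newdata)
    if (!is.na(expected) && any(lens != expected)) {
      bad <- which(lens != expected)[[1L]]
      stop("sequence length mismatch: model expects ", expected,
           " nt but '", names(newdata)[bad], "' has ", lens[bad], " nt",
           call. = FALSE)
    }
    mat <- encode_dataset(newdata)
  }
  missing <- setdiff(object$selected_columns, colnames(mat))
  if (length(missing) > 0L) {
    stop("feature matrix lacks model columns: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  mat <- mat[, object$selected_columns, drop = FALSE]
  scores <- predict(object$booster, xgboost::xgb.DMatrix(mat, nthread = 1L))
  data.frame(
    id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
         else rownames(mat),
    score = as.numeric(scores),
    label = as.integer(scores >= 0.5),
    stringsAsFactors = FALSE
  )
}

.BUNDLE_FORMAT <- 1L

#' Save a trained model bundle
#'
#' The bundle is a single file holding the serialized booster (raw bytes), the
#' selected feature columns, and a JSON metadata sidecar (encoding
#' configuration, best hyperparameters, seed, code-table version). Loading
#' reproduces predictions bit-identically; a bundle written under a different
#' dinucleotide code-table version is refused at load time.
#'
#' @param model An `m6a_model`.
#' @param path Output file path (conventionally `.m6apred.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m6a_model"))
  meta <- list(
    format = .BUNDLE_FORMAT,
    code_table = model$encoding_config$code_table,
    encoding_config = unclass(model$encoding_config),
    best_params = model$best_params,
    cv_accuracy = model$cv_accuracy,
    folds = model$folds,
    seed = model$seed,
    trained_at = model$trained_at,
    n_train = model$n_train
  )
  bundle <- list(
    format = .BUNDLE_FORMAT,
    code_table = model$encoding_config$code_table,
    meta_json = jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
    selected_columns = model$selected_columns,
    booster_raw = xgboost::xgb.save.raw(model$booster)
  )
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param path Bundle file path.
#' @return An `m6a_model` whose predictions are identical to the saved model's.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model bundle '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  required <- c("format", "code_table", "meta_json", "selected_columns",
                "booster_raw")
  if (!is.list(bundle) || !all(required %in% names(bundle))) {
    stop("file '", path, "' is not a valid model bundle (missing fields)",
         call. = FALSE)
  }
  if (bundle$format != .BUNDLE_FORMAT) {
    stop("model bundle format ", bundle$format, " is not supported by this ",
         "library version (expected ", .BUNDLE_FORMAT, ")", call. = FALSE)
  }
  if (!identical(bundle$code_table, code_table_version())) {
    stop("model bundle was built with dinucleotide code table '",
         bundle$code_table, "' but this library uses '",
         code_table_version(), "'; refusing to load to avoid silently ",
         "mismatched encodings. Retrain the model.", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(bundle$meta_json)
  booster <- xgboost::xgb.load.raw(bundle$booster_raw)
  structure(
    list(
      booster = booster,
      selected_columns = bundle$selected_columns,
      encoding_config = structure(as.list(meta$encoding_config),
                                  class = "m6a_encoding_config"),
      best_params = as.list(meta$best_params),
      cv_accuracy = meta$cv_accuracy,
      grid_results = NULL,
      folds = meta$folds,
      seed = meta$seed,
      trained_at = meta$trained_at,
      n_train = meta$n_train
    ),
    class = "m6a_model"
  )
}
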