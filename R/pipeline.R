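#' Full training pipeline: clean, encode, select, tune, evaluate
#'
#' Runs the two-step prediction framework end to end on a labeled dataset:
#' (1) encode every window with the combined DBE + LPSDF descriptor;
#' (2) rank features by F-score and choose the accuracy-maximizing prefix by
#' sequential forward search; (3) tune the gradient-boosted tree classifier by
#' exhaustive grid search on the selected columns and refit on all data;
#' (4) report pooled stratified cross-validated performance.
#'
#' `selection_mode` controls where selection happens relative to the reported
#' evaluation. `"flat"` (the reference protocol) selects once on the full data
#' and then cross-validates on the restricted matrix — simple, but the
#' evaluation sees features chosen using the test folds and is optimistically
#' biased. `"nested"` repeats selection inside every training fold, giving an
#' unbiased (and slower) estimate. `"none"` skips selection.
#'
#' @param data An `m6a_dataset` (e.g. from [assemble_dataset()] or
#'   [generate_synthetic()]).
#' @param seed Master seed for every stochastic step.
#' @param folds Folds of the reported cross-validation.
#' @param grid [m6a_grid()] searched during training; `NULL` fits
#'   `default_params` directly.
#' @param default_params Classifier parameters used when `grid` is `NULL`,
#'   and inside nested folds.
#' @param selection_mode `"flat"`, `"nested"` or `"none"`.
#' @param sfs_folds,sfs_stride Inner-CV folds and subset-size stride of the
#'   SFS (see [sfs_select()]).
#' @param evaluate Compute the cross-validated report? (Skip for speed when
#'   only the fitted model is wanted.)
#' @return A list of class `m6a_run`: `model` (an `m6a_model`), `selection`
#'   (an `m6a_selection`, or `NULL` for `"none"`), `metrics` (an
#'   `m6a_metrics`, or `NULL` when `evaluate = FALSE`), and the echoed
#'   configuration.
#' @export
run_train <- function(data, seed = 1L, folds = 10L, grid = m6a_grid(),
                      default_params = list(max_depth = 3L,
                                            learning_rate = 0.3,
                                            n_estimators = 10L),
                      selection_mode = c("flat", "nested", "none"),
                      sfs_folds = 10L, sfs_stride = 1L, evaluate = TRUE) {
  stopifnot(inherits(data, "m6a_dataset"))
  selection_mode <- match.arg(selection_mode)
  mat <- encode_dataset(data)
  labels <- data$labels
  enc <- m6a_encoding_config(window_length = data$window_length)

  selection <- NULL
  model_cols <- colnames(mat)
  if (selection_mode != "none") {
    selection <- sfs_select(mat, labels, trainer = xgb_trainer(seed = seed),
                            folds = sfs_folds, seed = seed,
                            stride = sfs_stride)
    model_cols <- selection$optimal_columns
  }

  if (is.null(grid)) {
    grid_fit <- m6a_grid(max_depth = default_params$max_depth,
                         learning_rate = default_params$learning_rate,
                         n_estimators = default_params$n_estimators)
  } else {
    grid_fit <- grid
  }
  model <- grid_search_train(mat[, model_cols, drop = FALSE], labels,
                             grid = grid_fit, folds = folds, seed = seed,
                             encoding_config = enc)

  metrics <- NULL
  if (isTRUE(evaluate)) {
    config <- if (selection_mode == "nested") {
      m6a_config(params = default_params, grid = grid, selection = TRUE,
                 sfs_folds = min(sfs_folds, 5L), sfs_stride = sfs_stride)
    } else {
      m6a_config(params = default_params, grid = grid,
                 selected_columns = model_cols)
    }
    metrics <- cross_validate(mat, config = config, folds = folds,
                              seed = seed, labels = labels)
  }

  structure(
    list(model = model, selection = selection, metrics = metrics,
         selection_mode = selection_mode, seed = as.integer(seed),
         folds = as.integer(folds)),
    class = "m6a_run"
  )
}

#' @export
print.m6a_run <- function(x, ...) {
  cat("m6a_run (selection mode: ", x$selection_mode, ", seed ", x$seed,
      ")\n", sep = "")
  print(x$model)
  if (!is.null(x$selection)) print(x$selection)
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Predict m6A sites for a query FASTA file
#'
#' Reads and normalizes the query windows, skips (or aborts on) records whose
#' length does not match the model, scores the rest, and optionally writes a
#' predictions TSV (`id`, `score`, `label`).
#'
#' @param model An `m6a_model` (or a bundle path, loaded via [load_model()]).
#' @param fasta_path Query FASTA.
#' @param out_path Optional output TSV path.
#' @param strict Abort on any wrong-length record instead of skipping it.
#' @return Data frame of predictions; skipped records are reported in the
#'   `skipped` attribute (ids and observed lengths).
#' @export
predict_fasta <- function(model, fasta_path, out_path = NULL, strict = FALSE) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "m6a_model"))
  seqs <- read_fasta(fasta_path)
  expected <- model$encoding_config$window_length
  lens <- nchar(seqs)
  bad <- lens != expected
  if (any(bad)) {
    msg <- paste0(sum(bad), " record(s) do not match the model window length (",
                  expected, " nt): ",
                  paste(utils::head(names(seqs)[bad], 5L), collapse = ", "))
    if (isTRUE(strict)) stop(msg, call. = FALSE)
    warning(msg, "; skipping them", call. = FALSE)
  }
  keep <- seqs[!bad]
  if (length(keep) == 0L) {
    stop("no query sequences of the expected length ", expected, " nt",
         call. = FALSE)
  }
  preds <- predict(model, keep)
  attr(preds, "skipped") <- data.frame(id = names(seqs)[bad],
                                       length = lens[bad])
  if (!is.null(out_path)) {
    utils::write.table(preds, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  preds
}
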