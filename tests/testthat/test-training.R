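test_that("grid validation rejects empty or non-positive ranges", {
  expect_error(m6a_grid(max_depth = integer(0)), "non-empty")
  expect_error(m6a_grid(learning_rate = c(0.1, -0.2)), "positive")
  g <- m6a_grid()
  expect_identical(g$max_depth, 2:10)
  expect_equal(g$learning_rate, seq(0.1, 0.8, by = 0.1))
  expect_identical(g$n_estimators, 1:10)
})

test_that("a single-point grid is selected trivially and separable data is learned", {
  sep <- make_separable_data(n = 200L, seed = 80L)
  g1 <- m6a_grid(max_depth = 3L, learning_rate = 0.3, n_estimators = 8L)
  mod <- grid_search_train(sep$mat, sep$labels, grid = g1, folds = 5L,
                           seed = 80L,
                           encoding_config = m6a_encoding_config(NA))
  expect_identical(mod$best_params,
                   list(max_depth = 3L, learning_rate = 0.3, n_estimators = 8L))
  expect_gte(mod$cv_accuracy, 0.99)

  mod2 <- grid_search_train(sep$mat, sep$labels, grid = small_grid(),
                            folds = 5L, seed = 80L,
                            encoding_config = m6a_encoding_config(NA))
  expect_gte(mod2$cv_accuracy, 0.99)
  expect_equal(nrow(mod2$grid_results), 8L)
})

test_that("grid search is deterministic and canonical under enumeration order", {
  sep <- make_separable_data(n = 120L, seed = 81L)
  m1 <- grid_search_train(sep$mat, sep$labels, grid = small_grid(), folds = 4L,
                          seed = 7L, encoding_config = m6a_encoding_config(NA))
  m2 <- grid_search_train(sep$mat, sep$labels, grid = small_grid(), folds = 4L,
                          seed = 7L, encoding_config = m6a_encoding_config(NA))
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(predict(m1, sep$mat)$score, predict(m2, sep$mat)$score)

  # a grid given in scrambled order yields the same canonical winner
  gs <- m6a_grid(max_depth = c(4L, 2L), learning_rate = c(0.3, 0.1),
                 n_estimators = c(10L, 5L))
  m3 <- grid_search_train(sep$mat, sep$labels, grid = gs, folds = 4L,
                          seed = 7L, encoding_config = m6a_encoding_config(NA))
  expect_identical(m3$best_params, m1$best_params)

  # ties break toward fewer rounds, then shallower, then slower learning:
  # on perfectly separable data many points reach equal accuracy
  expect_equal(m1$cv_accuracy,
               max(m1$grid_results$accuracy))
})

test_that("predict on sequences enforces the model window length and 0.5 threshold", {
  spec <- synthetic_spec(60, 60, window_length = 11, motif_probability = 1,
                         seed = 82)
  d <- generate_synthetic(spec)
  mat <- encode_dataset(d)
  mod <- grid_search_train(mat, d$labels, grid = small_grid(), folds = 5L,
                           seed = 82L,
                           encoding_config = m6a_encoding_config(11))
  preds <- predict(mod, setNames(d$sequences, d$ids))
  expect_identical(preds$label, as.integer(preds$score >= 0.5))
  # training positives from strongly planted signal score above 0.5
  expect_true(all(preds$label[d$labels == 1L] == 1L))

  expect_error(predict(mod, c(q = strrep("A", 13))),
               "expects 11 nt but 'q' has 13 nt")
})

test_that("model bundles round-trip through disk with identical predictions", {
  spec <- synthetic_spec(50, 50, window_length = 11, seed = 83)
  d <- generate_synthetic(spec)
  mat <- encode_dataset(d)
  mod <- grid_search_train(mat, d$labels, grid = small_grid(), folds = 5L,
                           seed = 83L,
                           encoding_config = m6a_encoding_config(11))

  probe_spec <- synthetic_spec(50, 50, window_length = 11, seed = 84)
  probe <- generate_synthetic(probe_spec)
  probe_seqs <- setNames(probe$sequences, probe$ids)

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mod, path)
  mod2 <- load_model(path)
  expect_identical(predict(mod2, probe_seqs), predict(mod, probe_seqs))
  expect_identical(mod2$selected_columns, mod$selected_columns)
  expect_identical(mod2$best_params, mod$best_params)
  expect_identical(mod2$encoding_config$window_length,
                   mod$encoding_config$window_length)
})

test_that("stale or corrupted bundles are refused with clear messages", {
  spec <- synthetic_spec(30, 30, window_length = 7, seed = 85)
  d <- generate_synthetic(spec)
  mod <- grid_search_train(encode_dataset(d), d$labels,
                           grid = m6a_grid(3L, 0.3, 5L), folds = 3L,
                           seed = 85L, encoding_config = m6a_encoding_config(7))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mod, path)

  stale <- readRDS(path)
  stale$code_table <- "dbe-2bit-v0"
  stale_path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(stale, stale_path)
  expect_error(load_model(stale_path), "code table")

  corrupt <- withr::local_tempfile(fileext = ".rds")
  writeLines("this is not a bundle", corrupt)
  expect_error(load_model(corrupt), "cannot read model bundle")

  wrong <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), wrong)
  expect_error(load_model(wrong), "not a valid model bundle")
})
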