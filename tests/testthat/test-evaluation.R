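test_that("metric formulas match hand-worked confusion tables", {
  perfect <- compute_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)

  m <- compute_metrics(tp = 8, fn = 2, tn = 7, fp = 3)
  expect_equal(m$sn, 0.8)
  expect_equal(m$sp, 0.7)
  expect_equal(m$acc, 0.75)
  expect_equal(m$mcc, 50 / sqrt(9900))

  # everything misclassified: MCC hits -1 (denominator is positive here)
  worst <- compute_metrics(tp = 0, tn = 0, fp = 5, fn = 5)
  expect_equal(worst$acc, 0)
  expect_equal(worst$mcc, -1)

  # true 0/0 degenerate table: all predictions negative on all-negative truth
  degen <- suppressWarnings(compute_metrics(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_equal(degen$mcc, 0)

  expect_warning(compute_metrics(tp = 0, tn = 5, fp = 5, fn = 0),
                 "sensitivity undefined")
})

test_that("compute_metrics agrees with per-sample counting on random predictions", {
  withr::with_seed(91, {
    for (i in 1:300) {
      n <- sample(4:80, 1L)
      actual <- rbinom(n, 1L, 0.5)
      predicted <- rbinom(n, 1L, 0.5)
      counts <- confusion_counts(predicted, actual)
      # naive per-sample loop oracle
      tp <- tn <- fp <- fn <- 0L
      for (j in seq_len(n)) {
        if (predicted[j] == 1L && actual[j] == 1L) tp <- tp + 1L
        else if (predicted[j] == 0L && actual[j] == 0L) tn <- tn + 1L
        else if (predicted[j] == 1L) fp <- fp + 1L
        else fn <- fn + 1L
      }
      expect_identical(counts, list(tp = tp, tn = tn, fp = fp, fn = fn))
      got <- suppressWarnings(compute_metrics(counts))
      want <- metrics_oracle(tp, tn, fp, fn)
      expect_equal(got$acc, want$acc)
      expect_equal(got$mcc, want$mcc)
      if (tp + fn > 0L) expect_equal(got$sn, want$sn)
      if (tn + fp > 0L) expect_equal(got$sp, want$sp)
    }
  })
})

test_that("sensitivity and specificity swap under label flipping", {
  withr::with_seed(92, {
    actual <- rbinom(60, 1L, 0.5)
    predicted <- rbinom(60, 1L, 0.5)
  })
  a <- suppressWarnings(compute_metrics(confusion_counts(predicted, actual)))
  b <- suppressWarnings(compute_metrics(confusion_counts(1L - predicted,
                                                         1L - actual)))
  expect_equal(a$sn, b$sp)
  expect_equal(a$sp, b$sn)
  expect_equal(a$acc, b$acc)
  expect_equal(a$mcc, b$mcc)
})

test_that("ROC sweep handles perfect, tied, and hand-counted score vectors", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1L, 0L), 5))$auc, 0.5)
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting, ties included", {
  withr::with_seed(93, {
    for (i in 1:200) {
      n <- sample(6:60, 1L)
      labels <- c(1L, 0L, rbinom(n - 2L, 1L, 0.5))
      # coarse scores force plenty of ties
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(roc_auc(scores, labels)$auc,
                   auc_pair_oracle(scores, labels))
    }
  })
})

test_that("AUC sweep agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(94, {
    for (i in 1:20) {
      labels <- c(1L, 0L, rbinom(48L, 1L, 0.5))
      scores <- round(runif(50L), 2L)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(scores, labels)$auc, ref)
    }
  })
})

test_that("pooled cross-validation learns separable data and conserves counts", {
  sep <- make_separable_data(n = 100L, seed = 95L)
  rep <- cross_validate(sep$mat, config = m6a_config(), folds = 10L,
                        seed = 95L, labels = sep$labels)
  expect_gte(rep$acc, 0.99)
  expect_equal(rep$protocol, "cv10")
  with(rep$counts, expect_equal(tp + tn + fp + fn, 100))
  expect_equal(rep$acc, (rep$counts$tp + rep$counts$tn) / rep$n)
  expect_length(rep$scores, 100L)
  expect_false(anyNA(rep$scores))

  rep2 <- cross_validate(sep$mat, config = m6a_config(), folds = 10L,
                         seed = 95L, labels = sep$labels)
  expect_identical(rep$scores, rep2$scores)
  expect_identical(rep$counts, rep2$counts)

  expect_error(cross_validate(sep$mat[1:8, ], folds = 10L, seed = 1L,
                              labels = sep$labels[1:8]),
               "jackknife")
})

test_that("cross-validation on label-shuffled data gives chance-level AUC", {
  withr::with_seed(96, {
    mat <- matrix(rnorm(500 * 8), ncol = 8L,
                  dimnames = list(NULL, paste0("x", 1:8)))
    labels <- sample(rep(c(1L, 0L), each = 250L))
  })
  rep <- cross_validate(mat, config = m6a_config(), folds = 10L, seed = 96L,
                        labels = labels)
  expect_gt(rep$auc, 0.43)
  expect_lt(rep$auc, 0.57)
})

test_that("jackknife pools n leave-one-out predictions and guards runtime", {
  sep <- make_separable_data(n = 10L, d = 2L, seed = 97L)
  rep <- jackknife(sep$mat, config = m6a_config(), seed = 97L,
                   labels = sep$labels)
  expect_equal(rep$protocol, "jackknife")
  expect_equal(rep$acc, 1.0)
  with(rep$counts, expect_equal(tp + tn + fp + fn, 10))

  rep2 <- jackknife(sep$mat, config = m6a_config(), seed = 97L,
                    labels = sep$labels)
  expect_identical(rep$scores, rep2$scores)

  expect_error(jackknife(sep$mat, seed = 1L, labels = sep$labels, cap = 5L),
               "force = TRUE")
})

test_that("metrics JSON and ROC TSV exports are well-formed", {
  m <- compute_metrics(tp = 8, fn = 2, tn = 7, fp = 3)
  parsed <- jsonlite::fromJSON(metrics_json(m))
  expect_equal(parsed$acc, 0.75)
  parsed_pct <- jsonlite::fromJSON(metrics_json(m, percent = TRUE))
  expect_equal(parsed_pct$sn, 80)
  expect_equal(parsed_pct$mcc, 50 / sqrt(9900)) # MCC is never scaled

  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_roc(r, tsv)
  back <- read.delim(tsv)
  expect_equal(back$fpr, r$points$fpr)
})
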