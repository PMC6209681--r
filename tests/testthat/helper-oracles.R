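# Shared fixtures and independent oracles used across the suite.

random_seq <- function(l) {
  paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
}

# Naive double-loop LPSDF oracle: for each i, count overlapping occurrences of
# the dinucleotide X_{i-1}X_i within the prefix X_1..X_i by scanning every
# ending position, then divide by the prefix length i.
lpsdf_oracle <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  l <- length(chars)
  f <- numeric(l - 1L)
  for (i in 2:l) {
    di <- paste0(chars[i - 1L], chars[i])
    count <- 0L
    for (j in 2:i) {
      if (paste0(chars[j - 1L], chars[j]) == di) count <- count + 1L
    }
    f[i - 1L] <- count / i
  }
  f
}

# Direct transcription of the published metric formulas.
metrics_oracle <- function(tp, tn, fp, fn) {
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  list(
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / (tp + fn + tn + fp),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  )
}

# AUC as the normalized Mann-Whitney pair count (ties worth 1/2).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Informative/noise selection benchmark: 5 columns equal to the label plus
# Gaussian noise (sd sigma), 95 pure-noise columns, balanced labels.
make_informative_matrix <- function(n = 400L, sigma = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), each = n %/% 2L)
    informative <- matrix(rep(labels, 5L), ncol = 5L) +
      matrix(rnorm(n * 5L, sd = sigma), ncol = 5L)
    noise <- matrix(rnorm(n * 95L), ncol = 95L)
    mat <- cbind(informative, noise)
    colnames(mat) <- c(paste0("inf_", 1:5), paste0("noise_", 1:95))
    list(mat = mat, labels = labels, informative = paste0("inf_", 1:5))
  })
}

# Two well-separated Gaussian classes (separation ~6 sd) for classifier tests.
make_separable_data <- function(n = 200L, d = 4L, seed = 1L) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), each = n %/% 2L)
    mat <- matrix(rnorm(n * d), ncol = d)
    mat[labels == 1L, 1L] <- mat[labels == 1L, 1L] + 6
    colnames(mat) <- paste0("x", seq_len(d))
    list(mat = mat, labels = labels)
  })
}

small_grid <- function() {
  m6a_grid(max_depth = c(2L, 4L), learning_rate = c(0.1, 0.3),
           n_estimators = c(5L, 10L))
}
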