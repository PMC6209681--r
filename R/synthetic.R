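#' Specification for a synthetic benchmark dataset
#'
#' Describes a dataset with the structural properties of the published m6A
#' benchmarks: equal-purpose positive and negative classes, an odd fixed
#' window length, and a central adenosine in every window of both classes
#' (negatives are A-centered windows without a site). Positives optionally
#' carry a planted positional signal: a short motif written around the center
#' (default `"GAC"`, echoing the DRACH-like consensus context with the
#' methylated A in the middle) with probability `motif_probability`, plus
#' optional per-position dinucleotide biases. Since both feature descriptors
#' are dinucleotide-positional, a dinucleotide-positional signal is exactly
#' what they should recover.
#'
#' @param n_pos,n_neg Class sizes.
#' @param window_length Odd window length >= 5 (benchmarks use 41/51/101).
#' @param motif Residue string over `{A,C,G,U}` planted in positives; must
#'   contain an `A`, which is aligned with the window center so the central
#'   adenosine is never overwritten.
#' @param motif_probability Probability that a given positive carries the
#'   motif.
#' @param background Per-residue sampling probabilities for A, C, G, U
#'   (default uniform).
#' @param positional_bias Optional list of `list(position, dinucleotide,
#'   prob)` entries: in positives, `dinucleotide` is written at 1-based end
#'   position `position` with probability `prob` (skipped if it would replace
#'   the central A with a non-A residue).
#' @param seed Integer seed; the dataset is fully determined by the spec.
#' @return A list of class `m6a_synth_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, window_length = 41L, motif = "GAC",
                           motif_probability = 1.0,
                           background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           positional_bias = NULL, seed = 1L) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  window_length <- as.integer(window_length)
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  if (window_length < 5L || window_length %% 2L == 0L) {
    stop("window_length must be an odd integer >= 5", call. = FALSE)
  }
  if (nchar(motif) > window_length) {
    stop("motif (", nchar(motif), " nt) is longer than the window (",
         window_length, " nt)", call. = FALSE)
  }
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (any(!motif_chars %in% c("A", "C", "G", "U"))) {
    stop("motif must be over {A,C,G,U}", call. = FALSE)
  }
  a_pos <- which(motif_chars == "A")
  if (length(a_pos) == 0L) {
    stop("motif must contain an A to align with the central adenosine",
         call. = FALSE)
  }
  stopifnot(motif_probability >= 0, motif_probability <= 1)
  background <- background / sum(background)
  if (length(background) != 4L) stop("background must have 4 entries", call. = FALSE)
  names(background) <- c("A", "C", "G", "U")
  center <- (window_length + 1L) %/% 2L
  # align the A nearest the motif's middle with the window center
  anchor <- a_pos[which.min(abs(a_pos - (nchar(motif) + 1) / 2))]
  motif_start <- center - anchor + 1L
  if (motif_start < 1L || motif_start + nchar(motif) - 1L > window_length) {
    stop("motif does not fit in the window when centered on its A", call. = FALSE)
  }
  if (!is.null(positional_bias)) {
    for (b in positional_bias) {
      stopifnot(all(c("position", "dinucleotide", "prob") %in% names(b)))
      if (b$position < 2L || b$position > window_length) {
        stop("positional_bias end position must lie in 2..window_length",
             call. = FALSE)
      }
      if (nchar(b$dinucleotide) != 2L ||
          grepl("[^ACGU]", b$dinucleotide)) {
        stop("positional_bias dinucleotide must be 2 residues over {A,C,G,U}",
             call. = FALSE)
      }
      stopifnot(b$prob >= 0, b$prob <= 1)
    }
  }
  structure(
    list(n_pos = n_pos, n_neg = n_neg, window_length = window_length,
         motif = motif, motif_start = motif_start,
         motif_probability = motif_probability, background = background,
         positional_bias = positional_bias, seed = as.integer(seed)),
    class = "m6a_synth_spec"
  )
}

#' Generate a synthetic labeled dataset
#'
#' Background residues are sampled i.i.d. from `spec$background`; the central
#' position is forced to `A` in every window of both classes. Each positive
#' then receives the motif (with probability `motif_probability`) and any
#' positional biases. Output is fully determined by `spec$seed`.
#'
#' @param spec An [synthetic_spec()].
#' @return An `m6a_dataset` with ids `pos_<i>` / `neg_<i>`, positives first.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "m6a_synth_spec"))
  l <- spec$window_length
  center <- (l + 1L) %/% 2L
  nucs <- names(spec$background)
  withr::with_seed(spec$seed, {
    n <- spec$n_pos + spec$n_neg
    res <- matrix(sample(nucs, n * l, replace = TRUE, prob = spec$background),
                  nrow = n, ncol = l)
    res[, center] <- "A"
    motif_chars <- strsplit(spec$motif, "", fixed = TRUE)[[1L]]
    span <- spec$motif_start:(spec$motif_start + length(motif_chars) - 1L)
    plant <- stats::runif(spec$n_pos) < spec$motif_probability
    for (i in which(plant)) {
      res[i, span] <- motif_chars
    }
    if (!is.null(spec$positional_bias)) {
      for (b in spec$positional_bias) {
        di <- strsplit(b$dinucleotide, "", fixed = TRUE)[[1L]]
        cols <- c(b$position - 1L, b$position)
        hit <- stats::runif(spec$n_pos) < b$prob
        # never overwrite the central A with a non-A residue
        if (center %in% cols && di[match(center, cols)] != "A") next
        for (i in which(hit)) res[i, cols] <- di
      }
    }
  })
  seqs <- apply(res, 1L, paste, collapse = "")
  ids <- c(sprintf("pos_%04d", seq_len(spec$n_pos)),
           sprintf("neg_%04d", seq_len(spec$n_neg)))
  m6a_dataset(stats::setNames(seqs, ids),
              c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)))
}

#' Write a benchmark-shaped synthetic dataset to disk
#'
#' Produces `pos.fa` and `neg.fa` in the FASTA dialect [read_fasta()] consumes,
#' plus `manifest.json` recording the full specification (including the seed),
#' which alone suffices to regenerate byte-identical files.
#'
#' @param spec An [synthetic_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a list with `pos`, `neg` and `manifest` paths.
#' @export
write_benchmark_like <- function(spec, out_dir) {
  stopifnot(inherits(spec, "m6a_synth_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  data <- generate_synthetic(spec)
  seqs <- stats::setNames(data$sequences, data$ids)
  pos_path <- file.path(out_dir, "pos.fa")
  neg_path <- file.path(out_dir, "neg.fa")
  write_fasta(seqs[data$labels == 1L], pos_path)
  write_fasta(seqs[data$labels == 0L], neg_path)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(generator = "m6apred::write_benchmark_like",
         code_table = code_table_version(),
         spec = unclass(spec)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(pos = pos_path, neg = neg_path, manifest = manifest))
}

#' Rebuild a synthetic spec from a manifest written by [write_benchmark_like()]
#'
#' @param path Path to `manifest.json`.
#' @return An `m6a_synth_spec` regenerating the identical dataset.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s <- m$spec
  bias <- s$positional_bias
  if (!is.null(bias) && is.data.frame(bias)) {
    bias <- lapply(seq_len(nrow(bias)), function(i) as.list(bias[i, ]))
  }
  synthetic_spec(
    n_pos = s[["n_pos"]], n_neg = s[["n_neg"]],
    window_length = s[["window_length"]], motif = s[["motif"]],
    motif_probability = s[["motif_probability"]],
    background = unlist(s[["background"]]), positional_bias = bias,
    seed = s[["seed"]]
  )
}
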