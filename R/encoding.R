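# Per-nucleotide 2-bit codes. A dinucleotide's 4-bit code is the
# concatenation first-then-second residue; this is the unique per-nucleotide
# scheme consistent with the four published anchor codes
# AA=(0,0,0,0), AU=(0,0,0,1), AC=(0,0,1,0), GG=(1,1,1,1).
.NUC_ORDER <- c("A", "C", "G", "U")
.NUC_BITS <- rbind(
  A = c(0L, 0L),
  U = c(0L, 1L),
  C = c(1L, 0L),
  G = c(1L, 1L)
)

# 16 x 4 lookup matrix indexed by 4*(first-1)+second over .NUC_ORDER indices
.DINUC_TABLE <- local({
  m <- matrix(0L, nrow = 16L, ncol = 4L)
  rn <- character(16L)
  for (i in seq_along(.NUC_ORDER)) {
    for (j in seq_along(.NUC_ORDER)) {
      k <- 4L * (i - 1L) + j
      m[k, ] <- c(.NUC_BITS[.NUC_ORDER[i], ], .NUC_BITS[.NUC_ORDER[j], ])
      rn[k] <- paste0(.NUC_ORDER[i], .NUC_ORDER[j])
    }
  }
  rownames(m) <- rn
  m
})

#' Version tag of the dinucleotide code table
#'
#' Stored in every saved model bundle; a bundle whose tag differs from the
#' running library's is refused at load time, so predictions can never be made
#' with a mismatched feature encoding.
#'
#' @return A character scalar.
#' @export
code_table_version <- function() "dbe-2bit-v1"

#' The 16-dinucleotide binary code table
#'
#' Each of the 16 RNA dinucleotides maps to a distinct 4-bit code, formed by
#' concatenating per-nucleotide 2-bit codes (A=00, U=01, C=10, G=11), first
#' residue then second. The mapping is a bijection.
#'
#' @return A data frame with columns `dinucleotide`, `b1`..`b4`.
#' @examples
#' dinucleotide_code_table()
#' @export
dinucleotide_code_table <- function() {
  data.frame(
    dinucleotide = rownames(.DINUC_TABLE),
    b1 = .DINUC_TABLE[, 1L], b2 = .DINUC_TABLE[, 2L],
    b3 = .DINUC_TABLE[, 3L], b4 = .DINUC_TABLE[, 4L],
    row.names = NULL
  )
}

.nuc_index <- function(chars, context = "sequence") {
  idx <- match(chars, .NUC_ORDER)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("invalid residue(s) in ", context, ": ",
         paste(bad, collapse = ", "),
         " (sequences must be normalized to {A,C,G,U})", call. = FALSE)
  }
  idx
}

#' 4-bit binary code of a dinucleotide
#'
#' @param dinuc A 2-residue string over `{A,C,G,U}` (normalize `T` to `U`
#'   first, e.g. with [read_fasta()]).
#' @return Integer vector of 4 bits.
#' @examples
#' dinucleotide_code("AA") # 0 0 0 0
#' dinucleotide_code("GG") # 1 1 1 1
#' @export
dinucleotide_code <- function(dinuc) {
  stopifnot(is.character(dinuc), length(dinuc) == 1L)
  if (nchar(dinuc) != 2L) {
    stop("a dinucleotide has exactly 2 residues, got '", dinuc, "'",
         call. = FALSE)
  }
  chars <- strsplit(dinuc, "", fixed = TRUE)[[1L]]
  idx <- .nuc_index(chars, context = paste0("dinucleotide '", dinuc, "'"))
  unname(.DINUC_TABLE[4L * (idx[1L] - 1L) + idx[2L], ])
}

# integer codes 1..16 of the l-1 overlapping dinucleotides of one sequence
.dinuc_indices <- function(seq) {
  l <- nchar(seq)
  if (l < 2L) {
    stop("sequence must have length >= 2 to contain a dinucleotide (got ",
         l, ")", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- .nuc_index(chars)
  4L * (idx[-l] - 1L) + idx[-1L]
}

#' Dinucleotide binary encoding (DBE) of one sequence
#'
#' Encodes the `l - 1` overlapping dinucleotides of a length-`l` sequence,
#' 5'-to-3', each as its 4-bit code, yielding a `4 * (l - 1)`-dimensional 0/1
#' vector (160 dimensions for a 41-nt window). The descriptor captures which
#' dinucleotide sits at each position.
#'
#' @param seq A sequence string over `{A,C,G,U}`, length >= 2.
#' @return Integer vector of `4 * (nchar(seq) - 1)` bits.
#' @examples
#' encode_dbe("AAC") # 0 0 0 0 0 0 1 0
#' @export
encode_dbe <- function(seq) {
  di <- .dinuc_indices(seq)
  as.integer(t(.DINUC_TABLE[di, , drop = FALSE]))
}

#' Local position-specific dinucleotide frequency (LPSDF) of one sequence
#'
#' For each position `i = 2..l`, the descriptor is
#' `f_i = C(X_{i-1} X_i) / |N_i|`, where `|N_i| = i` is the length of the
#' `i`-th prefix `X_1..X_i` and `C` counts the (overlapping) occurrences of
#' the dinucleotide `X_{i-1} X_i` within that prefix. The occurrence ending at
#' `i` itself always counts, and a length-`i` prefix holds at most `i - 1`
#' dinucleotides, so every `f_i` lies strictly inside `(0, 1)`.
#' Values decay along the sequence unless a dinucleotide
#' recurs, so the descriptor mixes positional and compositional information.
#'
#' @param seq A sequence string over `{A,C,G,U}`, length >= 2.
#' @return Numeric vector `(f_2, ..., f_l)` of length `nchar(seq) - 1`.
#' @examples
#' encode_lpsdf("AAAA") # 1/2 2/3 3/4
#' encode_lpsdf("ACGU") # 1/2 1/3 1/4
#' @export
encode_lpsdf <- function(seq) {
  di <- .dinuc_indices(seq)
  counts <- integer(16L)
  f <- numeric(length(di))
  for (k in seq_along(di)) {
    d <- di[k]
    counts[d] <- counts[d] + 1L
    f[k] <- counts[d] / (k + 1L)  # prefix X_1..X_i has length i = k + 1
  }
  f
}

#' Encode a labeled dataset as a feature matrix
#'
#' Each row is the concatenation `encode_dbe(seq)` then `encode_lpsdf(seq)`,
#' giving `d = 5 * (l - 1)` columns for windows of length `l` (200 for 41-nt
#' windows: 160 binary + 40 frequency features). The fixed DBE-then-LPSDF
#' order lets feature selection report which descriptor every selected column
#' came from. Features are used raw: tree ensembles are scale-invariant and no
#' standardization is applied.
#'
#' @param x An `m6a_dataset` or a named character vector of uniform-length
#'   sequences.
#' @return A numeric matrix with row names set to sequence ids, column names
#'   `DBE_p<i>_b<j>` / `LPSDF_p<i>` (`i` the 1-based end position of the
#'   dinucleotide), and attributes `descriptor`, `position` and
#'   `window_length` describing the columns.
#' @seealso [feature_meta()], [write_feature_matrix()]
#' @export
encode_dataset <- function(x) {
  if (inherits(x, "m6a_dataset")) {
    seqs <- stats::setNames(x$sequences, x$ids)
  } else {
    seqs <- x
  }
  if (length(seqs) == 0L) stop("empty dataset: nothing to encode", call. = FALSE)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop("sequences must share one window length to be encoded as a matrix",
         call. = FALSE)
  }
  l <- lens
  if (l < 2L) stop("window length must be >= 2", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))

  n <- length(seqs)
  d_dbe <- 4L * (l - 1L)
  mat <- matrix(NA_real_, nrow = n, ncol = d_dbe + (l - 1L))
  for (r in seq_len(n)) {
    row <- tryCatch(
      c(encode_dbe(seqs[[r]]), encode_lpsdf(seqs[[r]])),
      error = function(e) {
        stop("failed to encode sequence '", ids[r], "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    mat[r, ] <- row
  }
  pos <- 2:l
  colnames(mat) <- c(
    paste0("DBE_p", rep(pos, each = 4L), "_b", rep(1:4, l - 1L)),
    paste0("LPSDF_p", pos)
  )
  rownames(mat) <- ids
  attr(mat, "descriptor") <- c(rep("DBE", d_dbe), rep("LPSDF", l - 1L))
  attr(mat, "position") <- c(rep(pos, each = 4L), pos)
  attr(mat, "window_length") <- l
  mat
}

#' Per-column provenance of an encoded feature matrix
#'
#' @param mat A matrix produced by [encode_dataset()].
#' @return Data frame with columns `column`, `descriptor` (`DBE` or `LPSDF`)
#'   and `position` (1-based end position of the dinucleotide the feature
#'   describes).
#' @export
feature_meta <- function(mat) {
  desc <- attr(mat, "descriptor")
  pos <- attr(mat, "position")
  if (is.null(desc) || is.null(pos)) {
    stop("matrix carries no column metadata; was it made by encode_dataset()?",
         call. = FALSE)
  }
  data.frame(column = colnames(mat), descriptor = desc, position = pos,
             stringsAsFactors = FALSE)
}

#' Write a feature matrix as TSV
#'
#' Header row names the columns; sequence ids go in the first column (`id`).
#'
#' @param mat Matrix from [encode_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
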