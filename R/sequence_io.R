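#' Read fixed-length sequence windows from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file and normalizes every record to the
#' RNA alphabet: lowercase letters are uppercased and `T` is mapped to `U`.
#' DNA-alphabet files therefore load transparently; `U` and `T` share one code
#' in both feature descriptors, so the normalization changes no encoding.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA record
#'   identifiers (first whitespace-delimited token of the header), in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to read FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' The written dialect round-trips through [read_fasta()]: reading the file
#' back reproduces the input vector exactly (sequences are assumed already
#' normalized to `{A,C,G,U}`).
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("no sequences to write", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named to be written as FASTA", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Clean sequence windows, removing irrelevant records
#'
#' Applies the data-cleaning step of the prediction framework: a window is
#' retained only if it (i) has exactly `window_length` residues, (ii) contains
#' no character outside `{A,C,G,U}` (degenerate IUPAC codes such as `N` are
#' rejected, not imputed — both feature descriptors are defined only over the
#' four-letter alphabet), and (iii) if `require_central_a` is `TRUE`, carries
#' an `A` at the central position `(window_length + 1) / 2` (1-based), the
#' candidate methylation site.
#'
#' @param seqs Named character vector of normalized sequences (see
#'   [read_fasta()]).
#' @param window_length Declared window length (>= 2); benchmark windows are
#'   odd-length (41/51/101 nt) so the center is a single residue.
#' @param require_central_a Require the central residue to be `A`? Default
#'   `TRUE`, appropriate for training data where both classes are A-centered;
#'   set `FALSE` for bare prediction inputs.
#' @return A list with components `kept` (named character vector of retained
#'   sequences, input order preserved) and `rejected` (data frame with columns
#'   `id` and `reason`).
#' @seealso [write_rejection_report()]
#' @export
clean_sequences <- function(seqs, window_length, require_central_a = TRUE) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 2L) {
    stop("window_length must be an integer >= 2", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))

  reason <- rep(NA_character_, length(seqs))
  wrong_len <- nchar(seqs) != window_length
  reason[wrong_len] <- "wrong length"

  bad_alpha <- !wrong_len & grepl("[^ACGU]", seqs)
  reason[bad_alpha] <- "non-ACGU character"

  if (isTRUE(require_central_a)) {
    center <- (window_length + 1L) %/% 2L
    ok <- is.na(reason)
    not_a <- ok & substr(seqs, center, center) != "A"
    reason[not_a] <- "central residue not A"
  }

  keep <- is.na(reason)
  if (!any(keep)) {
    stop("all ", length(seqs), " sequences were rejected during cleaning; ",
         "check the window length (", window_length, ") and alphabet of the input",
         call. = FALSE)
  }
  list(
    kept = seqs[keep],
    rejected = data.frame(
      id = ids[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Write a cleaning rejection report as TSV
#'
#' @param rejected The `rejected` data frame from [clean_sequences()].
#' @param path Output TSV path (columns: id, reason).
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejected, path) {
  stopifnot(is.data.frame(rejected), all(c("id", "reason") %in% names(rejected)))
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a labeled dataset of uniform-length sequence windows
#'
#' @param sequences Named character vector of normalized sequences sharing one
#'   length.
#' @param labels Integer vector of class labels parallel to `sequences`;
#'   `1` marks a true m6A site, `0` a non-site.
#' @return An object of class `m6a_dataset`: a list with elements `ids`,
#'   `sequences`, `labels` and `window_length`.
#' @export
m6a_dataset <- function(sequences, labels) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  labels <- as.integer(labels)
  if (length(labels) != length(sequences)) {
    stop("labels must have exactly one entry per sequence (",
         length(labels), " labels for ", length(sequences), " sequences)",
         call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (non-m6A site) or 1 (true m6A site)", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- as.character(seq_along(sequences))
    common <- as.integer(names(which.max(table(lens))))
    off <- ids[lens != common]
    stop("sequences do not share one window length; offending ids: ",
         paste(utils::head(off, 10L), collapse = ", "),
         if (length(off) > 10L) ", ..." else "", call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sequences))
  structure(
    list(ids = unname(ids), sequences = unname(sequences),
         labels = labels, window_length = lens[[1L]]),
    class = "m6a_dataset"
  )
}

#' Assemble a labeled dataset from positive and negative sequence sets
#'
#' Positives are windows centered on a true m6A site (label 1); negatives are
#' A-centered windows without a detected site (label 0). Counts and input
#' order are preserved: positives first, then negatives.
#'
#' @param positives,negatives Named character vectors of normalized sequences.
#' @return An `m6a_dataset`.
#' @export
assemble_dataset <- function(positives, negatives) {
  if (length(positives) == 0L) {
    stop("no positive sequences: cannot train a two-class model", call. = FALSE)
  }
  if (length(negatives) == 0L) {
    stop("no negative sequences: cannot train a two-class model", call. = FALSE)
  }
  m6a_dataset(c(positives, negatives),
              c(rep(1L, length(positives)), rep(0L, length(negatives))))
}

#' @export
print.m6a_dataset <- function(x, ...) {
  cat("m6a_dataset: ", length(x$sequences), " windows of ", x$window_length,
      " nt (", sum(x$labels == 1L), " positive, ", sum(x$labels == 0L),
      " negative)\n", sep = "")
  invisible(x)
}

#' Read a two-column id/label table
#'
#' Alternative to the two-file (positive/negative FASTA) convention: a
#' headerless TSV with columns `id` and `label` (0/1).
#'
#' @param path TSV path.
#' @return Named integer vector of labels, names are sequence ids.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty label table: ", path, call. = FALSE)
  stats::setNames(tab$label, tab$id)
}
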