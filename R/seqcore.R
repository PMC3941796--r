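#' The 20-letter amino-acid alphabet, alphabetical order
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order, so
#' that the integer code of a residue is its index: A = 1, C = 2, ..., Y = 20.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode an amino-acid sequence as integer residue codes
#'
#' Maps each one-letter residue to its alphabetical index (A = 1 ... Y = 20).
#' Parsing is case-insensitive and surrounding whitespace is ignored.
#'
#' @param raw Character scalar, the sequence.
#' @param strict If `TRUE` (default) any character outside the 20-letter
#'   alphabet (including B, J, O, U, X, Z) is an error naming the offending
#'   position. If `FALSE`, invalid residues are encoded as `NA` so that
#'   downstream window extraction can drop the affected windows.
#' @return Integer vector of codes in 1..20 (with `NA`s when `strict = FALSE`).
#' @examples
#' encode_sequence("NFGAIL")  # 12 5 6 1 8 10
#' @seealso [decode_sequence()], [extract_windows()]
#' @export
encode_sequence <- function(raw, strict = TRUE) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  s <- toupper(gsub("\\s+", "", raw))
  if (nchar(s) == 0L) {
    stop("empty sequence after whitespace stripping")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  codes <- match(chars, AA_ALPHABET)
  if (strict && anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("invalid residue '%s' at position %d", chars[bad], bad))
  }
  codes
}

#' Decode integer residue codes back to a sequence string
#'
#' @param codes Integer vector of codes in 1..20.
#' @return Character scalar.
#' @export
decode_sequence <- function(codes) {
  stopifnot(is.numeric(codes), all(is.finite(codes)),
            all(codes >= 1L), all(codes <= 20L))
  paste(AA_ALPHABET[as.integer(codes)], collapse = "")
}

#' Construct a labeled sequence
#'
#' @param id Character identifier.
#' @param sequence Character sequence (encoded internally) or an integer
#'   code vector.
#' @param label One of `"positive"`, `"negative"`, `"unlabeled"`.
#' @param strict Passed to [encode_sequence()].
#' @return A `labeled_sequence` object: list with `id`, `codes`, `label`.
#' @export
labeled_sequence <- function(id, sequence, label = "unlabeled",
                             strict = TRUE) {
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  codes <- if (is.character(sequence)) {
    encode_sequence(sequence, strict = strict)
  } else {
    stopifnot(all(is.na(sequence) | (sequence >= 1 & sequence <= 20)))
    as.integer(sequence)
  }
  if (length(codes) < 1L) stop("sequence must have length >= 1")
  structure(list(id = as.character(id), codes = codes, label = label),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  sq <- paste(ifelse(is.na(x$codes), "x", AA_ALPHABET[x$codes]),
              collapse = "")
  cat(sprintf("<labeled_sequence> %s [%s] %s (%d aa)\n",
              x$id, x$label, sq, length(x$codes)))
  invisible(x)
}

#' Extract all sliding windows of a sequence
#'
#' Shifts a length-`n` window by one position at a time, yielding
#' `L - n + 1` windows for a length-`L` sequence. Windows containing an
#' invalid (`NA`) residue -- possible only for sequences encoded with
#' `strict = FALSE` -- are dropped with a warning.
#'
#' @param seq A `labeled_sequence`, or an integer code vector.
#' @param n Window length, `>= 2`.
#' @return Integer matrix with one row per window and `n` columns; row
#'   attribute `start` gives the 1-based start position of each window.
#' @export
extract_windows <- function(seq, n) {
  codes <- if (inherits(seq, "labeled_sequence")) seq$codes else as.integer(seq)
  n <- as.integer(n)
  if (n < 2L) stop("window length n must be >= 2")
  L <- length(codes)
  if (L < n) {
    stop(sprintf("sequence length %d is shorter than window length %d", L, n))
  }
  starts <- seq_len(L - n + 1L)
  W <- vapply(seq_len(n), function(j) codes[starts + j - 1L],
              integer(length(starts)))
  W <- matrix(W, nrow = length(starts), ncol = n)
  keep <- rowSums(is.na(W)) == 0L
  if (!all(keep)) {
    warning(sprintf("dropped %d window(s) containing invalid residues",
                    sum(!keep)))
    W <- W[keep, , drop = FALSE]
    starts <- starts[keep]
  }
  attr(W, "start") <- starts
  W
}
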