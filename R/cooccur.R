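#' @keywords internal
#' @noRd
position_pairs <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  cbind(p = idx[, "row"], q = idx[, "col"])
}

# column index of the (a, b) residue-pair cell in the 400-wide plane
#' @noRd
cell_index <- function(a, b) (a - 1L) * 20L + b

new_co_matrix <- function(counts, n, window_count, normalized) {
  structure(list(n = as.integer(n),
                 counts = counts,
                 window_count = as.integer(window_count),
                 normalized = isTRUE(normalized),
                 pairs = position_pairs(n)),
            class = "co_matrix")
}

#' Build a position-specific residue-pair co-occurrence matrix
#'
#' For every unordered position pair `p < q` within a length-`n` window,
#' counts how often residue `a` at position `p` co-occurs with residue `b`
#' at position `q` over a set of windows. The lower-triangle mirror
#' `(q, p, b, a)` is redundant and not stored.
#'
#' @param windows Integer matrix of windows (one row each, `n` columns), as
#'   produced by [extract_windows()], or a list of equal-length code vectors.
#' @param n Window length; defaults to `ncol(windows)`.
#' @return A `co_matrix`: `choose(n, 2)` position-pair planes of 20 x 20
#'   residue-pair cells (stored as a `choose(n,2)` x 400 count matrix), with
#'   `window_count` windows and `normalized = FALSE`. Each plane sums to
#'   `window_count`.
#' @export
build_comatrix <- function(windows, n = NULL) {
  if (is.list(windows)) {
    lens <- lengths(windows)
    if (length(unique(lens)) > 1L) stop("mixed window lengths")
    windows <- do.call(rbind, windows)
  }
  stopifnot(is.matrix(windows))
  if (is.null(n)) n <- ncol(windows)
  if (ncol(windows) != n) {
    stop(sprintf("windows have length %d, expected %d", ncol(windows), n))
  }
  pairs <- position_pairs(n)
  K <- nrow(windows)
  counts <- matrix(0, nrow = nrow(pairs), ncol = 400L)
  for (r in seq_len(nrow(pairs))) {
    if (K > 0L) {
      idx <- cell_index(windows[, pairs[r, "p"]], windows[, pairs[r, "q"]])
      counts[r, ] <- tabulate(idx, nbins = 400L)
    }
  }
  new_co_matrix(counts, n, K, normalized = FALSE)
}

#' Normalize a co-occurrence matrix to unit total mass
#'
#' Divides every cell by `window_count * choose(n, 2)` so the whole matrix
#' sums to 1. Idempotent on already-normalized input; `window_count` is
#' retained as metadata.
#'
#' @param m A `co_matrix` with `window_count >= 1`.
#' @return Normalized `co_matrix`.
#' @export
normalize_comatrix <- function(m) {
  stopifnot(inherits(m, "co_matrix"))
  if (m$normalized) return(m)
  if (m$window_count < 1L) stop("cannot normalize an empty matrix")
  m$counts <- m$counts / (m$window_count * nrow(m$pairs))
  m$normalized <- TRUE
  m
}

#' @export
print.co_matrix <- function(x, ...) {
  cat(sprintf(
    "<co_matrix> window length %d, %d position pairs x 400 cells, %d windows%s\n",
    x$n, nrow(x$pairs), x$window_count,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Element-wise ratio of two normalized co-occurrence matrices
#'
#' Forms `yes(c) / (no(c) + epsilon)` for every cell `c` and the training
#' distance `w`, the sum of those ratios over the cells where the positive
#' matrix has mass. `epsilon` is a smoothing pseudo-mass that keeps cells
#' unsupported by the negative matrix finite.
#'
#' @param yes,no Normalized `co_matrix` objects of equal window length.
#' @param epsilon Positive smoothing constant added to every denominator.
#' @return A `ratio_matrix`: list with `n`, `values` (same index space as the
#'   inputs), `epsilon`, `w` and the position-pair index.
#' @export
ratio_matrix <- function(yes, no, epsilon = 1e-6) {
  stopifnot(inherits(yes, "co_matrix"), inherits(no, "co_matrix"),
            epsilon > 0)
  if (yes$n != no$n) {
    stop(sprintf("mismatched window lengths: %d vs %d", yes$n, no$n))
  }
  if (!yes$normalized || !no$normalized) {
    stop("both matrices must be normalized")
  }
  values <- yes$counts / (no$counts + epsilon)
  structure(list(n = yes$n,
                 values = values,
                 epsilon = epsilon,
                 w = sum(values[yes$counts > 0]),
                 pairs = yes$pairs),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> window length %d, epsilon %g, w = %g\n",
              x$n, x$epsilon, x$w))
  invisible(x)
}

#' Distance between positive and negative co-occurrence matrices
#'
#' The training distance `w`: the sum of element-wise ratios
#' `yes / (no + epsilon)` over the positive-support cells. Larger `w` means
#' the positive mass sits where the negative pattern is thin.
#'
#' @inheritParams ratio_matrix
#' @return Numeric scalar `w`.
#' @export
distance_w <- function(yes, no, epsilon = 1e-6) {
  ratio_matrix(yes, no, epsilon)$w
}

#' Export a co-occurrence or ratio matrix as long-format TSV
#'
#' Writes one row per non-zero cell with columns
#' `p q aa_p aa_q value` (one-letter residue codes); round-trippable with
#' [read_matrix_tsv()].
#'
#' @param m A `co_matrix` or `ratio_matrix`.
#' @param path Output file path.
#' @param keep_zero Write all cells, including zeros (default `FALSE`).
#' @return Invisibly, the data frame written.
#' @export
write_matrix_tsv <- function(m, path, keep_zero = FALSE) {
  vals <- if (inherits(m, "ratio_matrix")) m$values else m$counts
  df <- matrix_to_long(vals, m$pairs)
  if (!keep_zero) df <- df[df$value != 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @noRd
matrix_to_long <- function(vals, pairs) {
  ab <- expand.grid(b = 1:20, a = 1:20)  # column order is (a-1)*20 + b
  data.frame(
    p = rep(pairs[, "p"], times = 400L),
    q = rep(pairs[, "q"], times = 400L),
    aa_p = AA_ALPHABET[rep(ab$a, each = nrow(pairs))],
    aa_q = AA_ALPHABET[rep(ab$b, each = nrow(pairs))],
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
}

#' Read a long-format matrix TSV back into the dense cell array
#'
#' @param path File written by [write_matrix_tsv()].
#' @param n Window length of the matrix.
#' @return Numeric `choose(n,2)` x 400 matrix of cell values.
#' @export
read_matrix_tsv <- function(path, n) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("p", "q", "aa_p", "aa_q", "value")
  if (!all(need %in% names(df))) {
    stop("matrix TSV must have columns: ", paste(need, collapse = " "))
  }
  pairs <- position_pairs(n)
  key <- paste(pairs[, "p"], pairs[, "q"])
  row <- match(paste(df$p, df$q), key)
  col <- cell_index(match(df$aa_p, AA_ALPHABET), match(df$aa_q, AA_ALPHABET))
  if (anyNA(row) || anyNA(col)) stop("cell outside the matrix index space")
  vals <- matrix(0, nrow = nrow(pairs), ncol = 400L)
  vals[cbind(row, col)] <- df$value
  vals
}
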