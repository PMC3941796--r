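#' Score a single window against a trained model
#'
#' A test window's own singleton co-occurrence matrix, contracted against
#' the model's ratio matrix, reduces to the sum of the `choose(n, 2)`
#' ratio-matrix cells addressed by the window's residue pairs. `ws`
#' expresses that raw distance as a fraction of the training maximum `w_d`.
#'
#' @param codes Integer residue codes of length `n` (the model's window
#'   length), or a character window.
#' @param model A `pair_model` from [fit_pair_model()].
#' @return List with `raw_score` and `ws = raw_score / w_d`.
#' @export
score_window <- function(codes, model) {
  stopifnot(inherits(model, "pair_model"))
  if (is.character(codes)) codes <- encode_sequence(codes)
  n <- model$config$window_length
  if (length(codes) != n) {
    stop(sprintf("window length %d does not match model window length %d",
                 length(codes), n))
  }
  raw <- sum(model$ratio$values[window_cells(codes, model$ratio$pairs)])
  list(raw_score = raw, ws = raw / model$w_d)
}

#' Classify a sequence by its sliding-window scores
#'
#' Scores every length-`n` window of the sequence, labels the sequence
#' positive when the best window score `ws` strictly exceeds the threshold
#' `w_l`, and annotates each residue with 1 when it lies inside at least one
#' above-threshold window.
#'
#' @param seq A `labeled_sequence`, character sequence, or integer codes.
#' @param model A `pair_model`.
#' @param w_l Decision threshold, normally in `[0, 1]` (a fraction of
#'   `w_d`); values above 1 are accepted for threshold sweeps.
#' @return A `sequence_prediction`: data frame `scores` (window `start`,
#'   `window_seq`, `raw_score`, `ws`, `call`), `max_ws`, `label`, and the
#'   binary `residue_annotation` string. A sequence shorter than the window
#'   yields zero windows, a negative label, and an all-zero annotation (with
#'   a warning).
#' @examples
#' pos <- c(a = "QQNYQQNYQQ", b = "AQQNYQCDEF")
#' neg <- c(x = "ACDEFGHIKL", y = "MNPQRSTVWY")
#' m <- fit_pair_model(pos, neg, training_config(window_length = 5))
#' classify_sequence("GGQQNYQQGG", m, w_l = 0.14)
#' @export
classify_sequence <- function(seq, model, w_l = 0.14) {
  stopifnot(inherits(model, "pair_model"), w_l >= 0)
  seq <- as_sequence_list(seq)[[1L]]
  n <- model$config$window_length
  L <- length(seq$codes)
  if (L < n) {
    warning(sprintf("sequence '%s' (length %d) shorter than window %d; %s",
                    seq$id, L, n, "classified negative"))
    return(structure(list(
      id = seq$id,
      scores = data.frame(start = integer(0), window_seq = character(0),
                          raw_score = numeric(0), ws = numeric(0),
                          call = logical(0)),
      max_ws = 0, threshold = w_l, label = "negative",
      residue_annotation = strrep("0", L)), class = "sequence_prediction"))
  }
  W <- extract_windows(seq, n)
  starts <- attr(W, "start")
  raw <- vapply(seq_len(nrow(W)), function(i) {
    sum(model$ratio$values[window_cells(W[i, ], model$ratio$pairs)])
  }, numeric(1))
  ws <- raw / model$w_d
  call <- ws > w_l
  ann <- integer(L)
  for (i in which(call)) ann[starts[i]:(starts[i] + n - 1L)] <- 1L
  structure(list(
    id = seq$id,
    scores = data.frame(
      start = starts,
      window_seq = apply(W, 1L, decode_sequence),
      raw_score = raw, ws = ws, call = call,
      stringsAsFactors = FALSE),
    max_ws = max(ws),
    threshold = w_l,
    label = if (any(call)) "positive" else "negative",
    residue_annotation = paste(ann, collapse = "")
  ), class = "sequence_prediction")
}

#' @export
print.sequence_prediction <- function(x, ...) {
  cat(sprintf("<sequence_prediction> %s: %s (max ws = %.3f at w_l = %g)\n",
              x$id, x$label, x$max_ws, x$threshold))
  cat(" ", x$residue_annotation, "\n")
  invisible(x)
}

#' Best window score of a sequence
#'
#' Convenience scalar used by ROC sweeps: the maximum `ws` over all windows
#' (0 when the sequence is shorter than the window).
#'
#' @inheritParams classify_sequence
#' @return Numeric scalar.
#' @export
max_window_score <- function(seq, model) {
  seq <- as_sequence_list(seq)[[1L]]
  n <- model$config$window_length
  if (length(seq$codes) < n) return(0)
  W <- extract_windows(seq, n)
  max(vapply(seq_len(nrow(W)), function(i) {
    sum(model$ratio$values[window_cells(W[i, ], model$ratio$pairs)])
  }, numeric(1))) / model$w_d
}

#' Extract the learned co-localized residue-pair pattern
#'
#' Rescales the ratio matrix to `[0, 1]` by its maximum cell and lists every
#' cell at or above the cut-off, sorted by position pair and descending
#' value -- the co-occurring residue pairs that carry the classification
#' pattern.
#'
#' @param model A `pair_model`.
#' @param cutoff Cut-off on the rescaled value, in `[0, 1]` (default 0.4).
#' @return Data frame with columns `p`, `q`, `aa_p`, `aa_q`, `value`.
#' @export
extract_pattern <- function(model, cutoff = 0.4) {
  stopifnot(inherits(model, "pair_model"), cutoff >= 0, cutoff <= 1)
  vals <- model$ratio$values
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0) stop("degenerate ratio matrix")
  df <- matrix_to_long(vals / mx, model$ratio$pairs)
  df <- df[df$value >= cutoff & df$value > 0, , drop = FALSE]
  df <- df[order(df$p, df$q, -df$value), , drop = FALSE]
  rownames(df) <- NULL
  df
}
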