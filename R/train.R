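#' Training configuration
#'
#' @param window_length Sliding-window length `n` (default 5; 4..10 covers
#'   the hot-spot fragment range, and 6 matches hexapeptide sets where the
#'   window equals the peptide and no selection is needed).
#' @param epsilon Smoothing pseudo-mass added to negative-matrix cells in
#'   the ratio. The default `NULL` resolves at fit time to the
#'   uniform-background cell mass `1 / (400 * choose(n, 2))` -- the mass a
#'   cell carries when negatives are i.i.d. uniform -- which keeps cells
#'   unseen in the finite negative sample on the same footing as typical
#'   supported cells. Much smaller values make sampling zeros of the
#'   negative matrix dominate both window selection and the ratio pattern.
#' @param max_iterations Maximum reselection sweeps over the positive set
#'   (default 100).
#' @param min_improvement Convergence tolerance on the distance `w`; the
#'   default 0 stops only at an exact window-assignment fixpoint.
#' @return A `training_config` list.
#' @export
training_config <- function(window_length = 5L, epsilon = NULL,
                            max_iterations = 100L, min_improvement = 0) {
  window_length <- as.integer(window_length)
  stopifnot(window_length >= 2L, is.null(epsilon) || epsilon > 0,
            max_iterations >= 1L, min_improvement >= 0)
  structure(list(window_length = window_length, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 min_improvement = min_improvement),
            class = "training_config")
}

# Coerce character vectors / data frames / labeled_sequence lists to a
# plain list of labeled_sequence.
#' @noRd
as_sequence_list <- function(x, label = "unlabeled", strict = TRUE) {
  if (inherits(x, "labeled_sequence")) return(list(x))
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    return(mapply(labeled_sequence, ids, x,
                  MoreArgs = list(label = label, strict = strict),
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  if (is.data.frame(x)) {
    lab <- if ("label" %in% names(x)) x$label else label
    return(mapply(labeled_sequence, x$id, x$sequence, lab,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "labeled_sequence")))
  x
}

# cell indices (row = position pair, col = residue pair) of one window's
# singleton co-occurrence matrix
#' @noRd
window_cells <- function(codes, pairs) {
  cbind(seq_len(nrow(pairs)),
        cell_index(codes[pairs[, "p"]], codes[pairs[, "q"]]))
}

# NULL epsilon -> uniform-background cell mass for this window length
#' @noRd
resolve_epsilon <- function(config) {
  if (is.null(config$epsilon)) {
    1 / (400 * choose(config$window_length, 2))
  } else {
    config$epsilon
  }
}

# The training distance of a selection state: the mean classification-style
# distance ratio of the selected windows against the state's own positive
# matrix X, i.e. w = choose(n,2) * sum_c X(c)^2 / (NO(c) + eps). Greedy
# per-sequence reselection is coordinate ascent on this objective, so it is
# monotone; it rewards windows that sit where the negative pattern is thin
# AND where the windows selected from other positive sequences agree.
#' @noRd
selection_distance <- function(S, cnt, R, npairs) {
  sum(S * S * R) / (cnt * cnt * npairs)
}

#' Build the negative co-occurrence matrix
#'
#' Every sliding window of every negative sequence contributes equally; the
#' shifting window averages away any positional pattern the negative set
#' might carry. Sequences shorter than the window are skipped with a warning.
#'
#' @param negatives Negative sequences: character vector, data frame with
#'   `id`/`sequence`, or list of `labeled_sequence`.
#' @param config A [training_config()].
#' @return Normalized `co_matrix` over all negative windows.
#' @export
build_negative_matrix <- function(negatives, config = training_config()) {
  seqs <- as_sequence_list(negatives, label = "negative")
  n <- config$window_length
  usable <- vapply(seqs, function(s) length(s$codes) >= n, TRUE)
  if (any(!usable)) {
    warning(sprintf("skipping %d negative sequence(s) shorter than %d",
                    sum(!usable), n))
  }
  if (!any(usable)) stop("no usable negative windows")
  W <- do.call(rbind, lapply(seqs[usable], extract_windows, n = n))
  if (nrow(W) == 0L) stop("no usable negative windows")
  normalize_comatrix(build_comatrix(W, n))
}

#' Select the most pattern-bearing window of one positive sequence
#'
#' Scores every candidate window of `seq` by the training distance `w` that
#' results from substituting it for the sequence's current contribution to
#' the positive matrix, and returns the maximizer; ties are broken by the
#' smallest start position. A candidate scores high when its residue pairs
#' avoid the negative pattern (small negative-matrix cells) and coincide
#' with the pairs of windows already selected from the other positive
#' sequences.
#'
#' @param seq A `labeled_sequence` (length `>= n`).
#' @param state A training state as carried by [fit_pair_model()]: list
#'   with the unnormalized positive cell-count matrix `S` (excluding this
#'   sequence's contribution) and the window count `cnt`; or `NULL` to
#'   score the sequence in isolation.
#' @param matrix_no Normalized negative `co_matrix`.
#' @param config A [training_config()].
#' @return List with `start`, `codes`, and the attained `w`.
#' @export
select_best_window <- function(seq, state = NULL, matrix_no,
                               config = training_config()) {
  seq <- as_sequence_list(seq)[[1L]]
  n <- config$window_length
  if (length(seq$codes) < n) {
    stop(sprintf("sequence '%s' (length %d) is shorter than the window (%d)",
                 seq$id, length(seq$codes), n))
  }
  R <- 1 / (matrix_no$counts + resolve_epsilon(config))
  pairs <- matrix_no$pairs
  npairs <- nrow(pairs)
  if (is.null(state)) {
    state <- list(S = matrix(0, npairs, 400L), cnt = 0L)
  }
  W <- extract_windows(seq, n)
  starts <- attr(W, "start")
  sc <- vapply(seq_len(nrow(W)), function(i) {
    cells <- window_cells(W[i, ], pairs)
    sum((2 * state$S[cells] + 1) * R[cells])
  }, numeric(1))
  best <- which.max(sc)  # which.max takes the first (leftmost) maximum
  cells <- window_cells(W[best, ], pairs)
  S2 <- state$S
  S2[cells] <- S2[cells] + 1
  list(start = starts[best], codes = W[best, ],
       w = selection_distance(S2, state$cnt + 1L, R, npairs))
}

#' Fit the co-occurrence pattern classifier
#'
#' Trains the model: (i) the negative matrix averages every sliding window
#' of every negative sequence; (ii) the positive matrix starts from all
#' windows of all positive sequences and is then refined by sequential
#' greedy sweeps that reselect, for each positive sequence in input order,
#' the single window maximizing the training distance `w` -- windows most
#' distant from the negative pattern and closest to the windows selected
#' from the other positive sequences -- until the selection reaches a
#' fixpoint or `max_iterations` sweeps; (iii) the maximal distance `w_d`
#' attained scales all classification scores. The procedure is
#' deterministic given inputs and configuration.
#'
#' @param positives,negatives Sequences (character vector, data frame with
#'   `id`/`sequence`, or list of `labeled_sequence`). Sequences shorter than
#'   the window are skipped with a warning.
#' @param config A [training_config()].
#' @return A `pair_model`: normalized `matrix_no` and `matrix_yes`, the
#'   `ratio` matrix, `w_d`, per-sequence selected window starts, the
#'   per-sweep distance trace `w_trace`, and counts `n_yes`/`n_no`.
#' @examples
#' pos <- c(a = "QQNYQQNYQQ", b = "AQQNYQCDEF")
#' neg <- c(x = "ACDEFGHIKL", y = "MNPQRSTVWY")
#' m <- fit_pair_model(pos, neg, training_config(window_length = 5))
#' m$w_d
#' @export
fit_pair_model <- function(positives, negatives,
                           config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  n <- config$window_length
  config$epsilon <- resolve_epsilon(config)

  matrix_no <- build_negative_matrix(negatives, config)
  n_no <- length(as_sequence_list(negatives))

  pos <- as_sequence_list(positives, label = "positive")
  usable <- vapply(pos, function(s) length(s$codes) >= n, TRUE)
  if (any(!usable)) {
    warning(sprintf("skipping %d positive sequence(s) shorter than %d",
                    sum(!usable), n))
  }
  pos <- pos[usable]
  if (length(pos) == 0L) stop("no usable positive sequences")
  ids <- vapply(pos, `[[`, "", "id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  R <- 1 / (matrix_no$counts + config$epsilon)
  pairs <- matrix_no$pairs
  npairs <- nrow(pairs)

  # candidate windows and their cell addresses
  cand <- lapply(pos, extract_windows, n = n)
  cand_cells <- lapply(cand, function(W) {
    lapply(seq_len(nrow(W)), function(i) window_cells(W[i, ], pairs))
  })

  # initialization: every window of every positive sequence contributes
  contrib <- lapply(cand, function(W) build_comatrix(W, n)$counts)
  seq_cnt <- vapply(cand, nrow, integer(1))
  S <- Reduce(`+`, contrib)
  cnt <- sum(seq_cnt)
  w_init <- selection_distance(S, cnt, R, npairs)

  # a sequence offering a single window already contributes exactly that
  # window, so it cannot change during sweeps
  selection <- ifelse(seq_cnt == 1L, 1L, NA_integer_)
  w_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  w_prev <- -Inf
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    changed <- FALSE
    for (k in seq_along(pos)) {
      S <- S - contrib[[k]]
      sc <- vapply(cand_cells[[k]], function(cells) {
        sum((2 * S[cells] + 1) * R[cells])
      }, numeric(1))
      best <- which.max(sc)
      if (is.na(selection[k]) || selection[k] != best) changed <- TRUE
      newC <- matrix(0, npairs, 400L)
      newC[cand_cells[[k]][[best]]] <- 1
      S <- S + newC
      cnt <- cnt - seq_cnt[k] + 1L
      contrib[[k]] <- newC
      seq_cnt[k] <- 1L
      selection[k] <- best
    }
    w_now <- selection_distance(S, cnt, R, npairs)
    w_trace <- c(w_trace, w_now)
    if (!changed) { converged <- TRUE; break }
    if (config$min_improvement > 0 && iter > 1L &&
        (w_now - w_prev) <= config$min_improvement) {
      converged <- TRUE
      break
    }
    w_prev <- w_now
  }
  if (!converged) {
    warning(sprintf("selection did not reach a fixpoint in %d sweeps",
                    config$max_iterations))
  }

  sel_windows <- do.call(rbind, lapply(seq_along(pos), function(k) {
    cand[[k]][selection[k], , drop = FALSE]
  }))
  matrix_yes <- normalize_comatrix(build_comatrix(sel_windows, n))
  ratio <- ratio_matrix(matrix_yes, matrix_no, config$epsilon)
  w_d <- max(w_trace)

  sel_starts <- vapply(seq_along(pos), function(k) {
    attr(cand[[k]], "start")[selection[k]]
  }, integer(1))

  structure(list(
    config = config,
    matrix_no = matrix_no,
    matrix_yes = matrix_yes,
    ratio = ratio,
    w_d = w_d,
    w_init = w_init,
    w_trace = w_trace,
    n_yes = length(pos),
    n_no = n_no,
    iterations_run = iter,
    converged = converged,
    selection = data.frame(id = ids, start = sel_starts,
                           stringsAsFactors = FALSE),
    provenance = sprintf("fit_pair_model n=%d epsilon=%g", n, config$epsilon)
  ), class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<pair_model> window length %d, %d positive / %d negative sequences\n",
    "  w_d = %.4f after %d sweep(s)%s\n"),
    x$config$window_length, x$n_yes, x$n_no, x$w_d, x$iterations_run,
    if (x$converged) "" else " (no fixpoint)"))
  invisible(x)
}
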