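MODEL_FORMAT_VERSION <- 1L

#' @noRd
long_to_matrix <- function(df, n) {
  pairs <- position_pairs(n)
  key <- paste(pairs[, "p"], pairs[, "q"])
  row <- match(paste(df$p, df$q), key)
  col <- cell_index(match(df$aa_p, AA_ALPHABET), match(df$aa_q, AA_ALPHABET))
  if (anyNA(row) || anyNA(col)) stop("cell outside the matrix index space")
  vals <- matrix(0, nrow = nrow(pairs), ncol = 400L)
  vals[cbind(row, col)] <- df$value
  vals
}

#' @noRd
sparse_cells <- function(vals, pairs) {
  df <- matrix_to_long(vals, pairs)
  df[df$value != 0, , drop = FALSE]
}

#' Serialize a trained model to JSON
#'
#' Writes the configuration, both normalized co-occurrence matrices (as
#' long-format non-zero cell lists), the maximal distance `w_d`, sequence
#' counts, the selection map and a format-version field.
#'
#' @param model A `pair_model`.
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pair_model"))
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    config = unclass(model$config),
    window_length = model$config$window_length,
    matrix_no = list(window_count = model$matrix_no$window_count,
                     cells = sparse_cells(model$matrix_no$counts,
                                          model$matrix_no$pairs)),
    matrix_yes = list(window_count = model$matrix_yes$window_count,
                      cells = sparse_cells(model$matrix_yes$counts,
                                           model$matrix_yes$pairs)),
    w_d = model$w_d,
    w_init = model$w_init,
    w_trace = model$w_trace,
    n_yes = model$n_yes,
    n_no = model$n_no,
    iterations_run = model$iterations_run,
    converged = model$converged,
    selection = model$selection,
    provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained model from JSON
#'
#' Validates matrix normalization and the `w_d` invariant before returning.
#'
#' @param path File written by [write_model()].
#' @return A `pair_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) ||
      doc$format_version != MODEL_FORMAT_VERSION) {
    stop("unsupported model format version")
  }
  config <- training_config(doc$config$window_length, doc$config$epsilon,
                            doc$config$max_iterations,
                            doc$config$min_improvement)
  n <- config$window_length
  rebuild <- function(part) {
    m <- new_co_matrix(long_to_matrix(part$cells, n), n,
                       part$window_count, normalized = TRUE)
    if (abs(sum(m$counts) - 1) > 1e-9) {
      stop("stored matrix is not normalized")
    }
    m
  }
  matrix_no <- rebuild(doc$matrix_no)
  matrix_yes <- rebuild(doc$matrix_yes)
  ratio <- ratio_matrix(matrix_yes, matrix_no, config$epsilon)
  if (!(doc$w_d > 0) || abs(max(doc$w_trace) - doc$w_d) > 1e-6 * doc$w_d) {
    stop("stored w_d is inconsistent with the training trace")
  }
  structure(list(
    config = config, matrix_no = matrix_no, matrix_yes = matrix_yes,
    ratio = ratio, w_d = doc$w_d, w_init = doc$w_init,
    w_trace = doc$w_trace, n_yes = doc$n_yes, n_no = doc$n_no,
    iterations_run = doc$iterations_run, converged = doc$converged,
    selection = as.data.frame(doc$selection),
    provenance = doc$provenance), class = "pair_model")
}
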