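#' Read a labeled peptide dataset from CSV
#'
#' Expects a header with at least `id`, `sequence`, `label` columns (an
#' optional `source` column is kept). Labels may be spelled `1/0`,
#' `pos/neg`, `positive/negative`, or `amyloid/non-amyloid`. Duplicate
#' (sequence, label) pairs are reported; the same sequence carrying
#' conflicting labels is an error.
#'
#' @param path CSV file path.
#' @param max_length Sequences longer than this are rejected unless
#'   `allow_long = TRUE` (hot-spot sets are 4-10 residues; full proteins
#'   need the flag).
#' @param allow_long Accept sequences longer than `max_length`.
#' @return Data frame with columns `id`, `sequence`, `label`
#'   (`"positive"`/`"negative"`), `source`.
#' @export
read_labeled_csv <- function(path, max_length = 10L, allow_long = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(df))) {
    stop("labeled CSV must have header columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no records in ", path)
  df$sequence <- toupper(gsub("\\s+", "", df$sequence))
  bad <- which(!vapply(df$sequence, function(s) {
    !inherits(tryCatch(encode_sequence(s), error = identity), "error")
  }, TRUE))
  if (length(bad) > 0L) {
    stop(sprintf("invalid sequence(s) at data row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  df$label <- ifelse(as_binary_labels(df$label), "positive", "negative")
  if (!allow_long && any(nchar(df$sequence) > max_length)) {
    stop(sprintf(
      "sequence(s) longer than %d residues (rows %s); use allow_long = TRUE",
      max_length,
      paste(which(nchar(df$sequence) > max_length), collapse = ", ")))
  }
  conflict <- unique(df$sequence[duplicated(df[c("sequence")]) |
                                   duplicated(df[c("sequence")],
                                              fromLast = TRUE)])
  for (s in conflict) {
    labs <- unique(df$label[df$sequence == s])
    if (length(labs) > 1L) {
      stop("sequence '", s, "' carries conflicting labels")
    }
  }
  ndup <- sum(duplicated(df[c("sequence", "label")]))
  if (ndup > 0L) {
    message(sprintf("%d duplicate (sequence, label) record(s) in %s",
                    ndup, path))
  }
  if (is.null(df$source)) df$source <- ""
  df[c("id", "sequence", "label", "source")]
}

#' Write a labeled peptide dataset to CSV
#'
#' @param records Data frame with `id`, `sequence`, `label` (and optionally
#'   `source`).
#' @param path Output path.
#' @export
write_labeled_csv <- function(records, path) {
  stopifnot(all(c("id", "sequence", "label") %in% names(records)))
  if (is.null(records$source)) records$source <- ""
  utils::write.csv(records[c("id", "sequence", "label", "source")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace; wrapped sequence lines
#' are concatenated.
#'
#' @param path FASTA file path.
#' @param strict Passed to [encode_sequence()]; with `FALSE`, non-standard
#'   residues become `NA` codes and windows touching them are dropped
#'   downstream.
#' @return List of unlabeled `labeled_sequence` objects, input order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, "")
  }
  if (any(nchar(gsub("\\s", "", seqs)) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(ids[nchar(gsub("\\s", "", seqs)) == 0L], collapse = ", "))
  }
  mapply(labeled_sequence, ids, seqs,
         MoreArgs = list(label = "unlabeled", strict = strict),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Specification for the synthetic planted-motif generator
#'
#' Describes peptide sets with a known ground truth: negatives are i.i.d.
#' background; each positive carries one planted window, at a uniformly
#' random admissible offset, in which correlated residue pairs sit at fixed
#' relative positions.
#'
#' @param n_pos,n_neg Numbers of positive and negative peptides (defaults
#'   100 and 200).
#' @param length_range Min/max peptide length (default both 10).
#' @param motif Data frame with columns `p`, `q` (relative positions within
#'   the motif window), `a`, `b` (one-letter residues), `prob`
#'   (co-occurrence probability). The default plants Q-N at (1,2), Y-F at
#'   (3,4) and N-Q at (2,5) -- mutually consistent assignments, so at
#'   strength 1 the planted window is the fixed word QNYFQ.
#' @param motif_window_length Length of the planted window (default 5).
#' @param strength Scalar multiplied into every `prob` (1 = always planted,
#'   0 = pattern-free positives).
#' @param background Residue sampling probabilities, length 20 (default
#'   uniform).
#' @param seed Integer seed; generation is deterministic given these
#'   settings.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 200L,
                           length_range = c(10L, 10L),
                           motif = NULL, motif_window_length = 5L,
                           strength = 1, background = rep(1 / 20, 20),
                           seed = 42L) {
  if (is.null(motif)) {
    motif <- data.frame(p = c(1L, 3L, 2L), q = c(2L, 4L, 5L),
                        a = c("Q", "Y", "N"), b = c("N", "F", "Q"),
                        prob = 1, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("p", "q", "a", "b", "prob") %in% names(motif)),
            all(motif$p < motif$q),
            all(motif$q <= motif_window_length),
            all(motif$prob >= 0 & motif$prob <= 1),
            strength >= 0, strength <= 1,
            length(background) == 20L, all(background >= 0),
            n_pos >= 1L, n_neg >= 1L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  if (motif_window_length > length_range[1]) {
    stop("motif window longer than the minimum sequence length")
  }
  motif$prob <- motif$prob * strength
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), motif = motif,
                 motif_window_length = as.integer(motif_window_length),
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic planted-motif peptide dataset
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame of records (`id`, `sequence`, `label`, `source`) with
#'   attribute `planted_start` (integer vector, `NA` for negatives) giving
#'   the ground-truth offset of the planted window in each positive.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    len_choices <- spec$length_range[1]:spec$length_range[2]
    lens <- len_choices[sample.int(length(len_choices),
                                   spec$n_pos + spec$n_neg,
                                   replace = TRUE)]
    planted <- rep(NA_integer_, spec$n_pos + spec$n_neg)
    seqs <- character(spec$n_pos + spec$n_neg)
    for (i in seq_along(seqs)) {
      codes <- sample.int(20L, lens[i], replace = TRUE,
                          prob = spec$background)
      if (i <= spec$n_pos) {
        off <- sample.int(lens[i] - spec$motif_window_length + 1L, 1L)
        for (m in seq_len(nrow(spec$motif))) {
          if (stats::runif(1) < spec$motif$prob[m]) {
            codes[off + spec$motif$p[m] - 1L] <-
              match(spec$motif$a[m], AA_ALPHABET)
            codes[off + spec$motif$q[m] - 1L] <-
              match(spec$motif$b[m], AA_ALPHABET)
          }
        }
        planted[i] <- off
      }
      seqs[i] <- decode_sequence(codes)
    }
  })
  out <- data.frame(
    id = c(sprintf("pos%03d", seq_len(spec$n_pos)),
           sprintf("neg%03d", seq_len(spec$n_neg))),
    sequence = seqs,
    label = rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
    source = "synthetic",
    stringsAsFactors = FALSE)
  attr(out, "planted_start") <- planted
  out
}
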