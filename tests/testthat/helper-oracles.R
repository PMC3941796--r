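# Independent brute-force oracles, kept deliberately naive: nested loops and
# direct enumeration, no shared code with the implementation under test.

# co-occurrence count of one (p, q, a, b) cell by direct row scanning
oracle_cell_count <- function(W, p, q, a, b) {
  hits <- 0L
  for (i in seq_len(nrow(W))) {
    if (W[i, p] == a && W[i, q] == b) hits <- hits + 1L
  }
  hits
}

# full co-occurrence tensor as a 4-d array [p, q, a, b]
oracle_comatrix <- function(W, n) {
  out <- array(0, dim = c(n, n, 20, 20))
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    for (i in seq_len(nrow(W))) {
      out[p, q, W[i, p], W[i, q]] <- out[p, q, W[i, p], W[i, q]] + 1
    }
  }
  out
}

# distance w: cell-by-cell summation over the full index space
oracle_distance_w <- function(yes_arr, no_arr, n, eps) {
  w <- 0
  for (p in 1:(n - 1)) for (q in (p + 1):n) for (a in 1:20) for (b in 1:20) {
    if (yes_arr[p, q, a, b] > 0) {
      w <- w + yes_arr[p, q, a, b] / (no_arr[p, q, a, b] + eps)
    }
  }
  w
}

# normalized 4-d array from a co_matrix, via the exported long-format table
as_oracle_array <- function(m) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  df <- amylopair::write_matrix_tsv(m, f, keep_zero = TRUE)
  out <- array(0, dim = c(m$n, m$n, 20, 20))
  for (i in seq_len(nrow(df))) {
    out[df$p[i], df$q[i],
        match(df$aa_p[i], AA_ALPHABET), match(df$aa_q[i], AA_ALPHABET)] <-
      df$value[i]
  }
  out
}

# AUC as the tie-corrected Mann-Whitney pairwise concordance
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# window score by exhaustive position-pair looping on the ratio table
oracle_score_window <- function(codes, model) {
  n <- model$config$window_length
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  df <- amylopair::write_matrix_tsv(model$ratio, f, keep_zero = TRUE)
  s <- 0
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    s <- s + df$value[df$p == p & df$q == q &
                        df$aa_p == AA_ALPHABET[codes[p]] &
                        df$aa_q == AA_ALPHABET[codes[q]]]
  }
  list(raw_score = s, ws = s / model$w_d)
}

random_windows <- function(k, n) {
  matrix(sample.int(20L, k * n, replace = TRUE), nrow = k, ncol = n)
}

random_sequences <- function(k, len, prefix = "s") {
  out <- vapply(seq_len(k), function(i) {
    paste(AA_ALPHABET[sample.int(20L, len, replace = TRUE)], collapse = "")
  }, "")
  names(out) <- paste0(prefix, seq_len(k))
  out
}

# small model fitted on random data, for scoring oracles
random_model <- function(n = 4L, n_pos = 8L, n_neg = 12L, len = 8L) {
  fit_pair_model(random_sequences(n_pos, len, "p"),
                 random_sequences(n_neg, len, "n"),
                 training_config(window_length = n))
}

synthetic_split <- function(ds) {
  list(pos = ds[ds$label == "positive", , drop = FALSE],
       neg = ds[ds$label == "negative", , drop = FALSE],
       planted = attr(ds, "planted_start")[ds$label == "positive"])
}
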