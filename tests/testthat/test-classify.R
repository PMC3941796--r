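# hand-built model with full control over the ratio cells
manual_model <- function(values, w_d, n = 5L) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  colnames(pairs) <- c("p", "q")
  structure(list(
    config = training_config(window_length = n),
    ratio = structure(list(n = n, values = values, epsilon = 1e-6,
                           w = sum(values), pairs = pairs),
                      class = "ratio_matrix"),
    w_d = w_d), class = "pair_model")
}

test_that("uniform ratio matrix scores every window C(n,2)*v", {
  m <- manual_model(matrix(2, 10, 400), w_d = 40)
  sc <- score_window("QQNYQ", m)
  expect_equal(sc$raw_score, 20)
  expect_equal(sc$ws, 0.5)
  sc2 <- score_window(encode_sequence("ACDEF"), m)
  expect_equal(sc2$raw_score, 20)
})

test_that("a single supported cell is looked up by the window's own residues", {
  vals <- matrix(0, 10, 400)
  q <- match("Q", AA_ALPHABET)
  vals[1, (q - 1) * 20 + q] <- 3  # cell (1, 2, Q, Q)
  m <- manual_model(vals, w_d = 30)
  expect_equal(score_window("QQNYQ", m)$ws, 0.1)
  expect_equal(score_window("NQQYQ", m)$ws, 0)  # Q,Q not at positions (1,2)
  expect_error(score_window("QQNY", m), "length")
})

test_that("window scores match the exhaustive pair-loop oracle", {
  set.seed(41)
  for (trial in 1:6) {
    m <- random_model(n = sample(3:5, 1))
    for (rep in 1:3) {
      codes <- sample.int(20L, m$config$window_length, replace = TRUE)
      got <- score_window(codes, m)
      want <- oracle_score_window(codes, m)
      expect_equal(got$raw_score, want$raw_score, tolerance = 1e-9)
      expect_equal(got$ws, want$ws, tolerance = 1e-9)
    }
  }
})

test_that("classification thresholds, labels and annotation behave geometrically", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(seed = 42)))
  m <- fit_pair_model(s$pos, s$neg)

  p <- classify_sequence(s$pos$sequence[1], m, w_l = 0.14)
  expect_equal(p$max_ws, max(p$scores$ws))
  expect_equal(nchar(p$residue_annotation), 10L)
  expect_equal(p$label, "positive")

  # threshold extremes
  expect_equal(classify_sequence(s$pos$sequence[1], m, 0)$label, "positive")
  high <- classify_sequence(s$pos$sequence[1], m, p$max_ws + 1)
  expect_equal(high$label, "negative")
  expect_equal(high$residue_annotation, strrep("0", 10))

  # exactly one window above threshold on a length n+1 sequence:
  # n ones and one zero
  seq6 <- "QNYFQA"  # planted consensus word plus one residue
  p6 <- classify_sequence(seq6, m, 0.5)
  expect_equal(nrow(p6$scores), 2L)
  if (sum(p6$scores$call) == 1L) {
    expect_equal(sum(strsplit(p6$residue_annotation, "")[[1]] == "1"), 5L)
  }

  # shorter than the window: negative with a warning
  expect_warning(ps <- classify_sequence("QNYF", m, 0.14), "shorter")
  expect_equal(ps$label, "negative")
  expect_equal(ps$residue_annotation, "0000")
  expect_equal(ps$max_ws, 0)
})

test_that("raising the threshold only shrinks calls and annotations", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(
    n_pos = 15, n_neg = 30, seed = 13)))
  m <- fit_pair_model(s$pos, s$neg)
  seqs <- c(s$pos$sequence[1:5], s$neg$sequence[1:5])
  for (sq in seqs) {
    prev_pos <- TRUE
    prev_ann <- NULL
    for (wl in c(0, 0.1, 0.3, 0.6, 1, 2)) {
      p <- classify_sequence(sq, m, wl)
      pos <- p$label == "positive"
      if (!prev_pos) expect_false(pos)
      ann <- strsplit(p$residue_annotation, "")[[1]] == "1"
      if (!is.null(prev_ann)) expect_true(all(prev_ann | !ann))
      prev_pos <- pos
      prev_ann <- ann
    }
  }
})

test_that("prepending residues shifts starts and annotation, not scores", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(
    n_pos = 15, n_neg = 30, seed = 14)))
  m <- fit_pair_model(s$pos, s$neg)
  base <- s$pos$sequence[2]
  p0 <- classify_sequence(base, m, 0.14)
  shifted <- classify_sequence(paste0("GGG", base), m, 0.14)
  common <- nrow(p0$scores)
  tail_scores <- shifted$scores[shifted$scores$start > 3, ]
  expect_equal(tail_scores$ws, p0$scores$ws)
  expect_equal(tail_scores$start, p0$scores$start + 3L)
  expect_equal(substr(shifted$residue_annotation, 4, 3 + nchar(base)),
               p0$residue_annotation)
})

test_that("training positives are recovered at thresholds below their scores", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(
    n_pos = 20, n_neg = 40, seed = 15)))
  m <- fit_pair_model(s$pos, s$neg)
  ws <- vapply(s$pos$sequence, function(x)
    max_window_score(labeled_sequence("x", x), m), numeric(1))
  wl <- min(ws) * 0.99
  labs <- vapply(s$pos$sequence, function(x)
    classify_sequence(x, m, wl)$label, "")
  expect_true(all(labs == "positive"))
})

test_that("pattern extraction rescales by the maximum and applies the cut-off", {
  vals <- matrix(0, 10, 400)
  vals[1, 5] <- 10   # rescaled 1.0
  vals[3, 17] <- 5   # rescaled 0.5
  vals[7, 300] <- 2  # rescaled 0.2
  m <- manual_model(vals, w_d = 10)
  pat04 <- extract_pattern(m, 0.4)
  expect_equal(nrow(pat04), 2L)
  expect_equal(pat04$value, c(1.0, 0.5))
  expect_equal(nrow(extract_pattern(m, 0)), 3L)
  pat1 <- extract_pattern(m, 1)
  expect_equal(nrow(pat1), 1L)
  expect_equal(pat1[1, c("p", "q")], data.frame(p = 1L, q = 2L))
  expect_error(extract_pattern(manual_model(matrix(0, 10, 400), 1), 0.4),
               "degenerate")
})
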