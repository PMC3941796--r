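test_that("negative matrix averages all sliding windows, skipping short sequences", {
  cfg <- training_config(window_length = 5)
  m <- build_negative_matrix("AAAAA", cfg)
  expect_equal(sum(m$counts), 1, tolerance = 1e-12)
  expect_equal(m$window_count, 1L)

  expect_warning(m2 <- build_negative_matrix(c("ACDEFG", "ACD"), cfg),
                 "skipping 1")
  expect_equal(m2$window_count, 2L)

  expect_error(suppressWarnings(build_negative_matrix(c("ACD", "EF"), cfg)),
               "no usable")
})

test_that("i.i.d. uniform negatives drive every cell to 1/(C(n,2)*400)", {
  set.seed(31)
  # 2000 sequences of length 54 -> 1e5 windows of length 5
  negs <- random_sequences(2000, 54)
  m <- build_negative_matrix(negs, training_config(window_length = 5))
  expect_equal(mean(m$counts), 1 / 4000, tolerance = 1e-12)
  # per-plane multinomial, 1e5 draws over 400 cells: max deviation over the
  # 4000 cells stays within ~6 standard errors of 2.5e-4
  expect_lt(max(abs(m$counts - 0.00025)), 1e-4)
})

test_that("length-n positives force their only window and converge in one sweep", {
  m <- fit_pair_model(c("QQNYQ", "NYQQN", "QYQNY"),
                      c("ACDEFG", "GHIKLM"),
                      training_config(window_length = 5))
  expect_equal(m$iterations_run, 1L)
  expect_true(m$converged)
  expect_equal(m$selection$start, c(1L, 1L, 1L))
  # positive matrix is the plain normalized matrix of all positives
  ref <- normalize_comatrix(build_comatrix(
    rbind(encode_sequence("QQNYQ"), encode_sequence("NYQQN"),
          encode_sequence("QYQNY"))))
  expect_equal(m$matrix_yes$counts, ref$counts)
})

test_that("planted motif windows are recovered from synthetic positives", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(seed = 42)))
  m <- fit_pair_model(s$pos, s$neg)
  expect_gte(mean(m$selection$start == s$planted), 0.95)
  # exhaustive check on a handful of sequences: the committed start beats
  # every alternative under the converged model's own window scores
  for (k in c(1, 25, 50, 100)) {
    p <- classify_sequence(s$pos$sequence[k], m, 0)
    expect_equal(p$scores$start[which.max(p$scores$ws)],
                 m$selection$start[k])
  }
})

test_that("distance trace is non-decreasing and w_d is its maximum", {
  set.seed(32)
  for (trial in 1:4) {
    m <- fit_pair_model(random_sequences(12, 10, "p"),
                        random_sequences(20, 10, "n"))
    expect_true(all(diff(m$w_trace) >= -1e-12))
    expect_equal(m$w_d, max(m$w_trace))
    expect_gt(m$w_d, 0)
  }
})

test_that("converged selection is a fixpoint under reselection", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(seed = 7)))
  m <- fit_pair_model(s$pos, s$neg)
  expect_true(m$converged)
  # rerunning the fit on the same inputs reproduces the selection exactly
  m2 <- fit_pair_model(s$pos, s$neg)
  expect_identical(m$selection, m2$selection)
  expect_identical(m$w_trace, m2$w_trace)
  # and each selected window is its sequence's best under select_best_window
  # with the rest of the converged state held fixed
  S_full <- round(m$matrix_yes$counts * m$n_yes * 10)
  for (k in c(3, 30, 77)) {
    codes <- encode_sequence(s$pos$sequence[k])
    W <- extract_windows(codes, 5)
    own <- W[match(m$selection$start[k], attr(W, "start")), ]
    Sk <- S_full
    cells <- cbind(seq_len(10),
                   (own[m$ratio$pairs[, "p"]] - 1L) * 20L +
                     own[m$ratio$pairs[, "q"]])
    Sk[cells] <- Sk[cells] - 1
    sel <- select_best_window(labeled_sequence(s$pos$id[k], codes, "positive"),
                              state = list(S = Sk, cnt = m$n_yes - 1L),
                              matrix_no = m$matrix_no,
                              config = m$config)
    expect_equal(sel$start, m$selection$start[k])
  }
})

test_that("fit is invariant to shuffling negatives, and to shuffling
           positives on strong-signal data", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(
    n_pos = 30, n_neg = 60, seed = 9)))
  m <- fit_pair_model(s$pos, s$neg)
  set.seed(33)
  m_shufn <- fit_pair_model(s$pos, s$neg[sample(nrow(s$neg)), ])
  expect_equal(m$matrix_no$counts, m_shufn$matrix_no$counts)
  expect_identical(m$selection, m_shufn$selection)
  expect_equal(m$w_d, m_shufn$w_d)

  perm <- sample(nrow(s$pos))
  m_shufp <- fit_pair_model(s$pos[perm, ], s$neg)
  expect_equal(m_shufp$selection$start[order(perm)], m$selection$start)
  expect_equal(m_shufp$matrix_yes$counts, m$matrix_yes$counts)
})

test_that("one window is accounted per usable positive sequence", {
  expect_warning(
    m <- fit_pair_model(c("QQNYQQNYQQ", "AQQNYQCDEF", "QNY"),
                        c("ACDEFGHIKL", "MNPQRSTVWY")),
    "skipping 1 positive")
  expect_equal(m$n_yes, 2L)
  expect_equal(m$matrix_yes$window_count, 2L)
  expect_equal(nrow(m$selection), 2L)
})

test_that("positives identical to negatives carry no signal", {
  set.seed(34)
  seqs <- random_sequences(24, 8)
  m <- fit_pair_model(seqs, seqs)
  r <- m$ratio$values[m$matrix_yes$counts > 0 & m$matrix_no$counts > 0]
  # selected windows are a subset of all windows: supported ratios are
  # bounded by the count inflation of concentrating 24 windows vs 96
  expect_true(all(r > 0))
  held <- random_sequences(30, 8, "h")
  roc <- roc_curve(vapply(held, function(x) max_window_score(
    labeled_sequence("h", x), m), numeric(1)),
    rep(c(TRUE, FALSE), 15))
  expect_gt(roc$auc, 0.2)
  expect_lt(roc$auc, 0.8)
})

test_that("degenerate training inputs are rejected", {
  expect_error(suppressWarnings(
    fit_pair_model(c("QNY", "AC"), c("ACDEFGHIKL"))), "no usable positive")
  expect_error(suppressWarnings(
    fit_pair_model(c("QQNYQQNYQQ"), c("ACD"))), "no usable negative")
})

test_that("model serialization round-trips and validates", {
  s <- synthetic_split(generate_synthetic(synthetic_spec(
    n_pos = 20, n_neg = 40, seed = 5)))
  m <- fit_pair_model(s$pos, s$neg)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$w_d, m$w_d)
  expect_equal(m2$ratio$values, m$ratio$values)
  expect_equal(m2$matrix_no$counts, m$matrix_no$counts)
  expect_equal(m2$selection, m$selection)
  expect_equal(m2$config$epsilon, m$config$epsilon)
  # classification identical through the round trip
  p1 <- classify_sequence("GGQNYFQGGG", m, 0.14)
  p2 <- classify_sequence("GGQNYFQGGG", m2, 0.14)
  expect_equal(p1$scores$ws, p2$scores$ws)

  # tampering with the stored trace is caught
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  doc$w_d <- doc$w_d * 2
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(f2), "inconsistent")
})
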