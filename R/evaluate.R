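#' @noRd
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  x <- tolower(as.character(labels))
  pos <- c("positive", "pos", "1", "yes", "amyloid", "+")
  neg <- c("negative", "neg", "0", "no", "non-amyloid", "nonamyloid", "-")
  out <- ifelse(x %in% pos, TRUE, ifelse(x %in% neg, FALSE, NA))
  if (anyNA(out)) {
    stop("unrecognized label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

# evaluate without disturbing the caller's RNG stream
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Confusion counts and sensitivity/specificity
#'
#' Sensitivity `Sn = TP / (TP + FN)` is the fraction of positives called
#' positive; specificity `Sp = TN / (TN + FP)` the fraction of negatives
#' called negative.
#'
#' @param labels True labels (logical, 0/1, or positive/negative spellings).
#' @param calls Predicted labels, same encoding and length.
#' @return A `confusion` list: `TP`, `FP`, `FN`, `TN`, `Sn`, `Sp`.
#' @export
confusion <- function(labels, calls) {
  labels <- as_binary_labels(labels)
  calls <- as_binary_labels(calls)
  if (length(labels) != length(calls)) {
    stop("labels and calls must have equal length")
  }
  if (!any(labels)) stop("no positive labels: Sn undefined")
  if (all(labels)) stop("no negative labels: Sp undefined")
  TP <- sum(labels & calls); FN <- sum(labels & !calls)
  TN <- sum(!labels & !calls); FP <- sum(!labels & calls)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 Sn = TP / (TP + FN), Sp = TN / (TN + FP)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d FP %d FN %d TN %d | Sn %.3f Sp %.3f\n",
              x$TP, x$FP, x$FN, x$TN, x$Sn, x$Sp))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over every distinct score (a call is
#' positive when `score > threshold`, so ties at the threshold are
#' negative), records `(threshold, Sn, Sp)` at each step, and integrates
#' sensitivity against `1 - Sp` by the trapezoidal rule. The resulting AUC
#' equals the tie-corrected Mann-Whitney pairwise-concordance statistic.
#'
#' @param scores Numeric sequence scores (e.g. best window `ws`).
#' @param labels True labels, one per score.
#' @return A `roc_result`: data frame `points` sorted by threshold (with
#'   `Sn` non-increasing and `Sp` non-decreasing) and scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels)) {
    stop("ROC needs at least one positive and one negative label")
  }
  thr <- sort(unique(c(-Inf, 0, scores, Inf)))
  npos <- sum(labels); nneg <- sum(!labels)
  Sn <- vapply(thr, function(t) sum(scores[labels] > t) / npos, numeric(1))
  Sp <- vapply(thr, function(t) sum(scores[!labels] <= t) / nneg, numeric(1))
  fpr <- 1 - Sp
  auc <- sum(diff(-fpr) * (utils::head(Sn, -1) + utils::tail(Sn, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, Sn = Sn, Sp = Sp),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d sweep points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Diagonal classification point of a ROC sweep
#'
#' The sweep point where sensitivity and specificity are closest to equal
#' (minimizing `|Sn - Sp|`); its level is reported as `(Sn + Sp) / 2`.
#'
#' @param roc A `roc_result`.
#' @return List with `threshold`, `Sn`, `Sp`, `level`.
#' @export
diagonal_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  i <- which.min(abs(p$Sn - p$Sp))
  list(threshold = p$threshold[i], Sn = p$Sn[i], Sp = p$Sp[i],
       level = (p$Sn[i] + p$Sp[i]) / 2)
}

#' @noRd
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop(sprintf(
        "only %d %s sequence(s) for %d folds; lower the fold count",
        length(idx), if (cls) "positive" else "negative", k))
    }
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' @noRd
score_sequences <- function(seqs, model) {
  vapply(seqs, max_window_score, numeric(1), model = model)
}

#' Repeated stratified k-fold cross-validation
#'
#' Repeats a stratified k-fold split (folds preserve the positive:negative
#' ratio), fits the model on k-1 folds and computes the held-out ROC for
#' each, giving `folds x repeats` trial AUCs, a vertically averaged mean ROC
#' (mean Sn at 101 fixed Sp grid points, linear interpolation), and
#' quantiles of the diagonal-point level across trials. Bit-for-bit
#' reproducible given the dataset order and seed.
#'
#' @param dataset Labeled sequences: data frame with `id`, `sequence`,
#'   `label`, or list of `labeled_sequence`.
#' @param config A [training_config()].
#' @param folds Number of folds `k >= 2` (default 4).
#' @param repeats Number of repeats (default 10, for 40 trials at k = 4).
#' @param seed Integer seed for the fold assignments.
#' @return A `cv_result`: `trial_aucs`, `auc_mean`, `mean_roc` (data frame
#'   `Sp`, `Sn`), `diagonal` (per-trial levels and their median/0.85/0.95
#'   quantiles), `folds`, `repeats`, `seed`.
#' @export
cross_validate <- function(dataset, config = training_config(),
                           folds = 4L, repeats = 10L, seed = 1L) {
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  stopifnot(folds >= 2L, repeats >= 1L)
  seqs <- as_sequence_list(dataset)
  labels <- as_binary_labels(vapply(seqs, `[[`, "", "label"))

  trial_aucs <- numeric(0)
  diag_levels <- numeric(0)
  sp_grid <- seq(0, 1, length.out = 101L)
  sn_curves <- list()

  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(labels, folds)
      for (f in seq_len(folds)) {
        test <- fold == f
        model <- fit_pair_model(seqs[!test & labels], seqs[!test & !labels],
                                config)
        roc <- roc_curve(score_sequences(seqs[test], model), labels[test])
        trial_aucs <- c(trial_aucs, roc$auc)
        diag_levels <- c(diag_levels, diagonal_point(roc)$level)
        sn_curves[[length(sn_curves) + 1L]] <-
          stats::approx(roc$points$Sp, roc$points$Sn, xout = sp_grid,
                        ties = max, rule = 2)$y
      }
    }
  })

  mean_sn <- colMeans(do.call(rbind, sn_curves))
  structure(list(
    folds = folds, repeats = repeats, seed = seed,
    trial_aucs = trial_aucs,
    auc_mean = mean(trial_aucs),
    mean_roc = data.frame(Sp = sp_grid, Sn = mean_sn),
    diagonal = list(
      levels = diag_levels,
      quantiles = stats::quantile(diag_levels, c(0.5, 0.85, 0.95),
                                  names = TRUE)),
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<cv_result> %d-fold x %d repeats (seed %d): mean AUC = %.3f\n",
    "  diagonal level median %.3f, q85 %.3f, q95 %.3f\n"),
    x$folds, x$repeats, x$seed, x$auc_mean,
    x$diagonal$quantiles[[1]], x$diagonal$quantiles[[2]],
    x$diagonal$quantiles[[3]]))
  invisible(x)
}

#' Train on one dataset, test on another
#'
#' Fits the model on `train_set` and computes the ROC on `test_set`. With
#' `swap_labels = TRUE` the test labels are inverted, probing whether the
#' negative set itself carries a discriminative pattern (values near 0.5
#' mean it does not). Overlapping sequences between the two sets are
#' reported with a warning; disjointness is the caller's responsibility.
#'
#' @param train_set,test_set Labeled sequence sets.
#' @param config A [training_config()].
#' @param swap_labels Invert the test labels before the ROC (default
#'   `FALSE`).
#' @return A `roc_result` with an added `model` attribute.
#' @export
cross_test <- function(train_set, test_set, config = training_config(),
                       swap_labels = FALSE) {
  tr <- as_sequence_list(train_set)
  te <- as_sequence_list(test_set)
  tr_lab <- as_binary_labels(vapply(tr, `[[`, "", "label"))
  tr_str <- vapply(tr, function(s) decode_sequence(s$codes), "")
  te_str <- vapply(te, function(s) decode_sequence(s$codes), "")
  if (length(intersect(tr_str, te_str)) > 0L) {
    warning(sprintf("%d sequence(s) shared between train and test sets",
                    length(intersect(tr_str, te_str))))
  }
  model <- fit_pair_model(tr[tr_lab], tr[!tr_lab], config)
  labels <- as_binary_labels(vapply(te, `[[`, "", "label"))
  if (swap_labels) labels <- !labels
  roc <- roc_curve(score_sequences(te, model), labels)
  attr(roc, "model") <- model
  roc
}
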