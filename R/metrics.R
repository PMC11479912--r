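#' Confusion counts from binary labels and predictions
#'
#' @param truth 0/1 vector of true labels.
#' @param predicted 0/1 vector of predicted labels.
#' @return A one-row tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  tibble(TP = sum(truth == 1 & predicted == 1),
         FP = sum(truth == 0 & predicted == 1),
         TN = sum(truth == 0 & predicted == 0),
         FN = sum(truth == 1 & predicted == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, recall, precision and F1 from their standard definitions:
#' `ACC = (TP + TN) / (TP + FN + TN + FP)`, `REC = TP / (TP + FN)`,
#' `PRE = TP / (TP + FP)`, `F1 = 2 * PRE * REC / (PRE + REC)`. A metric
#' whose denominator is zero is reported as `NA` (an explicit
#' undefined-marker) rather than silently zero-filled, so averages over
#' runs are never corrupted.
#'
#' @param counts A one-row data frame (or named vector/list) with `TP`,
#'   `FP`, `TN`, `FN`.
#' @return A one-row tibble with columns `acc`, `rec`, `pre`, `f1`.
#' @export
classification_metrics <- function(counts) {
  cc <- as.list(counts)
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  total <- TP + FP + TN + FN
  if (total == 0) {
    abort("all confusion counts are zero", class = "tcrcost_metric_error")
  }
  acc <- (TP + TN) / total
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  pre <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(rec) && !is.na(pre) && (pre + rec) > 0) {
    2 * pre * rec / (pre + rec)
  } else NA_real_
  tibble(acc = acc, rec = rec, pre = pre, f1 = f1)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * pre * rec / (pre + rec)`; `NA` when either input
#' is `NA` or the denominator is zero.
#'
#' @param pre,rec Precision and recall in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(pre, rec) {
  ifelse(is.na(pre) | is.na(rec) | (pre + rec) == 0, NA_real_,
         2 * pre * rec / (pre + rec))
}

#' Rank-based area under the ROC curve
#'
#' Computed from the Mann-Whitney statistic via midranks, so tied scores
#' contribute 1/2; equal to the trapezoidal ROC integral on tie-free data.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both classes", class = "tcrcost_metric_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report for probabilistic predictions
#'
#' @param truth 0/1 vector.
#' @param prob Predicted probabilities.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return A one-row tibble with `acc`, `rec`, `pre`, `f1`, `auc` and the
#'   confusion counts.
#' @export
metric_report <- function(truth, prob, threshold = 0.5) {
  counts <- confusion_counts(truth, as.integer(prob >= threshold))
  dplyr::bind_cols(classification_metrics(counts),
                   auc = auc_score(truth, prob), counts)
}

#' Random train/test split and cross-validation folds
#'
#' Draws a seeded random split at the given ratio and a disjoint k-fold
#' partition of the same samples. When `group` is supplied (e.g. TCR
#' identifiers), whole groups are assigned to one side of the split and to
#' one fold, so no group appears in both a training and a test set.
#'
#' @param n Number of samples, or a data frame whose rows are samples.
#' @param ratio Training fraction for the single split (default 0.8).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param group Optional grouping vector of length `n`.
#' @return A list with `train` and `test` index vectors and `folds`, a list
#'   of per-fold test index vectors (pairwise disjoint, covering all
#'   samples).
#' @export
cv_split <- function(n, ratio = 0.8, folds = 5L, seed = 1L, group = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < folds) abort("need at least as many samples as folds",
                       class = "tcrcost_metric_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(group)) group <- seq_len(n)
  g <- unique(group)
  gperm <- sample(g)
  n_train_g <- round(ratio * length(gperm))
  train_g <- gperm[seq_len(n_train_g)]
  train <- which(group %in% train_g)
  test <- setdiff(seq_len(n), train)
  fold_of_g <- setNames(rep_len(seq_len(folds), length(gperm)), gperm)
  fold_assign <- fold_of_g[as.character(group)]
  fold_sets <- lapply(seq_len(folds), function(k) which(fold_assign == k))
  list(train = train, test = test, folds = fold_sets)
}
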