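# Confusion-matrix metrics, the repeated 90/10 holdout protocol, and
# TOPSIS scoring of feature subsets.

#' Confusion matrix with accuracy, precision and recall
#'
#' Rows are true stages, columns predicted stages. Accuracy is the trace
#' over the total; precision of a predicted stage is its diagonal count
#' over the column sum; recall of a true stage is its diagonal count over
#' the row sum. A stage never predicted (empty column) has undefined
#' precision, reported as `NA`; likewise recall for an absent true stage.
#'
#' @param true_labels,predicted_labels equal-length vectors over
#'   `sleep_stages()` (or any common label set given in `levels`).
#' @param levels label set defining the matrix order.
#' @return object of class `sleep_confusion`: list with `matrix`,
#'   `accuracy`, `precision`, `recall`, `n`.
#' @export
confusion_and_metrics <- function(true_labels, predicted_labels,
                                  levels = sleep_stages()) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  tl <- factor(as.character(true_labels), levels = levels)
  pl <- factor(as.character(predicted_labels), levels = levels)
  if (anyNA(tl) || anyNA(pl)) stop("labels outside the declared level set")
  cm <- table(true = tl, predicted = pl)
  diagc <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  structure(list(
    matrix = cm,
    accuracy = sum(diagc) / sum(cm),
    precision = ifelse(colsum > 0, diagc / colsum, NA_real_),
    recall = ifelse(rowsum > 0, diagc / rowsum, NA_real_),
    n = sum(cm)
  ), class = "sleep_confusion")
}

#' @export
print.sleep_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d epochs), accuracy %.4f\n", x$n, x$accuracy))
  print(x$matrix)
  cat("\nPer-stage precision:\n")
  print(round(x$precision, 4))
  cat("Per-stage recall:\n")
  print(round(x$recall, 4))
  invisible(x)
}

#' @keywords internal
#' Stratified train/test split: returns test-row indices.
.stratified_test_split <- function(stage, test_fraction, stratify = TRUE) {
  n <- length(stage)
  if (!stratify) return(sample(n, max(1L, round(test_fraction * n))))
  unlist(lapply(split(seq_len(n), stage), function(idx) {
    if (length(idx) == 0L) return(integer(0))
    sample(idx, max(1L, round(test_fraction * length(idx))))
  }), use.names = FALSE)
}

#' Repeated holdout evaluation of the cascade
#'
#' Repeats: split the epochs into train/test (stratified by stage), rank
#' features by MIQ on the training rows only, fit [cascade_svm()], and
#' evaluate on the held-out rows. Reports per-repeat overall accuracy and
#' N1 recall, with their means and standard deviations.
#'
#' @param feature_table data.frame with the 51 canonical feature columns.
#' @param stage five-stage labels, one per row.
#' @param n_repeats number of random splits (default 5).
#' @param test_fraction held-out fraction (default 0.1).
#' @param seed integer; repeat `i` uses `seed + i` for its split, ranking
#'   subsample and model seeds, making the whole protocol reproducible.
#' @param stratify stratify the split by stage (default TRUE; keeps rare
#'   N1 present in both halves).
#' @param ... passed to [cascade_svm()] (e.g. `Const`, `k1`, `k2`).
#' @return list with `per_repeat` (data.frame: repeat, accuracy,
#'   n1_accuracy), `mean_accuracy`, `sd_accuracy`, `mean_n1_accuracy`,
#'   `sd_n1_accuracy`, and the last repeat's confusion matrix as `last`.
#' @export
repeated_holdout <- function(feature_table, stage, n_repeats = 5L,
                             test_fraction = 0.1, seed = 1L,
                             stratify = TRUE, ...) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  stage <- factor(as.character(stage), levels = sleep_stages())
  acc <- n1acc <- numeric(n_repeats)
  last_cm <- NULL
  for (rep_i in seq_len(n_repeats)) {
    rs <- seed + rep_i
    test_idx <- .with_seed(rs, .stratified_test_split(stage, test_fraction,
                                                      stratify))
    tr <- setdiff(seq_len(nrow(feature_table)), test_idx)
    if (any(table(stage[tr]) == 0L)) {
      warning(sprintf("repeat %d: a stage is absent from the training split; skipped",
                      rep_i))
      acc[rep_i] <- n1acc[rep_i] <- NA_real_
      next
    }
    fit <- cascade_svm(feature_table[tr, , drop = FALSE], stage[tr],
                       seed = rs, ...)
    pred <- predict(fit, feature_table[test_idx, , drop = FALSE])
    cm <- confusion_and_metrics(stage[test_idx], pred)
    acc[rep_i] <- cm$accuracy
    n1acc[rep_i] <- cm$recall[["N1"]]
    last_cm <- cm
  }
  list(per_repeat = data.frame(repeat_i = seq_len(n_repeats),
                               accuracy = acc, n1_accuracy = n1acc),
       mean_accuracy = mean(acc, na.rm = TRUE),
       sd_accuracy = stats::sd(acc, na.rm = TRUE),
       mean_n1_accuracy = mean(n1acc, na.rm = TRUE),
       sd_n1_accuracy = stats::sd(n1acc, na.rm = TRUE),
       last = last_cm)
}

#' TOPSIS scores for candidate feature subsets
#'
#' Scores items described by (computing time, average accuracy, N1
#' accuracy). Each criterion is min-max normalised to [0, 1] with time as
#' a cost (smaller is better) and the accuracies as benefits; the ideal
#' and anti-ideal vectors are then all-ones and all-zeros, and the score
#' of an item is `D- / (D+ + D-)` with weighted Euclidean distances
#' (square root applied) to the two ideals. `sqrt_distance = FALSE`
#' computes the distances without the square root.
#'
#' A criterion with no spread (max == min) cannot discriminate and is
#' dropped with a warning.
#'
#' @param items data.frame with columns `time`, `accuracy`, `n1_accuracy`
#'   (a `name` column is carried through if present).
#' @param weights positive weights for the three criteria, default equal
#'   thirds.
#' @param sqrt_distance take the square root in the distance (default
#'   TRUE, the standard TOPSIS form).
#' @return `items` with added columns `v_time`, `v_accuracy`,
#'   `v_n1_accuracy`, `d_plus`, `d_minus`, `score`.
#' @export
topsis_scores <- function(items, weights = rep(1 / 3, 3),
                          sqrt_distance = TRUE) {
  items <- as.data.frame(items)
  need <- c("time", "accuracy", "n1_accuracy")
  if (!all(need %in% names(items)))
    stop("items must have columns time, accuracy, n1_accuracy")
  if (nrow(items) < 2L) stop("need at least two items to compare")
  if (length(weights) != 3L || any(weights < 0))
    stop("weights must be three non-negative numbers")
  norm_benefit <- function(x) (x - min(x)) / (max(x) - min(x))
  norm_cost <- function(x) (max(x) - x) / (max(x) - min(x))
  v <- cbind(
    v_time = if (diff(range(items$time)) > 0) norm_cost(items$time) else NA_real_,
    v_accuracy = if (diff(range(items$accuracy)) > 0)
      norm_benefit(items$accuracy) else NA_real_,
    v_n1_accuracy = if (diff(range(items$n1_accuracy)) > 0)
      norm_benefit(items$n1_accuracy) else NA_real_)
  keep <- !is.na(v[1L, ])
  if (!all(keep))
    warning("criterion without spread dropped: ",
            paste(colnames(v)[!keep], collapse = ", "))
  if (!any(keep)) stop("no criterion discriminates between the items")
  w <- weights[keep]
  vk <- v[, keep, drop = FALSE]
  dplus <- sapply(seq_len(nrow(vk)), function(i) sum(w * (vk[i, ] - 1)^2))
  dminus <- sapply(seq_len(nrow(vk)), function(i) sum(w * (vk[i, ] - 0)^2))
  if (sqrt_distance) {
    dplus <- sqrt(dplus)
    dminus <- sqrt(dminus)
  }
  items$v_time <- v[, "v_time"]
  items$v_accuracy <- v[, "v_accuracy"]
  items$v_n1_accuracy <- v[, "v_n1_accuracy"]
  items$d_plus <- dplus
  items$d_minus <- dminus
  items$score <- dminus / (dplus + dminus)
  items
}
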