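#' Threshold metrics from confusion counts
#'
#' Closed-form accuracy, precision, sensitivity (recall), specificity, F1
#' and Matthews correlation from TP/TN/FP/FN. Any metric with a zero
#' denominator is reported as 0 and flagged in the `degenerate` attribute.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble with columns `acc`, `precision`, `sn`, `sp`,
#'   `f1`, `mcc`, plus the counts.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) abort("invalid confusion counts")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  acc <- (tp + tn) / sum(counts)
  precision <- safe(tp, tp + fp, "precision")
  sn <- safe(tp, tp + fn, "sn")
  sp <- safe(tn, tn + fp, "sp")
  f1 <- safe(2 * precision * sn, precision + sn, "f1")
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (tp * tn - fn * fp) / mcc_den
  out <- tibble::tibble(acc = acc, precision = precision, sn = sn, sp = sp,
                        f1 = f1, mcc = mcc, tp = tp, tn = tn, fp = fp, fn = fn)
  attr(out, "degenerate") <- degenerate
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with tied scores credited one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) abort("AUC undefined with a single class")
  r <- rank(scores)  # mean ranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal area under the precision-recall curve
#'
#' Sweeps the decision threshold over the distinct scores (descending)
#' and accumulates `sum (R_k - R_{k-1}) * (P_k + P_{k-1}) / 2`, starting
#' from recall 0 at the first point's precision.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0 || n1 == length(labels)) abort("AUPR undefined with a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cut <- which(!duplicated(s, fromLast = TRUE))  # last index of each distinct score
  tp <- cumsum(y)[cut]
  npred <- cut
  prec <- tp / npred
  rec <- tp / n1
  prec <- c(prec[1], prec); rec <- c(0, rec)
  sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
}

#' Score a prediction vector against labels
#'
#' Combines threshold metrics (hard labels at `threshold`) with the
#' ranking metrics AUC and AUPR.
#'
#' @inheritParams roc_auc
#' @param threshold Hard-label cut-off (default 0.5).
#' @return One-row tibble: `acc`, `precision`, `sn`, `sp`, `f1`, `mcc`,
#'   `auc`, `aupr`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  cm <- confusion_metrics(sum(pred == 1 & labels == 1),
                          sum(pred == 0 & labels == 0),
                          sum(pred == 1 & labels == 0),
                          sum(pred == 0 & labels == 1))
  dplyr::bind_cols(cm[c("acc", "precision", "sn", "sp", "f1", "mcc")],
                   tibble::tibble(auc = roc_auc(scores, labels),
                                  aupr = pr_auc(scores, labels),
                                  threshold = threshold))
}

#' Stratified cross-validation fold assignment
#'
#' Assigns rows to `n_folds` folds preserving the class ratio within one
#' sample per fold; deterministic under `seed`.
#'
#' @param labels Binary 0/1 labels.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds, seed = 42) {
  labels <- check_binary_labels(labels)
  if (n_folds < 2) abort("n_folds must be >= 2")
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated evaluation harness
#'
#' Fits `model_factory(train_features, train_labels)` on each stratified
#' training split and scores the held-out fold; the factory must return an
#' object whose `predict_scores(model, features)` method (any function
#' passed as `predictor`) yields probability scores.
#'
#' @param features Feature data frame or matrix.
#' @param labels Binary 0/1 labels.
#' @param model_factory `function(features, labels) -> model`.
#' @param predictor `function(model, features) -> scores` (defaults to the
#'   stacking predictor's score column when given a `stacking_model`).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `cv_report`: per-fold metric tibble, mean
#'   and sd rows, and the fold assignment.
#' @export
crossval_evaluate <- function(features, labels, model_factory,
                              predictor = default_predictor, n_folds = 5,
                              seed = 42) {
  x <- feature_matrix(features)
  labels <- check_binary_labels(labels)
  folds <- stratified_folds(labels, n_folds, seed = seed)
  per_fold <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- folds != f
    model <- model_factory(x[tr, , drop = FALSE], labels[tr])
    scores <- predictor(model, x[!tr, , drop = FALSE])
    dplyr::bind_cols(tibble::tibble(fold = f),
                     evaluate_scores(scores, labels[!tr]))
  })
  metric_cols <- c("acc", "precision", "sn", "sp", "f1", "mcc", "auc", "aupr")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd),
                 folds = folds, n_folds = n_folds, seed = seed),
            class = "cv_report")
}

default_predictor <- function(model, features) {
  if (inherits(model, "stacking_model")) predict_stacking(model, features)$score
  else if (inherits(model, "oneshot_state")) predict_oneshot(model, features)$score
  else if (inherits(model, "base_learner_fit")) predict_base_learner(model, features)
  else stop("supply a predictor for this model type")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$n_folds, " folds; mean AUC=",
      signif(x$mean[["auc"]], 4), " AUPR=", signif(x$mean[["aupr"]], 4), "\n",
      sep = "")
  invisible(x)
}

#' @rdname crossval_evaluate
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @rdname crossval_evaluate
#' @export
glance.cv_report <- function(x, ...) {
  tibble::as_tibble(as.list(x$mean))
}

#' @rdname crossval_evaluate
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$per_fold, -"fold",
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(y = "value", x = NULL, title = "Cross-validated metrics") +
    ggplot2::theme_minimal()
}
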