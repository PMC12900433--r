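#' One-way ANOVA F score of a single feature
#'
#' Ratio of between-group to within-group variance:
#' `F = [sum n_i (xbar_i - xbar)^2 / (k - 1)] / [sum sum (x_ij - xbar_i)^2 / (N - k)]`.
#' A zero within-group variance with non-zero between-group variance
#' yields `Inf` (perfect separation); a constant feature with equal group
#' means (0/0) is defined as 0, ranking it last as uninformative.
#'
#' @param x Numeric feature column.
#' @param labels Group labels (>= 2 groups, each non-empty).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
f_score <- function(x, labels) {
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  if (k < 2) abort("need at least two groups")
  n <- length(x)
  if (n - k < 1) abort("need N - k >= 1 residual degrees of freedom")
  comp <- f_components(x, labels)
  if (comp$within == 0) {
    if (comp$between == 0) return(0)
    return(Inf)
  }
  comp$between / comp$within
}

f_components <- function(x, labels) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  n <- length(x)
  grand <- mean(x)
  means <- tapply(x, labels, mean)
  sizes <- tabulate(labels)
  between <- sum(sizes * (means - grand)^2) / (k - 1)
  within <- sum((x - means[as.integer(labels)])^2) / (n - k)
  list(between = between, within = within)
}

#' Rank features by F score and keep the top k
#'
#' Computes the one-way ANOVA F value of every feature column against the
#' labels, keeps the `k_selected` highest (ties broken by column index)
#' and reports the mean F of both the full and selected sets.
#'
#' @param features Feature data frame or matrix.
#' @param labels Group labels.
#' @param k_selected Number of features to keep (default 140).
#' @return An object of class `f_test_result`: per-feature table
#'   (`feature`, `index`, `f`, `between`, `within`), `selected` indices
#'   (F-descending), `mean_f_all`, `mean_f_selected`.
#' @export
select_top_k <- function(features, labels, k_selected = 140) {
  x <- feature_matrix(features)
  if (k_selected < 1 || k_selected > ncol(x))
    abort("k_selected out of range")
  labels <- as.factor(labels)
  comp <- lapply(seq_len(ncol(x)), function(j) f_components(x[, j], labels))
  between <- vapply(comp, `[[`, numeric(1), "between")
  within <- vapply(comp, `[[`, numeric(1), "within")
  f <- ifelse(within == 0, ifelse(between == 0, 0, Inf), between / within)
  ord <- order(-f, seq_along(f))
  selected <- ord[seq_len(k_selected)]
  tab <- tibble::tibble(feature = colnames(x) %||% paste0("f", seq_along(f)),
                        index = seq_along(f), f = f,
                        between = between, within = within)
  structure(list(table = tab, selected = selected, k_selected = k_selected,
                 mean_f_all = mean(f[is.finite(f)]),
                 mean_f_selected = mean(f[selected][is.finite(f[selected])])),
            class = "f_test_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column-subset a feature table to the selected features
#'
#' @param features Feature data frame or matrix.
#' @param result An `f_test_result` from [select_top_k()].
#' @return The same container type restricted to the selected columns,
#'   row order preserved.
#' @export
reduce_matrix <- function(features, result) {
  stopifnot(inherits(result, "f_test_result"))
  x <- feature_matrix(features)
  if (max(result$selected) > ncol(x)) abort("selected index out of range")
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1))
    num[names(features) == "label"] <- FALSE
    features[which(num)[result$selected]]
  } else {
    x[, result$selected, drop = FALSE]
  }
}

#' @export
print.f_test_result <- function(x, ...) {
  cat("<f_test_result> ", x$k_selected, "/", nrow(x$table),
      " features selected; mean F all=", signif(x$mean_f_all, 4),
      ", selected=", signif(x$mean_f_selected, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname select_top_k
#' @param x An `f_test_result`.
#' @param ... Unused.
#' @export
tidy.f_test_result <- function(x, ...) {
  dplyr::mutate(x$table, selected = .data$index %in% x$selected)
}

#' @rdname select_top_k
#' @export
glance.f_test_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$table), k_selected = x$k_selected,
                 mean_f_all = x$mean_f_all, mean_f_selected = x$mean_f_selected)
}

#' @rdname select_top_k
#' @param object An `f_test_result`.
#' @export
autoplot.f_test_result <- function(object, ...) {
  dat <- tidy(object)
  dat$f[!is.finite(dat$f)] <- max(dat$f[is.finite(dat$f)], 1) * 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$f, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "F value (log scale)", y = "features",
                  title = "Per-feature ANOVA F values") +
    ggplot2::theme_minimal()
}
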