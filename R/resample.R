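#' K-means similarity undersampling (cluster + most-similar-pair removal)
#'
#' The default AMDKSU variant. Majority-class rows are partitioned into
#' `n_clusters` K-means clusters; within each cluster all pairwise
#' distances under `metric` are ranked ascending, and the `N = majority -
#' target` globally most-similar *disjoint* pairs are selected greedily
#' (ascending distance, ties by row index; a row joins at most one pair).
#' One member of each selected pair is then removed uniformly at random.
#' When `N` exceeds the number of disjoint pairs available, selection
#' proceeds in further rounds over the surviving rows (within their
#' original clusters) until the target is met. Minority rows are never
#' touched; the default target equals the minority count, giving the 1:1
#' balanced output used for training.
#'
#' @param features Feature data frame or matrix (numeric columns).
#' @param labels Binary 0/1 vector.
#' @param n_clusters Number of K-means clusters; default
#'   `max(2, floor(sqrt(majority / 2)))`.
#' @param metric,p,quantizer Distance settings (see [pair_distance()]).
#' @param target Majority rows to retain (default: minority count).
#' @param seed Integer seed (K-means initialisation and pair-member
#'   removal).
#' @return An object of class `resample_result` with `retained` (all kept
#'   row indices), `removed` (removed majority rows), `per_cluster`
#'   removal counts and distance diagnostics.
#' @export
ksu_pairs_undersample <- function(features, labels, n_clusters = NULL,
                                  metric = "euclidean", p = 3,
                                  quantizer = "median", target = NULL,
                                  seed = 42) {
  x <- feature_matrix(features)
  labels <- check_binary_labels(labels)
  cls <- split_classes(labels)
  target <- resolve_target(target, cls)
  n_remove <- length(cls$majority) - target
  maj_x <- x[cls$majority, , drop = FALSE]
  if (metric == "hamming" && identical(quantizer, "median"))
    maj_x <- quantize_binary(maj_x)
  dist_q <- if (metric == "hamming") "none" else quantizer

  if (is.null(n_clusters))
    n_clusters <- max(2, floor(sqrt(length(cls$majority) / 2)))
  n_clusters <- min(n_clusters, nrow(unique(maj_x)))
  n_clusters <- max(n_clusters, 1L)
  assign_cl <- local_seed(derive_seed(seed, 1), {
    if (n_clusters == 1L) rep(1L, nrow(maj_x))
    else kmeans(maj_x, centers = n_clusters, nstart = 5, iter.max = 50)$cluster
  })

  removed <- integer(0)   # positions within cls$majority
  alive <- rep(TRUE, nrow(maj_x))
  smallest <- numeric(0)
  sel_pairs <- list()
  local_seed(derive_seed(seed, 2), {
    while (length(removed) < n_remove) {
      cand <- intra_cluster_pairs(maj_x, assign_cl, alive, metric, p, dist_q)
      if (nrow(cand) == 0) {
        # no pair can be formed (lone survivors per cluster): drop at random
        left <- which(alive)
        drop <- left[sample.int(length(left), n_remove - length(removed))]
        alive[drop] <- FALSE
        removed <- c(removed, drop)
        break
      }
      cand <- cand[order(cand$dist, cand$i, cand$j), ]
      used <- logical(nrow(maj_x))
      picked <- 0L
      for (r in seq_len(nrow(cand))) {
        if (length(removed) >= n_remove) break
        i <- cand$i[r]; j <- cand$j[r]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        picked <- picked + 1L
        victim <- if (runif(1) < 0.5) i else j
        alive[victim] <- FALSE
        removed <- c(removed, victim)
        smallest <- c(smallest, cand$dist[r])
        sel_pairs[[length(sel_pairs) + 1]] <-
          c(cls$majority[i], cls$majority[j], cand$dist[r])
      }
      if (picked == 0L) break  # defensive; cannot make progress
    }
  })

  out <- build_resample_result(cls, removed, assign_cl, metric, smallest,
                               variant = "ksu_pairs", seed = seed)
  out$diagnostics$selected_pairs <- if (length(sel_pairs))
    tibble::tibble(i = vapply(sel_pairs, `[`, numeric(1), 1),
                   j = vapply(sel_pairs, `[`, numeric(1), 2),
                   dist = vapply(sel_pairs, `[`, numeric(1), 3))
  else tibble::tibble(i = numeric(), j = numeric(), dist = numeric())
  out
}

intra_cluster_pairs <- function(maj_x, assign_cl, alive, metric, p, quantizer) {
  out <- list()
  for (cl in sort(unique(assign_cl))) {
    rows <- which(alive & assign_cl == cl)
    if (length(rows) < 2) next
    dm <- distance_matrix(maj_x[rows, , drop = FALSE], metric = metric, p = p,
                          quantizer = quantizer)
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    out[[length(out) + 1]] <- tibble::tibble(
      i = rows[idx[, 1]], j = rows[idx[, 2]], dist = dm[idx], cluster = cl)
  }
  if (length(out) == 0)
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric(),
                          cluster = integer()))
  dplyr::bind_rows(out)
}

#' Edited-nearest-neighbour undersampling
#'
#' The secondary AMDKSU variant: a row is marked for removal when at least
#' `k_nn / 2` of its `k_nn` nearest neighbours (self excluded, under
#' `metric`) carry a different label. Removal is applied to majority rows
#' only, preserving undersampling semantics.
#'
#' @inheritParams ksu_pairs_undersample
#' @param k_nn Neighbourhood size (default 5); must be below the number of
#'   rows.
#' @return A `resample_result`.
#' @export
enn_edit_undersample <- function(features, labels, k_nn = 5,
                                 metric = "euclidean", p = 3,
                                 quantizer = "median") {
  x <- feature_matrix(features)
  labels <- check_binary_labels(labels)
  if (k_nn < 1) abort("k_nn must be >= 1")
  if (k_nn >= nrow(x)) abort("k_nn must be smaller than the number of rows")
  if (length(unique(labels)) == 1) {
    # homogeneous data: no neighbourhood disagreement, nothing to edit
    cls <- list(majority = seq_len(nrow(x)), minority = integer(0))
    return(build_resample_result(cls, integer(0), NULL, metric, numeric(0),
                                 variant = "enn_edit", seed = NA))
  }
  cls <- split_classes(labels)
  dm <- distance_matrix(x, metric = metric, p = p, quantizer = quantizer)
  diag(dm) <- Inf
  marked <- vapply(seq_len(nrow(x)), function(i) {
    nb <- order(dm[i, ], seq_len(ncol(dm)))[seq_len(k_nn)]
    sum(labels[nb] != labels[i]) >= k_nn / 2
  }, logical(1))
  removed_rows <- intersect(which(marked), cls$majority)
  removed_pos <- match(removed_rows, cls$majority)
  build_resample_result(cls, removed_pos, assign_cl = NULL, metric = metric,
                        smallest = numeric(0), variant = "enn_edit", seed = NA)
}

#' Drug-grouped similarity undersampling
#'
#' Partitions majority rows by a grouping key (typically the drug id of
#' each pair), assigns each group a proportional share of the global
#' retention target by largest-remainder rounding, and applies
#' [ksu_pairs_undersample()] independently within each group so that local
#' balance is preserved while the global retained majority count exactly
#' equals `target`. Groups whose quota exceeds their size have the excess
#' redistributed (with a message).
#'
#' @inheritParams ksu_pairs_undersample
#' @param groups Vector of group keys, one per row (values for minority
#'   rows are ignored).
#' @return A `resample_result`; `per_cluster` carries per-group counts.
#' @export
grouped_undersample <- function(features, labels, groups, n_clusters = NULL,
                                metric = "euclidean", p = 3,
                                quantizer = "median", target = NULL,
                                seed = 42) {
  x <- feature_matrix(features)
  labels <- check_binary_labels(labels)
  if (length(groups) != nrow(x)) abort("groups must have one entry per row")
  cls <- split_classes(labels)
  target <- resolve_target(target, cls)
  maj_groups <- as.character(groups[cls$majority])
  if (length(unique(maj_groups)) == 1) {
    # degenerate partition: identical to ungrouped KSU
    out <- ksu_pairs_undersample(x, labels, n_clusters = n_clusters,
                                 metric = metric, p = p,
                                 quantizer = quantizer, target = target,
                                 seed = seed)
    out$variant <- "grouped_ksu"
    return(out)
  }
  sizes <- table(maj_groups)
  quota <- largest_remainder(as.numeric(sizes) / sum(sizes) * target, target)
  names(quota) <- names(sizes)
  over <- quota > as.numeric(sizes)
  if (any(over)) {
    excess <- sum(quota[over] - as.numeric(sizes)[over])
    message("redistributing quota of ", excess, " row(s) from full group(s): ",
            paste(names(quota)[over], collapse = ", "))
    quota[over] <- as.numeric(sizes)[over]
    room <- as.numeric(sizes) - quota
    while (excess > 0 && any(room > 0)) {
      g <- which.max(room)
      quota[g] <- quota[g] + 1; room[g] <- room[g] - 1; excess <- excess - 1
    }
  }
  retained <- cls$minority
  removed <- integer(0)
  per_group <- list()
  for (gi in seq_along(sizes)) {
    g <- names(sizes)[gi]
    rows <- cls$majority[maj_groups == g]   # original row indices
    keep_g <- quota[[g]]
    if (keep_g == 0) {
      kept <- integer(0)
      rem <- rows
    } else if (length(rows) == 1 || keep_g >= length(rows)) {
      kept <- rows[seq_len(keep_g)]
      rem <- setdiff(rows, kept)
    } else {
      sub_labels <- c(rep(0L, length(rows)), rep(1L, keep_g))
      # embed a phantom minority of size keep_g so the per-group KSU target
      # resolves to the group's quota without touching real minority rows
      sub <- ksu_pairs_undersample(
        rbind(x[rows, , drop = FALSE],
              x[rows[seq_len(keep_g)], , drop = FALSE]),
        sub_labels, n_clusters = n_clusters, metric = metric, p = p,
        quantizer = quantizer, target = keep_g,
        seed = derive_seed(seed, gi))
      rem <- rows[sub$removed_majority_pos]
      kept <- setdiff(rows, rem)
    }
    retained <- c(retained, kept)
    removed <- c(removed, rem)
    per_group[[gi]] <- tibble::tibble(group = g, size = length(rows),
                                      quota = keep_g, removed = length(rem))
  }
  structure(list(
    retained = sort(retained), removed = sort(removed),
    removed_majority_pos = match(sort(removed), cls$majority),
    majority = cls$majority, minority = cls$minority,
    per_cluster = dplyr::bind_rows(per_group),
    metric = metric, variant = "grouped_ksu", seed = seed,
    diagnostics = list(quota = quota)), class = "resample_result")
}

largest_remainder <- function(raw, total) {
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Adaptive distance-metric selection
#'
#' Resamples the data once per candidate metric, scores each balanced set
#' with a cross-validated probe classifier (gradient-boosted trees with
#' the framework's reference hyperparameters) and returns the metric with
#' the highest mean validation AUC, ties broken by candidate order.
#'
#' @inheritParams ksu_pairs_undersample
#' @param candidate_metrics Character vector of metric names (>= 1).
#' @param probe_cv_folds Stratified CV folds for the probe (default 5).
#' @return A list of class `metric_selection`: `best` (metric name) and
#'   `scores` (tibble with one row per metric and its mean AUC).
#' @export
adaptive_metric_select <- function(features, labels,
                                   candidate_metrics = ddapre_metrics(),
                                   p = 3, n_clusters = NULL,
                                   probe_cv_folds = 5, seed = 42) {
  stopifnot(length(candidate_metrics) >= 1)
  x <- feature_matrix(features)
  labels <- check_binary_labels(labels)
  aucs <- vapply(seq_along(candidate_metrics), function(mi) {
    m <- candidate_metrics[mi]
    res <- ksu_pairs_undersample(x, labels, n_clusters = n_clusters,
                                 metric = m, p = p,
                                 seed = derive_seed(seed, mi))
    xs <- x[res$retained, , drop = FALSE]
    ys <- labels[res$retained]
    folds <- stratified_folds(ys, probe_cv_folds, seed = derive_seed(seed, 100 + mi))
    fold_auc <- vapply(seq_len(probe_cv_folds), function(f) {
      tr <- folds != f
      if (length(unique(ys[!tr])) < 2) return(NA_real_)
      fit <- fit_base_learner("gbt", xs[tr, , drop = FALSE], ys[tr], seed = 42)
      roc_auc(predict_base_learner(fit, xs[!tr, , drop = FALSE]), ys[!tr])
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  scores <- tibble::tibble(metric = candidate_metrics, auc = aucs)
  best <- candidate_metrics[which.max(aucs)]
  structure(list(best = best, scores = scores), class = "metric_selection")
}

split_classes <- function(labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  maj_label <- if (n0 >= n1) 0L else 1L
  list(majority = which(labels == maj_label),
       minority = which(labels != maj_label),
       maj_label = maj_label)
}

resolve_target <- function(target, cls) {
  if (is.null(target)) target <- length(cls$minority)
  if (target < 1) abort("target must be >= 1")
  if (target > length(cls$majority))
    abort("target exceeds the current majority count")
  as.integer(target)
}

build_resample_result <- function(cls, removed_pos, assign_cl, metric,
                                  smallest, variant, seed) {
  removed_rows <- sort(cls$majority[removed_pos])
  retained <- sort(c(cls$minority, setdiff(cls$majority, removed_rows)))
  per_cluster <- if (is.null(assign_cl)) {
    tibble::tibble(cluster = NA_integer_, size = length(cls$majority),
                   removed = length(removed_rows))
  } else {
    tab <- tibble::tibble(cluster = assign_cl,
                          removed = seq_along(assign_cl) %in% removed_pos)
    dplyr::summarise(dplyr::group_by(tab, .data$cluster),
                     size = dplyr::n(), removed = sum(.data$removed),
                     .groups = "drop")
  }
  structure(list(
    retained = retained, removed = removed_rows,
    removed_majority_pos = match(removed_rows, cls$majority),
    majority = cls$majority, minority = cls$minority,
    per_cluster = per_cluster, metric = metric, variant = variant,
    seed = seed,
    diagnostics = list(cluster_sizes = per_cluster$size,
                       nearest_pair_distances = smallest)),
    class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat("<resample_result> variant=", x$variant, " metric=", x$metric,
      " | majority ", length(x$majority), " -> ",
      length(x$majority) - length(x$removed), ", minority ",
      length(x$minority), " (untouched)\n", sep = "")
  invisible(x)
}

#' @rdname ksu_pairs_undersample
#' @param x A `resample_result`.
#' @param ... Unused.
#' @export
tidy.resample_result <- function(x, ...) {
  n <- length(x$majority) + length(x$minority)
  tibble::tibble(row = seq_len(n),
                 class = ifelse(seq_len(n) %in% x$majority, "majority", "minority"),
                 retained = seq_len(n) %in% x$retained)
}
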