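#' Base learner specifications
#'
#' Reference hyperparameters for the four Level-0 learners: gradient-
#' boosted trees (`gbt`: colsample 0.8, subsample 0.8, learning rate 0.1,
#' max depth 5, 100 rounds), CART (`cart`: min split 10, min leaf 5,
#' unlimited depth), random forest (`rf`: 30 trees, max depth 5, min node
#' size 10) and the training-free one-shot classifier (`oneshot`).
#' Overrides are merged over the defaults.
#'
#' @param kind One of `"gbt"`, `"cart"`, `"rf"`, `"oneshot"`.
#' @param ... Named hyperparameter overrides.
#' @return A list of class `base_learner_spec`.
#' @export
base_learner_spec <- function(kind = c("gbt", "cart", "rf", "oneshot"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    gbt = list(colsample_bytree = 0.8, subsample = 0.8, learning_rate = 0.1,
               max_depth = 5, n_estimators = 100),
    cart = list(min_samples_leaf = 5, min_samples_split = 10, max_depth = 30),
    rf = list(min_samples_leaf = 10, n_estimators = 30, max_depth = 5),
    oneshot = list(h = 1024, k_pca = 128))
  params <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, params = params), class = "base_learner_spec")
}

fit_base_learner <- function(spec, x, y, seed = 42) {
  if (is.character(spec)) spec <- base_learner_spec(spec)
  p <- spec$params
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- switch(spec$kind,
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$learning_rate,
                      max_depth = p$max_depth, subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = p$n_estimators, verbose = 0)
    },
    cart = {
      df <- data.frame(x, .y = factor(y, levels = c(0, 1)))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minsplit = p$min_samples_split,
                     minbucket = p$min_samples_leaf,
                     maxdepth = p$max_depth, cp = 0, xval = 0))
    },
    rf = {
      df <- data.frame(x, .y = factor(y, levels = c(0, 1)))
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = p$n_estimators, max.depth = p$max_depth,
                     min.node.size = p$min_samples_leaf, probability = TRUE,
                     seed = seed, num.threads = 1)
    },
    oneshot = fit_oneshot(x, y, h = p$h, k_pca = p$k_pca, seed = seed))
  structure(list(kind = spec$kind, fit = fit, n_features = ncol(x)),
            class = "base_learner_fit")
}

predict_base_learner <- function(model, x) {
  x <- feature_matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(model$kind,
    gbt = predict(model$fit, xgboost::xgb.DMatrix(x)),
    cart = predict(model$fit, data.frame(x))[, "1"],
    rf = predict(model$fit, data = data.frame(x),
                 num.threads = 1)$predictions[, "1"],
    oneshot = predict_oneshot(model$fit, x)$score)
}

#' Fit the two-layer stacking ensemble
#'
#' Level 0 holds four heterogeneous learners; their out-of-fold (OOF)
#' probabilities — each row predicted by a fold model that never saw it —
#' form the n x 4 feature matrix on which the Level-1 ridge-regularised
#' logistic meta-model is trained, then every base learner is refit on all
#' rows for inference. The one-shot learner generates its weights per fold
#' with no gradient updates at any point.
#'
#' @param features Feature data frame or matrix.
#' @param labels Binary 0/1 labels.
#' @param learners Character vector or list of [base_learner_spec()]s.
#' @param n_folds OOF folds (default 5, stratified).
#' @param meta_l2 L2 regularisation strength of the meta-model
#'   (default 1; the ridge penalty is `1/(n * meta_l2)`).
#' @param seed Integer seed.
#' @return An object of class `stacking_model` with the fitted base
#'   learners, the OOF matrix, the fold assignment and the meta-model.
#' @export
fit_stacking <- function(features, labels,
                         learners = c("gbt", "cart", "rf", "oneshot"),
                         n_folds = 5, meta_l2 = 1, seed = 42) {
  x <- feature_matrix(features)
  y <- check_binary_labels(labels)
  specs <- lapply(learners, function(l)
    if (is.character(l)) base_learner_spec(l) else l)
  names(specs) <- vapply(specs, `[[`, character(1), "kind")
  folds <- stratified_folds(y, n_folds, seed = seed)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2))
    abort("a fold contains a single class; reduce n_folds")
  oof <- matrix(NA_real_, nrow(x), length(specs),
                dimnames = list(NULL, names(specs)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    for (m in seq_along(specs)) {
      fit <- fit_base_learner(specs[[m]], x[tr, , drop = FALSE], y[tr],
                              seed = derive_seed(seed, f * 10 + m))
      oof[!tr, m] <- predict_base_learner(fit, x[!tr, , drop = FALSE])
    }
  }
  full_fits <- lapply(seq_along(specs), function(m)
    fit_base_learner(specs[[m]], x, y, seed = derive_seed(seed, m)))
  names(full_fits) <- names(specs)
  meta <- fit_meta_ridge(oof, y, meta_l2)
  structure(list(base = full_fits, meta = meta, oof = oof, folds = folds,
                 labels = y, specs = specs, n_folds = n_folds,
                 meta_l2 = meta_l2, seed = seed, n_features = ncol(x)),
            class = "stacking_model")
}

# Ridge logistic meta-model; a warm-start lambda path down to the target
# penalty keeps glmnet stable on near-separable OOF matrices.
fit_meta_ridge <- function(oof, y, meta_l2) {
  lam <- 1 / (nrow(oof) * meta_l2)
  path <- exp(seq(log(max(0.5, lam * 2)), log(lam), length.out = 25))
  path[length(path)] <- lam
  fit <- glmnet::glmnet(oof, y, family = "binomial", alpha = 0,
                        lambda = path, standardize = FALSE)
  list(fit = fit, lambda = lam)
}

predict_meta <- function(meta, newx) {
  as.numeric(predict(meta$fit, newx, s = meta$lambda, type = "response"))
}

coef_meta <- function(meta) {
  as.matrix(predict(meta$fit, s = meta$lambda, type = "coefficients"))
}

#' Predict with a stacking ensemble
#'
#' @param model A `stacking_model`.
#' @param features Feature data frame or matrix with the training
#'   dimensionality.
#' @param threshold Hard-label cut-off (default 0.5).
#' @return Tibble with per-learner probabilities, the fused `score` and
#'   `label_pred`.
#' @export
predict_stacking <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "stacking_model"))
  x <- feature_matrix(features)
  if (ncol(x) != model$n_features) abort("feature dimension mismatch")
  base_p <- vapply(model$base, predict_base_learner, numeric(nrow(x)), x = x)
  if (nrow(x) == 1) base_p <- matrix(base_p, nrow = 1,
                                     dimnames = list(NULL, names(model$base)))
  score <- predict_meta(model$meta, base_p)
  dplyr::bind_cols(tibble::as_tibble(base_p),
                   tibble::tibble(score = score,
                                  label_pred = as.integer(score >= threshold)))
}

#' @export
print.stacking_model <- function(x, ...) {
  cat("<stacking_model> base learners: ", paste(names(x$base), collapse = ", "),
      "; ", x$n_folds, "-fold OOF; n=", nrow(x$oof), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_stacking
#' @param x A `stacking_model`.
#' @param ... Unused.
#' @export
tidy.stacking_model <- function(x, ...) {
  co <- coef_meta(x$meta)
  tibble::tibble(term = rownames(co), estimate = co[, 1])
}

#' @rdname fit_stacking
#' @export
glance.stacking_model <- function(x, ...) {
  tibble::tibble(n = nrow(x$oof), n_folds = x$n_folds,
                 n_learners = length(x$base),
                 oof_auc = roc_auc(predict_meta(x$meta, x$oof), x$labels))
}

#' @rdname fit_stacking
#' @param object A `stacking_model`.
#' @export
autoplot.stacking_model <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[dat$term != "(Intercept)", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                    y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "meta-model coefficient",
                  title = "Learned base-learner weights") +
    ggplot2::theme_minimal()
}
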