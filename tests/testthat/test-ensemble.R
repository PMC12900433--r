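small_specs <- function() list(base_learner_spec("gbt", n_estimators = 30),
                               base_learner_spec("cart"),
                               base_learner_spec("rf"),
                               base_learner_spec("oneshot", h = 64, k_pca = 16))

fit_small_stack <- function(seed = 3, n_folds = 3) {
  fx <- make_planted_dataset(fixture_spec(n_drugs = 12, n_diseases = 25,
                                          n_features = 8, planted_dims = 1:2,
                                          positive_fraction = 0.3, seed = seed))
  x <- feature_matrix(fx$features); y <- fx$features$label
  list(x = x, y = y,
       model = fit_stacking(x, y, learners = small_specs(), n_folds = n_folds,
                            seed = seed))
}

test_that("OOF matrix is complete, bounded, and leakage-free", {
  s <- fit_small_stack(seed = 3)
  m <- s$model
  expect_equal(dim(m$oof), c(300, 4))
  expect_false(anyNA(m$oof))
  expect_true(all(m$oof >= 0 & m$oof <= 1))
  # audit: recomputing one fold's cart model from the stored assignment
  # reproduces the OOF entries, proving held-out rows were never trained on
  f <- 1
  tr <- m$folds != f
  refit <- ddapre:::fit_base_learner(m$specs[["cart"]], s$x[tr, , drop = FALSE],
                                     s$y[tr],
                                     seed = ddapre:::derive_seed(m$seed, f * 10 + 2))
  expect_equal(unname(m$oof[!tr, "cart"]),
               unname(ddapre:::predict_base_learner(refit, s$x[!tr, , drop = FALSE])))
})

test_that("meta-model is trained on the OOF matrix alone", {
  s <- fit_small_stack(seed = 5)
  m <- s$model
  refit <- ddapre:::fit_meta_ridge(m$oof, m$labels, meta_l2 = 1)
  expect_equal(as.numeric(ddapre:::coef_meta(m$meta)),
               as.numeric(ddapre:::coef_meta(refit)))
})

test_that("an uninformative constant learner earns a near-zero meta weight", {
  wins <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      y <- rbinom(300, 1, 0.5)
      oof <- cbind(informative = plogis(3 * (y - 0.5) + rnorm(300)),
                   constant = rep(0.5, 300))
    })
    meta <- ddapre:::fit_meta_ridge(oof, y, meta_l2 = 1)
    co <- as.numeric(ddapre:::coef_meta(meta))[-1]
    if (abs(co[2]) < 0.1 * abs(co[1])) wins <- wins + 1
  }
  expect_gt(wins, 15)
})

test_that("stacking prediction is deterministic and shape-checked", {
  s1 <- fit_small_stack(seed = 7)
  s2 <- fit_small_stack(seed = 7)
  p1 <- predict_stacking(s1$model, s1$x)
  p2 <- predict_stacking(s2$model, s2$x)
  expect_identical(p1, p2)
  expect_true(all(c("gbt", "cart", "rf", "oneshot", "score", "label_pred") %in%
                    names(p1)))
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_error(predict_stacking(s1$model, s1$x[, 1:3]), "dimension mismatch")
})

test_that("the fused model tracks its strongest base learner", {
  s <- fit_small_stack(seed = 9)
  holdout <- make_planted_dataset(fixture_spec(n_drugs = 12, n_diseases = 25,
                                               n_features = 8, planted_dims = 1:2,
                                               positive_fraction = 0.3, seed = 101))
  xq <- feature_matrix(holdout$features); yq <- holdout$features$label
  pred <- predict_stacking(s$model, xq)
  base_aucs <- vapply(c("gbt", "cart", "rf", "oneshot"),
                      function(b) roc_auc(pred[[b]], yq), numeric(1))
  ens_auc <- roc_auc(pred$score, yq)
  expect_gt(ens_auc, 0.9)
  expect_gte(ens_auc, max(base_aucs) - 0.05)
})

test_that("fold assignment rejects degenerate configurations", {
  x <- matrix(rnorm(40), 20, 2)
  y <- c(rep(0L, 18), 1L, 1L)
  expect_error(fit_stacking(x, y, learners = list(base_learner_spec("cart")),
                            n_folds = 5, seed = 1), "single class")
})

test_that("learner specs merge overrides over reference defaults", {
  spec <- base_learner_spec("gbt")
  expect_equal(spec$params$learning_rate, 0.1)
  expect_equal(spec$params$n_estimators, 100)
  expect_equal(spec$params$max_depth, 5)
  expect_equal(base_learner_spec("rf")$params$n_estimators, 30)
  expect_equal(base_learner_spec("cart")$params$min_samples_split, 10)
  over <- base_learner_spec("gbt", n_estimators = 7)
  expect_equal(over$params$n_estimators, 7)
  expect_error(base_learner_spec("svm"), "arg")
})
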