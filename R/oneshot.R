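#' Fit the training-free one-shot classifier
#'
#' A gradient-free classifier in the style of hypernetwork-generated
#' models: all layer weights are produced analytically from the support
#' set in a single pass. The stages are (1) per-feature standardisation
#' (sd floored at 1e-8); (2) a fixed Gaussian random projection followed
#' by ReLU, approximating an arc-cosine kernel map; (3) PCA to `k_pca`
#' components for compactness; (4) weight generation — the two hidden
#' layers of the three-layer residual MLP are seeded random maps scaled by
#' the pooled (global-average) activation statistics of the support set,
#' and the classification layer is built from class-prototype (class-wise
#' mean) vectors with biases set so the decision boundary bisects the
#' prototypes. No iterative optimisation happens anywhere. This is an
#' analytic stand-in for a pre-trained hypernetwork: the generation rules
#' are fixed formulas, not learned weights.
#'
#' @param support_features Feature data frame or matrix.
#' @param support_labels Binary 0/1 labels (both classes required).
#' @param h Random-feature width (default 1024).
#' @param k_pca Principal components kept (default 128, capped at the
#'   available rank).
#' @param seed Integer seed fixing the random projection and hidden maps.
#' @return An object of class `oneshot_state`.
#' @export
fit_oneshot <- function(support_features, support_labels, h = 1024,
                        k_pca = 128, seed = 42) {
  x <- feature_matrix(support_features)
  y <- check_binary_labels(support_labels)
  if (length(unique(y)) < 2) abort("support set must contain both classes")
  if (k_pca > h) abort("k_pca must not exceed h")
  # canonical row order: all pooled statistics are order-invariant in exact
  # arithmetic; sorting makes them bit-identical under row permutation too
  ord <- do.call(order, c(unname(as.list(as.data.frame(x))), list(y)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  mu <- colMeans(x)
  sigma <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  d <- ncol(x)
  proj <- local_seed(derive_seed(seed, 1), {
    list(R = matrix(rnorm(d * h) / sqrt(d), d, h), b = rnorm(h))
  })
  z <- relu(xs %*% proj$R + matrix(proj$b, nrow(xs), h, byrow = TRUE))
  z_center <- colMeans(z)
  zc <- sweep(z, 2, z_center)
  # PCA via eigendecomposition of the h x h covariance (h << n typically)
  eig <- eigen(crossprod(zc) / (nrow(zc) - 1), symmetric = TRUE)
  k_pca <- min(k_pca, sum(eig$values > 1e-10))
  w_k <- eig$vectors[, seq_len(k_pca), drop = FALSE]
  z_s <- zc %*% w_k

  # hidden-layer generation: seeded near-identity maps scaled by pooled
  # support statistics (global average pooling of activation energy)
  hidden <- local_seed(derive_seed(seed, 2), {
    lapply(1:2, function(l) {
      g <- matrix(rnorm(k_pca * k_pca), k_pca, k_pca)
      scale <- 0.1 / max(sqrt(mean(z_s^2)), 1e-8)
      g * scale
    })
  })
  h_s <- forward_hidden(z_s, hidden)
  proto0 <- colMeans(h_s[y == 0L, , drop = FALSE])
  proto1 <- colMeans(h_s[y == 1L, , drop = FALSE])
  w_cls <- cbind(proto0, proto1)
  b_cls <- -c(sum(proto0^2), sum(proto1^2)) / 2

  structure(list(mu = mu, sigma = sigma, R = proj$R, b = proj$b,
                 z_center = z_center, w_k = w_k, hidden = hidden,
                 w_cls = w_cls, b_cls = b_cls, h = h, k_pca = k_pca,
                 seed = seed, eigenvalues = eig$values),
            class = "oneshot_state")
}

relu <- function(x) pmax(x, 0)

forward_hidden <- function(z, hidden) {
  a <- z
  for (g in hidden) a <- relu(a %*% g) + a  # residual connection
  a
}

#' Predict with a fitted one-shot classifier
#'
#' Deterministic forward pass through the generated three-layer residual
#' network followed by softmax; weights are static (no updates, no
#' gradients).
#'
#' @param state An `oneshot_state` from [fit_oneshot()].
#' @param query_features Feature data frame or matrix with the same
#'   columns as the support set.
#' @return A tibble with `logit0`, `logit1`, `score` (softmax posterior of
#'   class 1).
#' @export
predict_oneshot <- function(state, query_features) {
  stopifnot(inherits(state, "oneshot_state"))
  x <- feature_matrix(query_features)
  if (ncol(x) != length(state$mu)) abort("feature dimension mismatch")
  xs <- sweep(sweep(x, 2, state$mu), 2, state$sigma, "/")
  z <- relu(xs %*% state$R + matrix(state$b, nrow(xs), state$h, byrow = TRUE))
  z_q <- sweep(z, 2, state$z_center) %*% state$w_k
  h_q <- forward_hidden(z_q, state$hidden)
  logits <- sweep(h_q %*% state$w_cls, 2, state$b_cls, "+")
  m <- pmax(logits[, 1], logits[, 2])
  p1 <- exp(logits[, 2] - m) / (exp(logits[, 1] - m) + exp(logits[, 2] - m))
  tibble::tibble(logit0 = logits[, 1], logit1 = logits[, 2], score = p1)
}

#' @export
print.oneshot_state <- function(x, ...) {
  cat("<oneshot_state> d=", length(x$mu), " h=", x$h, " k_pca=", x$k_pca,
      " (training-free)\n", sep = "")
  invisible(x)
}
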