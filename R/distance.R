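#' Distance metrics for similarity undersampling
#'
#' The resampler chooses adaptively among five metrics: euclidean
#' (straight-line), hamming (count of differing coordinates, applied after
#' a quantizer on continuous features), chebyshev (maximum coordinate
#' gap), manhattan (L1) and minkowski (Lp, `p >= 1`). `pair_distance()`
#' evaluates one pair; `distance_matrix()` returns the full symmetric
#' matrix for the rows of `x`.
#'
#' @param x,y Numeric vectors of equal length (or a numeric matrix /
#'   feature data frame for `distance_matrix()`).
#' @param metric One of `"euclidean"`, `"hamming"`, `"chebyshev"`,
#'   `"manhattan"`, `"minkowski"`.
#' @param p Minkowski order (`p >= 1`).
#' @param quantizer For hamming on continuous features: `"median"`
#'   (default) thresholds each feature at its per-feature median computed
#'   over the data being compared; `"none"` compares raw values for
#'   inequality.
#' @return `pair_distance()`: a non-negative scalar. `distance_matrix()`:
#'   an n x n symmetric matrix with zero diagonal.
#' @export
pair_distance <- function(x, y, metric = "euclidean", p = 3, quantizer = "none") {
  metric <- match.arg(metric, ddapre_metrics())
  if (length(x) != length(y)) abort("vectors must have equal length")
  d <- x - y
  switch(metric,
    euclidean = sqrt(sum(d^2)),
    manhattan = sum(abs(d)),
    chebyshev = max(abs(d)),
    minkowski = {
      if (p < 1) abort("minkowski order p must be >= 1")
      sum(abs(d)^p)^(1 / p)
    },
    hamming = {
      if (identical(quantizer, "median")) {
        thr <- (x + y) / 2  # degenerate two-point median split
        sum((x > thr) != (y > thr))
      } else sum(x != y)
    })
}

#' @rdname pair_distance
#' @export
distance_matrix <- function(x, metric = "euclidean", p = 3, quantizer = "median") {
  metric <- match.arg(metric, ddapre_metrics())
  x <- feature_matrix(x)
  if (metric == "hamming") {
    xq <- if (identical(quantizer, "median")) quantize_binary(x) else x
    # pairwise count of disagreeing coordinates
    m <- matrix(0, nrow(xq), nrow(xq))
    for (j in seq_len(ncol(xq))) m <- m + outer(xq[, j], xq[, j], "!=")
    return(m)
  }
  if (metric == "minkowski" && p < 1) abort("minkowski order p must be >= 1")
  method <- switch(metric, euclidean = "euclidean", manhattan = "manhattan",
                   chebyshev = "maximum", minkowski = "minkowski")
  as.matrix(stats::dist(x, method = method, p = p))
}

#' @rdname pair_distance
#' @export
ddapre_metrics <- function() {
  c("euclidean", "hamming", "chebyshev", "manhattan", "minkowski")
}

#' Median-split binary quantizer
#'
#' Maps each feature column to 0/1 by thresholding at its median (values
#' strictly above the median become 1), turning continuous embeddings into
#' the discrete codes the hamming metric is defined on.
#'
#' @param x Numeric matrix or feature data frame.
#' @return Integer 0/1 matrix of the same shape.
#' @export
quantize_binary <- function(x) {
  x <- feature_matrix(x)
  med <- apply(x, 2, stats::median)
  (sweep(x, 2, med, ">")) * 1L
}
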