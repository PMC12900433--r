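#' LIME-style local surrogate explanation for one prediction
#'
#' Explains a single instance of a black-box probability scorer by (1)
#' discretising every feature into quartile bins computed on background
#' data, (2) drawing perturbed samples that keep each feature's bin with
#' probability 1/2 and otherwise resample a random bin (values drawn
#' uniformly within the bin), (3) weighting perturbations by the proximity
#' kernel `exp(-d^2 / width^2)` on the binary same-bin representation, and
#' (4) fitting a weighted ridge regression on the `n_features_shown`
#' features chosen by forward selection. Contributions are the surrogate
#' coefficients of the instance's own bins, sorted by absolute magnitude,
#' each annotated with its bin-threshold rule string.
#'
#' @param scorer `function(feature_matrix) -> numeric scores`.
#' @param instance A single-row feature data frame / numeric vector.
#' @param background Background feature data frame (defines quartile bins
#'   and within-bin sampling ranges).
#' @param n_perturbations Number of perturbed samples (default 5000).
#' @param kernel_width Proximity kernel width (default `0.75 * sqrt(d)`).
#' @param n_features_shown Features retained in the surrogate (default 25,
#'   capped at `d`).
#' @param ridge Ridge penalty of the surrogate fit (default 1e-3).
#' @param keep_perturbations Also return the perturbation design (`z`),
#'   black-box responses (`y`) and kernel weights (`w`) under
#'   `$perturbations`, for fidelity diagnostics.
#' @param seed Integer seed.
#' @return An object of class `explanation`: tibble `contributions`
#'   (`feature`, `contribution`, `rule`), `intercept`, weighted `r2`, and
#'   the perturbation settings. A constant scorer yields all-zero
#'   contributions with `degenerate = TRUE`.
#' @export
explain_instance <- function(scorer, instance, background,
                             n_perturbations = 5000, kernel_width = NULL,
                             n_features_shown = 25, ridge = 1e-3,
                             keep_perturbations = FALSE, seed = 42) {
  bg <- feature_matrix(background)
  inst <- as.numeric(feature_matrix(if (is.numeric(instance))
    matrix(instance, 1) else instance))
  d <- ncol(bg)
  if (length(inst) != d) abort("instance/background dimension mismatch")
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
  n_features_shown <- min(n_features_shown, d)
  feat_names <- colnames(bg) %||% paste0("f", seq_len(d))

  qs <- apply(bg, 2, stats::quantile, probs = c(0, .25, .5, .75, 1))
  inst_bin <- vapply(seq_len(d), function(j)
    bin_of(inst[j], qs[, j]), integer(1))

  pert <- local_seed(seed, {
    same <- matrix(runif(n_perturbations * d) < 0.5, n_perturbations, d)
    xp <- matrix(0, n_perturbations, d)
    for (j in seq_len(d)) {
      bins <- ifelse(same[, j], inst_bin[j],
                     sample.int(4, n_perturbations, replace = TRUE))
      lo <- qs[bins, j]; hi <- qs[bins + 1, j]
      xp[, j] <- lo + runif(n_perturbations) * (hi - lo)
      same[, j] <- bins == inst_bin[j]  # resampled bin may coincide
    }
    list(x = xp, z = same * 1)
  })
  yp <- scorer(pert$x)
  w <- exp(-rowSums((1 - pert$z)^2) / kernel_width^2)

  if (stats::sd(yp) < 1e-12) {
    return(structure(list(
      contributions = tibble::tibble(feature = feat_names,
                                     contribution = 0,
                                     rule = rule_string(feat_names, inst_bin, qs))[
                                       seq_len(n_features_shown), ],
      intercept = mean(yp), r2 = 0, degenerate = TRUE,
      n_perturbations = n_perturbations, kernel_width = kernel_width,
      seed = seed), class = "explanation"))
  }

  chosen <- forward_select(pert$z, yp, w, n_features_shown, ridge)
  fit <- ridge_wls(pert$z[, chosen, drop = FALSE], yp, w, ridge)
  contrib <- numeric(d)
  contrib[chosen] <- fit$coef
  yhat <- fit$intercept + pert$z[, chosen, drop = FALSE] %*% fit$coef
  r2 <- 1 - sum(w * (yp - yhat)^2) / sum(w * (yp - weighted.mean(yp, w))^2)

  tab <- tibble::tibble(feature = feat_names[chosen],
                        contribution = contrib[chosen],
                        rule = rule_string(feat_names[chosen],
                                           inst_bin[chosen],
                                           qs[, chosen, drop = FALSE]))
  tab <- tab[order(-abs(tab$contribution)), ]
  structure(list(contributions = tab, intercept = fit$intercept, r2 = r2,
                 degenerate = FALSE, n_perturbations = n_perturbations,
                 kernel_width = kernel_width, seed = seed,
                 perturbations = if (keep_perturbations)
                   list(z = pert$z, y = yp, w = w)),
            class = "explanation")
}

bin_of <- function(v, q) {
  b <- findInterval(v, q[2:4]) + 1L  # quartile bins 1..4
  min(max(b, 1L), 4L)
}

rule_string <- function(names, bins, qs) {
  vapply(seq_along(names), function(i) {
    q <- qs[, i]
    switch(bins[i],
           paste0(names[i], " <= ", signif(q[2], 3)),
           paste0(signif(q[2], 3), " < ", names[i], " <= ", signif(q[3], 3)),
           paste0(signif(q[3], 3), " < ", names[i], " <= ", signif(q[4], 3)),
           paste0(names[i], " > ", signif(q[4], 3)))
  }, character(1))
}

ridge_wls <- function(z, y, w, ridge) {
  zc <- cbind(1, z)
  a <- crossprod(zc * w, zc) + diag(c(0, rep(ridge, ncol(z))))
  b <- crossprod(zc * w, y)
  beta <- solve(a, b)
  list(intercept = beta[1], coef = beta[-1])
}

forward_select <- function(z, y, w, k, ridge) {
  chosen <- integer(0)
  remaining <- seq_len(ncol(z))
  for (step in seq_len(min(k, ncol(z)))) {
    errs <- vapply(remaining, function(j) {
      cols <- c(chosen, j)
      fit <- ridge_wls(z[, cols, drop = FALSE], y, w, ridge)
      yhat <- fit$intercept + z[, cols, drop = FALSE] %*% fit$coef
      sum(w * (y - yhat)^2)
    }, numeric(1))
    best <- remaining[which.min(errs)]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

#' @export
print.explanation <- function(x, ...) {
  cat("<explanation> top contributions (local R2=", signif(x$r2, 3), "):\n",
      sep = "")
  print(utils::head(x$contributions, 10))
  invisible(x)
}

#' @rdname explain_instance
#' @param x An `explanation`.
#' @param ... Unused.
#' @export
tidy.explanation <- function(x, ...) x$contributions

#' @rdname explain_instance
#' @param object An `explanation`.
#' @export
autoplot.explanation <- function(object, ...) {
  dat <- object$contributions
  dat$rule <- factor(dat$rule, levels = rev(dat$rule))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rule, y = .data$contribution,
                                    fill = .data$contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkgreen", `FALSE` = "darkred")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "influence on prediction",
                  title = "Local surrogate contributions") +
    ggplot2::theme_minimal()
}
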