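# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# ROC AUC by exhaustive positive-negative pair counting (ties half credit).
bf_pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Greedy disjoint smallest-pairs selection over ALL pairwise distances
# (single-cluster KSU oracle). Returns the selected pairs in order.
bf_smallest_pairs <- function(x, n_pairs, dist_fun = function(a, b) sqrt(sum((a - b)^2))) {
  n <- nrow(x)
  cand <- expand.grid(i = seq_len(n), j = seq_len(n))
  cand <- cand[cand$i < cand$j, ]
  cand$dist <- mapply(function(i, j) dist_fun(x[i, ], x[j, ]), cand$i, cand$j)
  cand <- cand[order(cand$dist, cand$i, cand$j), ]
  used <- logical(n)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    if (length(out) >= n_pairs) break
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1]] <- c(i = i, j = j, dist = cand$dist[r])
  }
  do.call(rbind, out)
}

# Exhaustive ENN removal rule: majority rows whose k nearest neighbours
# (euclidean, self excluded, ties by index) disagree at rate >= k/2.
bf_enn_removed <- function(x, labels, k_nn) {
  n <- nrow(x)
  maj_label <- if (sum(labels == 0) >= sum(labels == 1)) 0 else 1
  removed <- integer(0)
  for (i in seq_len(n)) {
    d <- apply(x, 1, function(r) sqrt(sum((r - x[i, ])^2)))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k_nn)]
    if (sum(labels[nb] != labels[i]) >= k_nn / 2 && labels[i] == maj_label)
      removed <- c(removed, i)
  }
  removed
}

# Textbook one-way ANOVA F via group sums of squares.
bf_anova_f <- function(x, g) {
  g <- as.factor(g)
  k <- nlevels(g); n <- length(x)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Two-class gaussian blobs.
make_blobs <- function(n_per, gap, d = 2, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
               matrix(rnorm(n_per * d, gap, sd), n_per, d))
    list(x = x, y = rep(c(0L, 1L), each = n_per))
  })
}

# Forge a mesh_graph around an arbitrary undirected igraph (used for the
# clique-structure embedding checks, which need graphs a code tree cannot
# express).
forge_mesh_graph <- function(edge_df) {
  nodes <- unique(c(edge_df$from, edge_df$to))
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = data.frame(node = nodes))
  structure(list(nodes = tibble::tibble(node = nodes,
                                        disease_id = nodes,
                                        codes = as.list(nodes)),
                 edges = tibble::as_tibble(edge_df), graph = g),
            class = "mesh_graph")
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

planted_2000 <- function(seed, positive_fraction = 0.125, effect_size = 3) {
  make_planted_dataset(fixture_spec(n_drugs = 40, n_diseases = 50,
                                    n_features = 20, planted_dims = 1:4,
                                    positive_fraction = positive_fraction,
                                    effect_size = effect_size, seed = seed))
}
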