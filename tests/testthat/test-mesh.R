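dis1 <- function() tibble::tibble(disease_id = "D1", tree_numbers = list("A.B.C"))

test_that("truncation builds the full ancestor chain", {
  g <- build_mesh_dag(dis1())
  codes <- unlist(g$nodes$codes)
  expect_setequal(codes, c("A", "A.B", "A.B.C"))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(g$edges$parent_code, c("A", "A.B"))
  # the disease node is named by its id and carries the leaf code
  expect_true("D1" %in% g$nodes$node)
  expect_equal(g$edges$to[g$edges$parent_code == "A.B"], "D1")
})

test_that("multi-code diseases hang from every root, sharing one node", {
  dis <- tibble::tibble(disease_id = "D1", tree_numbers = list(c("A.B", "X.Y")))
  g <- build_mesh_dag(dis)
  expect_equal(sum(!is.na(g$nodes$disease_id)), 1)
  paths_a <- igraph::distances(g$graph, v = "A", to = "D1", mode = "out")
  paths_x <- igraph::distances(g$graph, v = "X", to = "D1", mode = "out")
  expect_true(is.finite(paths_a[1, 1]))
  expect_true(is.finite(paths_x[1, 1]))
})

test_that("shared prefixes create common ancestors with out-degree >= 2", {
  dis <- tibble::tibble(disease_id = c("D1", "D2"),
                        tree_numbers = list("A.B.C", "A.B.D"))
  g <- build_mesh_dag(dis)
  deg <- igraph::degree(g$graph, v = "A.B", mode = "out")
  expect_gte(unname(deg), 2)
})

test_that("DAG invariants hold on random fixtures; bad codes abort", {
  for (seed in 1:5) {
    dis <- make_toy_mesh(25, depth = 4, branching = 3, seed = seed)
    g <- build_mesh_dag(dis)
    expect_true(igraph::is_dag(g$graph))
    # ancestor closure: every multi-segment code has its parent materialised
    all_codes <- unlist(g$nodes$codes)
    deep <- all_codes[grepl(".", all_codes, fixed = TRUE)]
    expect_true(all(sub("\\.[^.]+$", "", deep) %in% all_codes))
  }
  bad <- tibble::tibble(disease_id = "D1", tree_numbers = list("A..B"))
  expect_error(build_mesh_dag(bad), "malformed tree number")
})

test_that("random walks stay on edges, are seeded, and stop at dead ends", {
  dis <- make_toy_mesh(15, seed = 2)
  g <- build_mesh_dag(dis)
  walks <- random_walks(g, walks_per_node = 3, walk_length = 12, seed = 5)
  expect_identical(walks, random_walks(g, 3, 12, seed = 5))
  expect_equal(length(walks), 3 * nrow(g$nodes))
  und <- igraph::as_undirected(g$graph)
  edge_ok <- vapply(walks, function(w) {
    if (length(w) < 2) return(TRUE)
    all(vapply(seq_len(length(w) - 1), function(t)
      igraph::are_adjacent(und, w[t], w[t + 1]), logical(1)))
  }, logical(1))
  expect_true(all(edge_ok))

  iso <- forge_mesh_graph(data.frame(from = "a", to = "b"))
  iso$graph <- igraph::add_vertices(iso$graph, 1, name = "lonely")
  w <- random_walks(iso, walks_per_node = 2, walk_length = 10, seed = 1)
  lonely <- w[vapply(w, function(x) x[1] == "lonely", logical(1))]
  expect_true(all(lengths(lonely) == 1))
})

test_that("transition frequencies are uniform over neighbours", {
  # star centre with two leaves: each leaf should receive half the steps
  star <- forge_mesh_graph(data.frame(from = c("c", "c"), to = c("a", "b")))
  walks <- random_walks(star, walks_per_node = 400, walk_length = 31, seed = 3)
  steps_from_c <- unlist(lapply(walks, function(w) {
    at_c <- which(w == "c")
    at_c <- at_c[at_c < length(w)]
    w[at_c + 1]
  }))
  n <- length(steps_from_c)
  expect_gt(n, 10000)
  frac_a <- mean(steps_from_c == "a")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / n))
})

test_that("deepwalk embeddings reflect graph structure", {
  # two disconnected 5-cliques: within-clique cosine must beat cross-clique
  cl <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  g <- forge_mesh_graph(rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:5))))
  wins <- 0
  for (seed in 1:20) {
    walks <- random_walks(g, walks_per_node = 8, walk_length = 15, seed = seed)
    emb <- embedding_matrix(train_deepwalk(walks, dim = 16, epochs = 3, seed = seed))
    a <- paste0("a", 1:5); b <- paste0("b", 1:5)
    within <- mean(c(apply(t(combn(a, 2)), 1, function(p) cosine(emb[p[1], ], emb[p[2], ])),
                     apply(t(combn(b, 2)), 1, function(p) cosine(emb[p[1], ], emb[p[2], ]))))
    cross <- mean(outer(a, b, Vectorize(function(i, j) cosine(emb[i, ], emb[j, ]))))
    if (within > cross) wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("parent-child pairs sit closer than random node pairs", {
  dis <- make_toy_mesh(20, depth = 4, branching = 3, seed = 8)
  g <- build_mesh_dag(dis)
  wins <- 0
  for (seed in 1:20) {
    walks <- random_walks(g, walks_per_node = 6, walk_length = 20, seed = seed)
    emb <- embedding_matrix(train_deepwalk(walks, dim = 16, epochs = 3, seed = seed))
    pc <- mean(apply(g$edges, 1, function(e) cosine(emb[e[["from"]], ], emb[e[["to"]], ])))
    rnd <- withr::with_seed(seed, {
      nodes <- rownames(emb)
      mean(replicate(200, {
        p <- sample(nodes, 2)
        cosine(emb[p[1], ], emb[p[2], ])
      }))
    })
    if (pc > rnd) wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("disease embedding excludes ancestors unless asked", {
  dis <- make_toy_mesh(12, seed = 4)
  emb <- embed_diseases(dis, dim = 8, walks_per_node = 3, walk_length = 10,
                        epochs = 2, seed = 1)
  expect_setequal(emb$id, dis$disease_id)
  emb_all <- embed_diseases(dis, dim = 8, walks_per_node = 3, walk_length = 10,
                            epochs = 2, seed = 1, include_ancestors = TRUE)
  expect_gt(nrow(emb_all), nrow(emb))
})
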