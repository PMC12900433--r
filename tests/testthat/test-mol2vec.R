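test_that("substructure sentences follow the length law", {
  # ethanol: 3 heavy atoms x radii {0,1}
  expect_length(molecule_to_sentence("CCO", radius = 1), 6)
  expect_length(molecule_to_sentence("C", radius = 0), 1)
  # independent heavy-atom count from the template grammar (element letters)
  count_heavy <- function(s) {
    s2 <- gsub("Cl", "Q", s)  # two-letter halogen counts once
    sum(strsplit(s2, "")[[1]] %in% c("C", "c", "O", "N", "Q"))
  }
  for (smi in make_toy_smiles(10, seed = 2)$smiles) {
    sent <- molecule_to_sentence(smi, radius = 1)
    expect_length(sent, 2 * count_heavy(smi))
  }
  expect_error(molecule_to_sentence("C1CC"), "unparseable")
})

test_that("token identity is invariant to SMILES spelling", {
  expect_setequal(molecule_to_sentence("CCO"), molecule_to_sentence("OCC"))
  expect_equal(sort(molecule_to_sentence("CC(C)O")),
               sort(molecule_to_sentence("OC(C)C")))
  expect_equal(sort(molecule_to_sentence("CCN")),
               sort(molecule_to_sentence("NCC")))
  # different molecules give different token multisets
  expect_false(identical(sort(molecule_to_sentence("CCO")),
                         sort(molecule_to_sentence("CCN"))))
})

test_that("skip-gram training is deterministic and well-shaped", {
  sents <- lapply(make_toy_smiles(15, seed = 3)$smiles, molecule_to_sentence)
  m1 <- train_mol2vec(sents, dim = 24, window = 5, epochs = 3, seed = 7)
  m2 <- train_mol2vec(sents, dim = 24, window = 5, epochs = 3, seed = 7)
  expect_identical(m1$vectors, m2$vectors)
  expect_equal(ncol(m1$vectors), 24)
  expect_setequal(rownames(m1$vectors), unique(unlist(sents)))
  # one repeated sentence still trains
  single <- train_mol2vec(rep(sents[1], 3), dim = 8, epochs = 2, seed = 1)
  expect_setequal(rownames(single$vectors), unique(sents[[1]]))
  expect_error(train_mol2vec(list()), "empty")
})

test_that("molecule embedding is the mean of token vectors", {
  fake <- structure(list(vectors = rbind(a = c(1, 2, 3), b = c(3, 2, 1),
                                         u = c(2, 2, 2), v = c(-2, -2, -2)),
                         dim = 3), class = "mol2vec_model")
  expect_equal(embed_molecule(fake, c("u", "u")), c(2, 2, 2))       # all equal
  expect_equal(embed_molecule(fake, c("u", "v")), c(0, 0, 0))       # symmetry
  expect_equal(embed_molecule(fake, c("a", "b", "u")), c(2, 2, 2))  # hand mean
  expect_warning(z <- embed_molecule(fake, c("zz")), "out of vocabulary")
  expect_equal(z, c(0, 0, 0))
  # permutation invariance in token order
  expect_equal(embed_molecule(fake, c("a", "b", "v")),
               embed_molecule(fake, c("v", "a", "b")))
})

test_that("co-occurring tokens embed closer than never co-occurring ones", {
  set_a <- paste0("A", 1:4)
  set_b <- paste0("B", 1:4)
  wins <- 0
  for (seed in 1:20) {
    corpus <- withr::with_seed(seed, c(
      replicate(30, sample(set_a, 6, replace = TRUE), simplify = FALSE),
      replicate(30, sample(set_b, 6, replace = TRUE), simplify = FALSE)))
    m <- train_mol2vec(corpus, dim = 12, window = 3, epochs = 5, seed = seed)
    v <- m$vectors
    pairs_within <- rbind(t(combn(set_a, 2)), t(combn(set_b, 2)))
    within <- mean(apply(pairs_within, 1, function(p) cosine(v[p[1], ], v[p[2], ])))
    cross <- mean(outer(set_a, set_b, Vectorize(function(a, b)
      cosine(v[a, ], v[b, ]))))
    if (within > cross) wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("feature fusion concatenates per id with dimension additivity", {
  m <- tibble::tibble(id = c("d1", "d2"), V1 = c(1, 2), V2 = c(3, 4), V3 = c(5, 6))
  e <- tibble::tibble(id = c("d2", "d1"), V1 = c(9, 7), V2 = c(10, 8))
  fused <- fuse_drug_features(m, e)
  expect_equal(ncol(fused) - 1, 3 + 2)
  expect_equal(unname(embedding_matrix(fused)["d1", ]), c(1, 3, 5, 7, 8))
  expect_identical(fuse_drug_features(m, NULL), m)
  expect_error(fuse_drug_features(m, e[1, ]), "missing from external.*d1")
})

test_that("drug-table embedding emits one finite vector per drug", {
  drugs <- make_toy_smiles(10, seed = 6)
  emb <- embed_drugs(drugs, dim = 16, window = 5, epochs = 2, seed = 1)
  expect_equal(emb$id, drugs$drug_id)
  expect_equal(ncol(emb) - 1, 16)
  expect_true(all(is.finite(embedding_matrix(emb))))
})
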