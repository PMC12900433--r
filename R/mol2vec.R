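#' Convert a molecule to a substructure sentence
#'
#' Emits one Morgan-style atom-environment identifier per heavy atom and
#' radius 0..`radius`, in parser atom order. Radius-0 identifiers encode
#' the atom's element, heavy degree and total bond order; radius-r
#' identifiers fold in the sorted radius-(r-1) identifiers of bonded
#' neighbours, so identical molecules written as different SMILES yield
#' identical token multisets. With every environment resolvable the
#' sentence length is `heavy_atoms * (radius + 1)`.
#'
#' @param smiles SMILES string.
#' @param radius Maximum environment radius (default 1).
#' @return Character vector of substructure tokens.
#' @export
molecule_to_sentence <- function(smiles, radius = 1) {
  mol <- parse_smiles(smiles)
  if (is.null(mol)) abort(paste0("unparseable SMILES: '", smiles, "'"))
  n <- nrow(mol$atoms)
  nbr <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bond_sum <- vapply(nbr, function(x) if (is.null(x)) 0L else sum(x[, 2]), integer(1))
  ids <- matrix("", nrow = n, ncol = radius + 1)
  ids[, 1] <- paste(mol$atoms$element, degree, bond_sum, sep = "|")
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      for (a in seq_len(n)) {
        env <- if (is.null(nbr[[a]])) character(0) else
          sort(paste(nbr[[a]][, 2], ids[nbr[[a]][, 1], r], sep = "~"))
        ids[a, r + 1] <- paste(ids[a, r], paste(env, collapse = ","), sep = ";")
      }
    }
  }
  tokens <- character(0)
  for (a in seq_len(n))
    for (r in 0:radius)
      tokens <- c(tokens, paste0("m", r, "-", fnv_hash(ids[a, r + 1])))
  tokens
}

# Polynomial rolling string hash (mod 2^31-1); deterministic and
# platform-independent, used to compact environment descriptors into
# stable substructure identifiers.
fnv_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  format(h, scientific = FALSE)
}

#' Train a mol2vec-style substructure embedding model
#'
#' Trains skip-gram with negative sampling over substructure sentences.
#' Defaults mirror the reference configuration: 300-dimensional vectors
#' and a context window of 10.
#'
#' @param sentences List of character vectors (substructure sentences).
#' @param dim Vector dimension (default 300).
#' @param window Context window (default 10).
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param epochs,negative,lr Skip-gram training settings.
#' @param seed Integer seed; training is single-threaded and deterministic.
#' @return An object of class `mol2vec_model` holding the token-vector
#'   matrix and the training configuration.
#' @export
train_mol2vec <- function(sentences, dim = 300, window = 10, min_count = 1,
                          epochs = 5, negative = 5, lr = 0.025, seed = 42) {
  if (length(sentences) == 0) abort("empty training corpus")
  counts <- table(unlist(sentences))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) == 0) abort("no tokens survive min_count")
  vec <- train_sgns(sentences, vocab, as.numeric(counts[vocab]), dim = dim,
                    window = window, epochs = epochs, negative = negative,
                    lr = lr, seed = seed)
  structure(list(vectors = vec, dim = dim, window = window,
                 min_count = min_count, epochs = epochs, negative = negative,
                 seed = seed, n_sentences = length(sentences)),
            class = "mol2vec_model")
}

# Shared skip-gram front end (used by mol2vec and DeepWalk training).
train_sgns <- function(sentences, vocab, counts, dim, window, epochs,
                       negative, lr, seed) {
  idx <- stats::setNames(seq_along(vocab), vocab)
  coded <- lapply(sentences, function(s) unname(idx[s[s %in% vocab]]))
  coded <- coded[lengths(coded) > 0]
  if (length(coded) == 0) abort("no in-vocabulary tokens in corpus")
  mat <- .sgns_train_cpp(coded, length(vocab), as.integer(dim),
                         as.integer(window), as.integer(negative),
                         as.integer(epochs), lr, counts, as.double(seed))
  rownames(mat) <- vocab
  mat
}

#' Embed one molecule from its substructure sentence
#'
#' The molecule vector is the arithmetic mean (uniform weights) of the
#' vectors of its in-vocabulary tokens; out-of-vocabulary tokens are
#' skipped, and a molecule with no known tokens maps to the zero vector
#' with a warning.
#'
#' @param model A `mol2vec_model`.
#' @param sentence Character vector of tokens.
#' @return Numeric vector of length `model$dim`.
#' @export
embed_molecule <- function(model, sentence) {
  stopifnot(inherits(model, "mol2vec_model"), length(sentence) > 0)
  known <- sentence[sentence %in% rownames(model$vectors)]
  if (length(known) == 0) {
    warn("all tokens out of vocabulary; returning zero vector")
    return(numeric(model$dim))
  }
  colMeans(model$vectors[known, , drop = FALSE])
}

#' Embed a drug table with a trained mol2vec model
#'
#' @param drugs Drug tibble (`drug_id`, `smiles`).
#' @param model A `mol2vec_model` (trained with [train_mol2vec()]); if
#'   `NULL`, a model is trained on the drugs' own sentences.
#' @param radius Morgan environment radius used for sentences.
#' @param ... Passed to [train_mol2vec()] when `model` is `NULL`.
#' @return Embedding tibble (`id` + `V1..Vd`).
#' @export
embed_drugs <- function(drugs, model = NULL, radius = 1, ...) {
  sentences <- lapply(drugs$smiles, molecule_to_sentence, radius = radius)
  if (is.null(model)) model <- train_mol2vec(sentences, ...)
  mat <- t(vapply(sentences, function(s) embed_molecule(model, s),
                  numeric(model$dim)))
  as_embedding_table(mat, drugs$drug_id)
}

#' Fuse mol2vec drug vectors with an external embedding table
#'
#' Concatenates, per drug, the locally trained substructure vector with an
#' externally supplied global embedding (for instance a pre-trained
#' transformer fingerprint table). With no external table the mol2vec
#' table passes through unchanged.
#'
#' @param mol2vec Embedding tibble from [embed_drugs()].
#' @param external Optional embedding tibble covering the same ids.
#' @return Embedding tibble of dimension `d_mol2vec + d_external`.
#' @export
fuse_drug_features <- function(mol2vec, external = NULL) {
  if (is.null(external)) return(mol2vec)
  only_a <- setdiff(mol2vec$id, external$id)
  only_b <- setdiff(external$id, mol2vec$id)
  if (length(only_a) || length(only_b))
    abort(paste0("id mismatch between tables; missing from external: [",
                 paste(only_a, collapse = ", "), "], missing from mol2vec: [",
                 paste(only_b, collapse = ", "), "]"))
  ext <- external[match(mol2vec$id, external$id), ]
  as_embedding_table(cbind(embedding_matrix(mol2vec), embedding_matrix(ext)),
                     mol2vec$id)
}
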