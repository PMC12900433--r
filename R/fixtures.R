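#' Synthetic fixture specification
#'
#' Bundles the knobs of the synthetic benchmark: inventory size, the
#' positive-pair fraction (default 0.1145, matching the benchmark's
#' 18,416 / 160,862 share and its roughly 1:7.7 imbalance), the planted
#' informative feature dimensions, their class mean shift and the noise
#' level. The default inventory (27 drugs x 60 diseases) mirrors the
#' benchmark's drug:disease ratio at a tenth of its scale.
#'
#' @param n_drugs,n_diseases Inventory sizes.
#' @param n_features Per-pair feature dimension.
#' @param positive_fraction Probability a pair is labelled positive.
#' @param planted_dims Indices of informative features.
#' @param effect_size Class mean shift: planted features have mean
#'   `+effect_size` for positives and `-effect_size` for negatives.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 27, n_diseases = 60, n_features = 20,
                         positive_fraction = 0.1145, planted_dims = 1:4,
                         effect_size = 3, noise_sd = 1, seed = 42) {
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            all(planted_dims >= 1), all(planted_dims <= n_features))
  structure(list(n_drugs = n_drugs, n_diseases = n_diseases,
                 n_features = n_features,
                 positive_fraction = positive_fraction,
                 planted_dims = as.integer(planted_dims),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = seed), class = "fixture_spec")
}

#' Generate toy drug records with valid SMILES
#'
#' Draws molecules from a template grammar (alkane chains with alcohol,
#' amine, acid, ether and aromatic fragments) guaranteed to parse;
#' deterministic under `seed`.
#'
#' @param n Number of drugs (>= 1).
#' @param seed Integer seed.
#' @return Drug tibble (`drug_id`, `smiles`).
#' @export
make_toy_smiles <- function(n, seed = 42) {
  stopifnot(n >= 1)
  heads <- c("C", "CC", "CCC", "CC(C)", "CCCC", "CCC(C)")
  links <- c("C", "CO", "CC", "C(C)", "CN", "CCO")
  tails <- c("O", "N", "C", "C(=O)O", "OC", "Cc1ccccc1", "c1ccccc1",
             "C(=O)N", "CCl", "C#N")
  local_seed(seed, {
    smiles <- paste0(sample(heads, n, replace = TRUE),
                     sample(links, n, replace = TRUE),
                     sample(tails, n, replace = TRUE))
    tibble::tibble(drug_id = sprintf("DR%04d", seq_len(n)), smiles = smiles)
  })
}

#' Generate toy disease records over a random MeSH-like tree
#'
#' Builds a rooted code tree of the requested depth and branching (roots
#' "C01", "C02", ...) and assigns each disease one or two distinct
#' deepest-level codes; siblings share ancestor prefixes by construction,
#' and internal codes appear as ancestor concepts. Keeping disease codes
#' at the leaf level guarantees the merged concept graph stays acyclic
#' even for multi-code diseases.
#'
#' @param n_diseases Number of diseases.
#' @param depth Tree depth (>= 2, counting the root level).
#' @param branching Children per internal node.
#' @param n_roots Number of top-level categories.
#' @param seed Integer seed.
#' @return Disease tibble (`disease_id`, `tree_numbers` list-column).
#' @export
make_toy_mesh <- function(n_diseases, depth = 4, branching = 3, n_roots = 3,
                          seed = 42) {
  stopifnot(depth >= 2, n_diseases >= 1)
  level <- sprintf("C%02d", seq_len(n_roots))
  for (dp in seq_len(depth - 1)) {
    level <- as.vector(vapply(level, function(p)
      paste0(p, ".", sprintf("%03d", seq_len(branching))),
      character(branching)))
  }
  codes <- level  # deepest-level codes only
  local_seed(seed, {
    # sample without replacement so codes stay unique across diseases
    if (n_diseases > length(codes))
      abort("tree too small for n_diseases; increase depth/branching")
    take <- sample(codes, n_diseases)
    pool <- setdiff(codes, take)
    second <- runif(n_diseases) < 0.3 & seq_len(n_diseases) <= length(pool)
    extra <- character(n_diseases)
    extra[second] <- sample(pool, sum(second))
    tibble::tibble(
      disease_id = sprintf("DIS%04d", seq_len(n_diseases)),
      tree_numbers = lapply(seq_len(n_diseases), function(i)
        if (second[i]) c(take[[i]], extra[[i]]) else take[[i]]))
  })
}

#' Generate the planted-signal benchmark dataset
#'
#' Emits one feature row per drug x disease pair. Labels are Bernoulli at
#' `positive_fraction`; every feature is `Normal(0, noise_sd^2)` except
#' the planted dimensions, whose class means sit at `+effect_size`
#' (positives) and `-effect_size` (negatives). The mean-shift model makes
#' downstream ANOVA F values analytically predictable and gives
#' classifiers a known, controllable signal.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `features` (tibble: `drug_id`, `disease_id`,
#'   `label`, `f1..fd`) and `pairs` (the association tibble).
#' @export
make_planted_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_drugs * spec$n_diseases
  pairs <- tidyr::expand_grid(drug_id = sprintf("DR%04d", seq_len(spec$n_drugs)),
                              disease_id = sprintf("DIS%04d", seq_len(spec$n_diseases)))
  local_seed(spec$seed, {
    label <- rbinom(n, 1, spec$positive_fraction)
    x <- matrix(rnorm(n * spec$n_features, sd = spec$noise_sd),
                n, spec$n_features)
    shift <- ifelse(label == 1, spec$effect_size, -spec$effect_size)
    for (j in spec$planted_dims) x[, j] <- x[, j] + shift
    colnames(x) <- paste0("f", seq_len(spec$n_features))
    features <- dplyr::bind_cols(pairs, tibble::tibble(label = label),
                                 tibble::as_tibble(x))
    pairs$label <- label
    attr(pairs, "provenance") <- "enumerated"
    list(features = features, pairs = pairs)
  })
}

#' Write a complete fixture input set to disk
#'
#' Emits `drugs.csv`, `diseases.csv` and `positives.csv` for a toy
#' inventory, ready for the end-to-end pipeline or the command-line
#' interface.
#'
#' @param dir Output directory (created if needed).
#' @param n_drugs,n_diseases,positive_fraction,seed Fixture settings.
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_inputs <- function(dir, n_drugs = 27, n_diseases = 60,
                                 positive_fraction = 0.1145, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- make_toy_smiles(n_drugs, seed = seed)
  diseases <- make_toy_mesh(n_diseases, seed = derive_seed(seed, 2))
  pairs <- enumerate_pair_space(drugs, diseases)
  local_seed(derive_seed(seed, 3), {
    pos <- pairs[runif(nrow(pairs)) < positive_fraction, c("drug_id", "disease_id")]
  })
  pos$label <- 1L
  paths <- c(drugs = file.path(dir, "drugs.csv"),
             diseases = file.path(dir, "diseases.csv"),
             positives = file.path(dir, "positives.csv"))
  readr::write_csv(drugs, paths[["drugs"]])
  readr::write_csv(tibble::tibble(
    disease_id = diseases$disease_id,
    tree_numbers = vapply(diseases$tree_numbers, paste, character(1),
                          collapse = "|")), paths[["diseases"]])
  readr::write_csv(pos, paths[["positives"]])
  invisible(paths)
}
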