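#' Assemble per-pair feature rows from embedding tables
#'
#' Concatenates, for every (drug, disease) pair, the drug vector and the
#' disease vector. Drug columns are suffixed `_x`, disease columns `_y`.
#'
#' @param pairs Association tibble (`drug_id`, `disease_id`, optionally
#'   `label`).
#' @param drug_emb,disease_emb Embedding tibbles keyed by the pair ids.
#' @return Tibble with the pair keys, `label` (if present) and numeric
#'   feature columns.
#' @export
build_pair_features <- function(pairs, drug_emb, disease_emb) {
  missing_dr <- setdiff(pairs$drug_id, drug_emb$id)
  missing_di <- setdiff(pairs$disease_id, disease_emb$id)
  if (length(missing_dr) || length(missing_di))
    abort(paste0("pairs reference unembedded ids: ",
                 paste(c(missing_dr, missing_di), collapse = ", ")))
  dm <- embedding_matrix(drug_emb)
  em <- embedding_matrix(disease_emb)
  colnames(dm) <- paste0("f", seq_len(ncol(dm)), "_x")
  colnames(em) <- paste0("f", seq_len(ncol(em)), "_y")
  keep <- intersect(c("drug_id", "disease_id", "label"), names(pairs))
  dplyr::bind_cols(pairs[keep],
                   tibble::as_tibble(dm[pairs$drug_id, , drop = FALSE]),
                   tibble::as_tibble(em[pairs$disease_id, , drop = FALSE]))
}

#' Default pipeline configuration
#'
#' Returns the full configuration list with reference defaults (300-d
#' drug vectors with window 10 and radius 1; 64-d disease vectors; hamming
#' resampling metric; 140 selected features; 5 OOF folds), which callers
#' override by name.
#'
#' @param out_dir Run directory for artifacts.
#' @param ... Named overrides.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, ...) {
  cfg <- list(
    out_dir = out_dir,
    drugs = NULL, diseases = NULL, positives = NULL,  # input paths
    external_drug_embedding = NULL,
    fixture = list(n_drugs = 27, n_diseases = 60, positive_fraction = 0.1145),
    drug_dim = 300, drug_window = 10, radius = 1, embed_epochs = 5,
    disease_dim = 64, walks_per_node = 10, walk_length = 40,
    disease_window = 5,
    balance = TRUE, metric = "hamming", minkowski_p = 3,
    group_by_drug = FALSE,
    select = TRUE, k_selected = 140,
    learners = c("gbt", "cart", "rf", "oneshot"),
    oneshot_h = 1024, oneshot_k_pca = 128,
    oof_folds = 5, eval_folds = 5,
    explain_row = NULL,
    seed = 42)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config field(s): ",
                                paste(bad, collapse = ", ")))
  structure(utils::modifyList(cfg, over), class = c("pipeline_config", "list"))
}

#' Run the full prediction pipeline
#'
#' Orchestrates the stages in order: featurise drugs and diseases,
#' enumerate the pair space, then evaluate by outer stratified
#' cross-validation in which each training split is balanced by
#' similarity undersampling (evaluation folds keep their natural
#' imbalance), reduced to the top-F features, and fit with the stacking
#' ensemble. A final model trained on all (balanced, reduced) rows scores
#' every pair. All artifacts (embeddings, per-fold report, predictions,
#' manifest) are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()] (or a named list of overrides plus
#'   `out_dir`).
#' @return An object of class `pipeline_result`: the cross-validated
#'   `report`, the final `model`, the `selection`, prediction tibble, and
#'   the run manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  stage <- function(name, code) {
    ts <- Sys.time()
    out <- tryCatch(force(code), error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e))))
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), ts, units = "secs")), 3)
    out
  }

  inputs <- stage("inputs", {
    if (is.null(cfg$drugs)) {
      paths <- write_fixture_inputs(file.path(cfg$out_dir, "inputs"),
                                    n_drugs = cfg$fixture$n_drugs,
                                    n_diseases = cfg$fixture$n_diseases,
                                    positive_fraction = cfg$fixture$positive_fraction,
                                    seed = cfg$seed)
      cfg$drugs <- paths[["drugs"]]; cfg$diseases <- paths[["diseases"]]
      cfg$positives <- paths[["positives"]]
    }
    list(drugs = read_drug_table(cfg$drugs),
         diseases = read_disease_table(cfg$diseases),
         positives = if (!is.null(cfg$positives)) read_association_table(cfg$positives))
  })

  drug_emb <- stage("embed_drugs", {
    emb <- embed_drugs(inputs$drugs, radius = cfg$radius, dim = cfg$drug_dim,
                       window = cfg$drug_window, epochs = cfg$embed_epochs,
                       seed = derive_seed(cfg$seed, 11))
    if (!is.null(cfg$external_drug_embedding))
      emb <- fuse_drug_features(emb, read_embedding_table(cfg$external_drug_embedding))
    write_embedding_table(emb, file.path(cfg$out_dir, "drug_embeddings.tsv"))
    emb
  })
  disease_emb <- stage("embed_diseases", {
    emb <- embed_diseases(inputs$diseases, dim = cfg$disease_dim,
                          walks_per_node = cfg$walks_per_node,
                          walk_length = cfg$walk_length,
                          window = cfg$disease_window,
                          epochs = cfg$embed_epochs,
                          seed = derive_seed(cfg$seed, 12))
    write_embedding_table(emb, file.path(cfg$out_dir, "disease_embeddings.tsv"))
    emb
  })

  feats <- stage("featurize_pairs", {
    pairs <- enumerate_pair_space(inputs$drugs, inputs$diseases, inputs$positives)
    build_pair_features(pairs, drug_emb, disease_emb)
  })
  x <- feature_matrix(feats)
  y <- feats$label
  k_sel <- min(cfg$k_selected, ncol(x))
  specs <- lapply(cfg$learners, function(l)
    if (l == "oneshot") base_learner_spec("oneshot", h = cfg$oneshot_h,
                                          k_pca = cfg$oneshot_k_pca)
    else base_learner_spec(l))

  fit_fold <- function(xtr, ytr, gtr, slot) {
    if (cfg$balance) {
      res <- if (cfg$group_by_drug)
        grouped_undersample(xtr, ytr, gtr, metric = cfg$metric,
                            p = cfg$minkowski_p,
                            seed = derive_seed(cfg$seed, slot))
      else ksu_pairs_undersample(xtr, ytr, metric = cfg$metric,
                                 p = cfg$minkowski_p,
                                 seed = derive_seed(cfg$seed, slot))
      xtr <- xtr[res$retained, , drop = FALSE]; ytr <- ytr[res$retained]
    }
    sel <- if (cfg$select) select_top_k(xtr, ytr, k_selected = k_sel)
    if (cfg$select) xtr <- reduce_matrix(xtr, sel)
    model <- fit_stacking(xtr, ytr, learners = specs, n_folds = cfg$oof_folds,
                          seed = derive_seed(cfg$seed, slot + 1))
    list(model = model, selection = sel)
  }

  report <- stage("evaluate", {
    folds <- stratified_folds(y, cfg$eval_folds, seed = derive_seed(cfg$seed, 20))
    per_fold <- purrr::map_dfr(seq_len(cfg$eval_folds), function(f) {
      tr <- folds != f
      fitted <- fit_fold(x[tr, , drop = FALSE], y[tr], feats$drug_id[tr],
                         slot = 30 + f)
      xte <- x[!tr, , drop = FALSE]
      if (cfg$select) xte <- reduce_matrix(xte, fitted$selection)
      scores <- predict_stacking(fitted$model, xte)$score
      dplyr::bind_cols(tibble::tibble(fold = f),
                       evaluate_scores(scores, y[!tr]))
    })
    per_fold
  })

  final <- stage("final_model", fit_fold(x, y, feats$drug_id, slot = 50))
  predictions <- stage("predict_all", {
    xa <- if (cfg$select) reduce_matrix(x, final$selection) else x
    pred <- predict_stacking(final$model, xa)
    out <- dplyr::bind_cols(feats[c("drug_id", "disease_id", "label")],
                            pred[c("score", "label_pred")])
    readr::write_csv(out, file.path(cfg$out_dir, "predictions.csv"))
    out
  })

  explanation <- if (!is.null(cfg$explain_row)) stage("explain", {
    xa <- if (cfg$select) reduce_matrix(x, final$selection) else x
    explain_instance(function(m) predict_stacking(final$model, m)$score,
                     xa[cfg$explain_row, , drop = FALSE], xa,
                     n_perturbations = 1000,
                     seed = derive_seed(cfg$seed, 60))
  })

  manifest <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    timings_sec = as.list(timings),
    n_pairs = nrow(feats), n_positive = sum(y),
    started = format(t0), finished = format(Sys.time()),
    versions = list(ddapre = as.character(utils::packageVersion("ddapre")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)

  structure(list(report = report, model = final$model,
                 selection = final$selection, predictions = predictions,
                 explanation = explanation, manifest = manifest,
                 drug_emb = drug_emb, disease_emb = disease_emb,
                 features = feats, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$manifest$n_pairs, " pairs (",
      x$manifest$n_positive, " positive); mean CV AUC=",
      signif(mean(x$report$auc), 4), "\n", sep = "")
  invisible(x)
}

#' Rank candidate drugs for a disease
#'
#' Scores every drug against one disease with a fitted pipeline and
#' returns the strongest `top_k` candidates (score descending, ties
#' broken by drug id).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param disease_id Disease to rank against.
#' @param top_k Number of candidates (default 10).
#' @return Tibble (`rank`, `drug_id`, `score`).
#' @export
rank_candidates <- function(result, disease_id, top_k = 10) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!disease_id %in% result$disease_emb$id)
    abort(paste0("unknown disease: ", disease_id))
  pairs <- tibble::tibble(drug_id = result$drug_emb$id, disease_id = disease_id)
  feats <- build_pair_features(pairs, result$drug_emb, result$disease_emb)
  xa <- feature_matrix(feats)
  if (result$config$select) xa <- reduce_matrix(xa, result$selection)
  scores <- predict_stacking(result$model, xa)$score
  out <- tibble::tibble(drug_id = pairs$drug_id, score = scores)
  out <- out[order(-out$score, out$drug_id), ]
  out <- utils::head(out, top_k)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}
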