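#' Read a drug table (id + SMILES)
#'
#' Reads a delimited file with columns `drug_id` and `smiles` (delimiter
#' inferred from the extension: `.csv` comma, anything else tab) and
#' validates every SMILES with the molecular parser.
#'
#' @param path Path to a CSV/TSV file with header columns `drug_id`,
#'   `smiles`.
#' @param invalid_smiles Policy for rows whose SMILES does not parse:
#'   `"reject"` (default) aborts with a per-row report, `"drop"` removes
#'   them (reporting what was dropped), `"keep-raw"` keeps them unparsed.
#' @return A tibble with columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path, invalid_smiles = c("reject", "drop", "keep-raw")) {
  invalid_smiles <- match.arg(invalid_smiles)
  tbl <- read_delim_auto(path, c("drug_id", "smiles"))
  check_unique_ids(tbl$drug_id, "drug_id")
  if (nrow(tbl) == 0) return(tbl)
  ok <- vapply(tbl$smiles, smiles_is_valid, logical(1))
  if (!all(ok) && invalid_smiles != "keep-raw") {
    report <- paste0("row ", which(!ok), " (", tbl$drug_id[!ok], "): unparseable SMILES '",
                     tbl$smiles[!ok], "'", collapse = "\n")
    if (invalid_smiles == "reject")
      abort(paste0("invalid SMILES in ", path, ":\n", report))
    warn(paste0("dropping rows with invalid SMILES:\n", report))
    tbl <- tbl[ok, ]
  }
  tbl
}

#' Read a disease table (id + MeSH TreeNumbers)
#'
#' Expects columns `disease_id` and `tree_numbers`, the latter holding one
#' or more dotted TreeNumber codes separated by `|`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `disease_id` and `tree_numbers` (a
#'   list-column of character vectors).
#' @export
read_disease_table <- function(path) {
  tbl <- read_delim_auto(path, c("disease_id", "tree_numbers"))
  check_unique_ids(tbl$disease_id, "disease_id")
  codes <- strsplit(tbl$tree_numbers, "|", fixed = TRUE)
  bad <- vapply(codes, function(cc) length(cc) == 0 || !all(tree_number_valid(cc)),
                logical(1))
  if (any(bad))
    abort(paste0("malformed tree numbers for: ",
                 paste(tbl$disease_id[bad], collapse = ", ")))
  tibble::tibble(disease_id = tbl$disease_id, tree_numbers = codes)
}

tree_number_valid <- function(code) {
  nzchar(code) & grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", code)
}

#' Read an association pair list
#'
#' @param path Path to a CSV/TSV file with columns `drug_id`, `disease_id`,
#'   `label` (0/1).
#' @return A tibble with those columns and a `provenance` attribute set to
#'   `"observed"`.
#' @export
read_association_table <- function(path) {
  tbl <- read_delim_auto(path, c("drug_id", "disease_id", "label"))
  tbl$label <- check_binary_labels(tbl$label)
  dup <- duplicated(tbl[c("drug_id", "disease_id")])
  if (any(dup))
    abort(paste0("duplicate (drug_id, disease_id) pairs: ",
                 paste(tbl$drug_id[dup], tbl$disease_id[dup], sep = "/", collapse = ", ")))
  attr(tbl, "provenance") <- "observed"
  tbl
}

#' Enumerate the full drug x disease pair space
#'
#' Builds all `|drugs| * |diseases|` candidate pairs (drug-major, both in
#' input order), labelling pairs present in `positives` as 1 and all other
#' pairs as 0. On the benchmark inventory of 269 drugs and 598 diseases
#' this yields 160,862 pairs, of which 142,446 are unverified when 18,416
#' positives are supplied.
#'
#' @param drugs Drug table (tibble with `drug_id`).
#' @param diseases Disease table (tibble with `disease_id`).
#' @param positives Optional association tibble (`drug_id`, `disease_id`,
#'   any `label` column is ignored: listed pairs count as positive).
#' @return A tibble (`drug_id`, `disease_id`, `label`) with a `provenance`
#'   attribute `"enumerated"`.
#' @export
enumerate_pair_space <- function(drugs, diseases, positives = NULL) {
  pairs <- tidyr::expand_grid(drug_id = drugs$drug_id,
                              disease_id = diseases$disease_id)
  pairs$label <- 0L
  if (!is.null(positives) && nrow(positives) > 0) {
    bad_drug <- setdiff(positives$drug_id, drugs$drug_id)
    bad_dis <- setdiff(positives$disease_id, diseases$disease_id)
    if (length(bad_drug) || length(bad_dis))
      abort(paste0("positive pairs reference unknown ids: ",
                   paste(c(bad_drug, bad_dis), collapse = ", ")))
    if (anyDuplicated(paste(positives$drug_id, positives$disease_id, sep = "\r")))
      abort("duplicate pairs in positives")
    key <- paste(pairs$drug_id, pairs$disease_id, sep = "\r")
    pos_key <- paste(positives$drug_id, positives$disease_id, sep = "\r")
    pairs$label[key %in% pos_key] <- 1L
  }
  attr(pairs, "provenance") <- "enumerated"
  pairs
}

#' Write / read an embedding table
#'
#' Embedding tables are tibbles with an `id` column followed by `d` numeric
#' columns `V1..Vd`; on disk they are TSV with a header. All vectors must
#' be finite and of equal length.
#'
#' @param table Embedding tibble.
#' @param path Output TSV path.
#' @return `write_embedding_table()` returns `path` invisibly;
#'   `read_embedding_table()` returns the tibble.
#' @export
write_embedding_table <- function(table, path) {
  stopifnot(names(table)[1] == "id")
  mat <- feature_matrix(table)
  if (ncol(mat) == 0) abort("embedding table has no numeric columns")
  if (!all(is.finite(mat))) abort("refusing to write non-finite embedding values")
  check_unique_ids(table$id, "id")
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  tbl <- suppressWarnings(  # malformed rows surface via problems() below
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(id = readr::col_character(),
                                            .default = readr::col_double())))
  if (names(tbl)[1] != "id") abort("embedding TSV must start with an 'id' column")
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0)
    abort(paste0("ragged or non-numeric rows in ", path, " (row ",
                 paste(unique(probs$row), collapse = ", "), ")"))
  mat <- feature_matrix(tbl)
  if (anyNA(mat)) abort(paste0("ragged or missing values in ", path))
  check_unique_ids(tbl$id, "id")
  tbl
}

#' Turn an embedding tibble into an id-rownamed matrix
#' @param table Embedding tibble (`id` + numeric columns).
#' @return Numeric matrix with ids as rownames.
#' @export
embedding_matrix <- function(table) {
  mat <- feature_matrix(table)
  rownames(mat) <- table$id
  mat
}

as_embedding_table <- function(mat, ids = rownames(mat)) {
  colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(mat))
}

read_delim_auto <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE, col_types = readr::cols())
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  tibble::as_tibble(tbl)[required]
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) abort(paste0("empty ", what, " values"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort(paste0("duplicate ", what, ": ", paste(dup, collapse = ", ")))
  invisible(ids)
}
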