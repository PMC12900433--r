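#' Parse a SMILES string into a molecular graph
#'
#' Delegates parsing to Open Babel (via ChemmineOB) and returns the heavy-
#' atom graph: element symbols plus a bond list with orders. Hydrogens are
#' implicit.
#'
#' @param smiles A single SMILES string.
#' @return A list with `atoms` (tibble: `idx`, `element`) and `bonds`
#'   (tibble: `a1`, `a2`, `order`), or `NULL` if the SMILES is not
#'   parseable.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) < 1) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  elements <- sub("_\\d+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(mol)
  bb <- if (is.null(bb) || length(bb) == 0) NULL else as.matrix(bb)
  if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    # bond-free molecule (single heavy atom): Open Babel emits a stub block
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- tibble::tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
  }
  list(atoms = tibble::tibble(idx = seq_along(elements), element = elements),
       bonds = bonds)
}

#' @rdname parse_smiles
#' @return `smiles_is_valid()` returns a logical scalar.
#' @export
smiles_is_valid <- function(smiles) {
  !is.null(parse_smiles(smiles))
}
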