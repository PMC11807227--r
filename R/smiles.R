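# Optional SMILES adapter. Parsing goes through ChemmineR/ChemmineOB
# (OpenBabel); both are Suggests so edge-list and adjacency input keep
# working on installations without them.

.smilesAdapterAvailable <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}

#' Build a molecular graph from a SMILES string
#'
#' Returns the hydrogen-suppressed heavy-atom graph: hydrogens are dropped
#' and bond orders ignored, so an aromatic or double bond contributes one
#' edge. Multi-fragment SMILES (containing a `.`) is an error rather than
#' being reduced to a largest component.
#'
#' @param smiles a single-fragment SMILES string.
#' @return a [MolecularGraph-class] with labels like `C1`, `N5` (element +
#'   atom index).
#' @examples
#' if (revent:::.smilesAdapterAvailable()) {
#'   graphFromSmiles("C1CCC1")  # cyclobutane -> C4
#' }
#' @export
graphFromSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!.smilesAdapterAvailable()) {
    .reventStop("smiles_unavailable",
      paste("SMILES support needs the ChemmineR and ChemmineOB packages;",
            "supply an edge-list or adjacency file instead"))
  }
  if (grepl(".", smiles, fixed = TRUE)) {
    .reventStop("multi_fragment",
      "multi-fragment SMILES is not supported; analyze each fragment separately")
  }
  parsed <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
    mol <- sdf[[1L]]
    atoms <- rownames(ChemmineR::atomblock(mol))
    bonds <- ChemmineR::bondblock(mol)
    if (!is.matrix(bonds)) bonds <- matrix(bonds, nrow = 1L)
    list(atoms = atoms, bonds = bonds)
  }, error = function(e) NULL)
  if (is.null(parsed) || length(parsed$atoms) < 2L || nrow(parsed$bonds) == 0L) {
    .reventStop("smiles_parse", sprintf("could not parse SMILES: '%s'", smiles))
  }
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  # atom labels are "C_1", "O_4", ...; keep element + index, drop hydrogens
  elem <- sub("_.*$", "", atoms)
  labels <- paste0(elem, seq_along(atoms))
  heavy <- elem != "H"
  from <- as.integer(bonds[, 1L])
  to <- as.integer(bonds[, 2L])
  keep <- heavy[from] & heavy[to]
  if (!any(keep)) {
    .reventStop("empty_input", sprintf("SMILES '%s' has no heavy-atom bonds", smiles))
  }
  ed <- unique(cbind(labels[from[keep]], labels[to[keep]]))
  g <- tryCatch(molecularGraph(ed, vertices = labels[heavy]),
    revent_disconnected = function(e) {
      .reventStop("multi_fragment",
        "SMILES describes a disconnected structure; analyze fragments separately")
    })
  g
}
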