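#' MACCS structural-key fingerprints
#'
#' Computes the 166-key MACCS substructure fingerprint for each SMILES via
#' the OpenBabel backend (ChemmineOB). Key numbering follows the standard
#' convention in which key j of the 166-key set occupies column j; the
#' toolkit-internal 167-bit layout with an always-unset bit 0 is not used,
#' and this choice is recorded in the matrix metadata.
#'
#' Input SMILES are canonicalized by the toolkit before keying, so
#' kekulized and aromatic spellings of the same molecule yield identical
#' rows.
#'
#' @param smiles_list Character vector of SMILES; names, if present, become
#'   compound ids (defaults `cmpd1..n`).
#' @return A binary [descriptor_matrix()] with 166 columns `maccs_1..166`.
#' @export
#' @examples
#' \donttest{
#' fp <- compute_maccs(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' rowSums(fp$values)
#' }
compute_maccs <- function(smiles_list) {
  smiles_list <- validate_smiles(smiles_list)
  ids <- names(smiles_list)
  src <- paste0(paste(smiles_list, collapse = "\n"), "\n")
  fp <- ChemmineOB::forEachMol("SMILES", src,
                               function(m) ChemmineOB::fingerprint_OB(list(m), "MACCS"),
                               reduce = rbind)
  fp <- matrix(as.numeric(fp), nrow = length(smiles_list))[, 1:166, drop = FALSE]
  descriptor_matrix(fp, ids, "binary_fingerprint",
                    feature_names = paste0("maccs_", 1:166),
                    metadata = list(fingerprint = "MACCS",
                                    n_keys = 166L,
                                    bit_convention = "166 keys, column j = key j (no dummy bit 0)"))
}

# Parse each SMILES record individually so a bad record can be named by
# index; returns the (named) vector unchanged on success.
validate_smiles <- function(smiles_list) {
  if (!length(smiles_list)) stop("empty SMILES list")
  smiles_list <- stats::setNames(as.character(smiles_list), names(smiles_list))
  if (is.null(names(smiles_list)) || any(names(smiles_list) == "")) {
    nm <- names(smiles_list)
    if (is.null(nm)) nm <- rep("", length(smiles_list))
    nm[nm == ""] <- paste0("cmpd", which(nm == ""))
    names(smiles_list) <- nm
  }
  for (i in seq_along(smiles_list)) {
    ok <- tryCatch({
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", paste0(smiles_list[[i]], "\n"),
        function(m) ChemmineOB::prop_OB(list(m))$formula))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("unparseable SMILES at record ", i, " ('", smiles_list[[i]],
           "', id '", names(smiles_list)[i], "')")
    }
  }
  smiles_list
}

#' Morgan-style substructure identifiers of a molecule
#'
#' Extracts one identifier per atom environment at radius 0 (the element
#' itself) and radius 1 (the element plus its bond-order/neighbour-element
#' multiset, sorted for canonical form). These identifier strings are the
#' keys into an [embedding_table()]; a molecule contributes one identifier
#' per atom per radius, with multiplicity.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of substructure identifiers (radius-0 ids
#'   first, then radius-1).
#' @export
extract_substructures <- function(smiles) {
  smiles <- validate_smiles(stats::setNames(smiles, "m"))
  molblock <- ChemmineOB::convertFormat("SMILES", "SDF", paste0(smiles, "\n"))
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  atom_lines <- lines[4L + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  r0 <- elements
  if (n_bonds == 0L) return(r0)
  bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
  b1 <- as.integer(substr(bond_lines, 1L, 3L))
  b2 <- as.integer(substr(bond_lines, 4L, 6L))
  bo <- as.integer(substr(bond_lines, 7L, 9L))
  neigh <- vector("list", n_atoms)
  for (k in seq_len(n_bonds)) {
    neigh[[b1[k]]] <- c(neigh[[b1[k]]], paste0(bo[k], elements[b2[k]]))
    neigh[[b2[k]]] <- c(neigh[[b2[k]]], paste0(bo[k], elements[b1[k]]))
  }
  r1 <- vapply(seq_len(n_atoms), function(i) {
    paste0(elements[i], "(", paste(sort(neigh[[i]]), collapse = ","), ")")
  }, character(1L))
  c(r0, r1)
}

#' Substructure embedding table
#'
#' A lookup from substructure identifier to a fixed-dimension numeric
#' vector, in the style of unsupervised substructure embeddings where a
#' molecule's vector is the sum of its substructures' vectors. A row named
#' `"UNK"`, if present, is the designated out-of-vocabulary vector.
#'
#' @param vectors Numeric matrix with one row per substructure id
#'   (rownames are the ids), or a named list of equal-length vectors.
#' @return An object of class `EmbeddingTable`.
#' @export
embedding_table <- function(vectors) {
  if (is.list(vectors)) {
    dims <- lengths(vectors)
    if (length(unique(dims)) != 1L) stop("all embedding vectors must share one dimension")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || is.null(rownames(vectors))) {
    stop("embedding table needs a rownamed matrix or a named list")
  }
  if (ncol(vectors) < 1L || nrow(vectors) < 1L) stop("empty embedding table")
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, dim = ncol(vectors)), class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat("<EmbeddingTable> ", nrow(x$vectors), " substructures, dimension ",
      x$dim, "\n", sep = "")
  invisible(x)
}

#' Featurize molecules by substructure-vector summation
#'
#' Each compound's descriptor vector is the element-wise sum of the
#' embedding vectors of its extracted substructure identifiers (with
#' multiplicity). Identifiers absent from the table contribute the table's
#' `"UNK"` vector when one is present, else the zero vector.
#'
#' @param smiles_list Character vector of SMILES (names become compound ids).
#' @param table An [embedding_table()].
#' @return A continuous [descriptor_matrix()] with `table$dim` columns.
#' @export
embed_mol2vec <- function(smiles_list, table) {
  stopifnot(inherits(table, "EmbeddingTable"))
  smiles_list <- validate_smiles(smiles_list)
  vocab <- rownames(table$vectors)
  unk <- if ("UNK" %in% vocab) table$vectors["UNK", ] else rep(0, table$dim)
  vals <- t(vapply(smiles_list, function(s) {
    ids <- extract_substructures(s)
    v <- rep(0, table$dim)
    for (id in ids) {
      v <- v + if (id %in% vocab) table$vectors[id, ] else unk
    }
    v
  }, numeric(table$dim)))
  descriptor_matrix(vals, names(smiles_list), "continuous",
                    feature_names = paste0("emb_", seq_len(table$dim)),
                    metadata = list(embedding_dim = table$dim))
}
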