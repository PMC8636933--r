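#' Descriptor matrix container
#'
#' A `DescriptorMatrix` holds a compounds-by-features numeric matrix together
#' with its representation kind. Binary fingerprints (e.g. MACCS keys) and
#' continuous descriptor tables (e.g. substructure embeddings, physicochemical
#' descriptors) flow through the same container so that preprocessing,
#' similarity analysis and modelling can dispatch on `kind`.
#'
#' @param values Numeric matrix, one row per compound.
#' @param compound_ids Character vector of unique compound identifiers,
#'   one per row.
#' @param kind Either `"binary_fingerprint"` (all entries 0/1) or
#'   `"continuous"`.
#' @param feature_names Optional character vector of column names; defaults
#'   to the matrix's existing `colnames` or `f1..fp`.
#' @param metadata Optional named list of free-form annotations (e.g. the
#'   fingerprint bit-length convention).
#'
#' @return An object of class `DescriptorMatrix`: a list with elements
#'   `compound_ids`, `values`, `feature_names`, `kind`, `metadata`.
#' @export
#' @examples
#' m <- descriptor_matrix(matrix(rnorm(6), 2, 3), c("a", "b"), "continuous")
#' dim(m)
descriptor_matrix <- function(values, compound_ids, kind,
                              feature_names = NULL, metadata = list()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  kind <- match.arg(kind, c("binary_fingerprint", "continuous"))
  compound_ids <- as.character(compound_ids)
  if (nrow(values) != length(compound_ids)) {
    stop("row count (", nrow(values), ") does not equal number of compound ids (",
         length(compound_ids), ")")
  }
  if (anyDuplicated(compound_ids)) {
    dup <- unique(compound_ids[duplicated(compound_ids)])
    stop("duplicate compound ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (ncol(values) < 1L) stop("descriptor matrix must have at least one feature")
  if (anyNA(values)) stop("descriptor matrix contains missing values")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length does not match number of columns")
  }
  if (kind == "binary_fingerprint" && !all(values %in% c(0, 1))) {
    stop("binary_fingerprint matrix contains entries other than 0/1")
  }
  dimnames(values) <- list(compound_ids, feature_names)
  structure(
    list(compound_ids = compound_ids, values = values,
         feature_names = as.character(feature_names), kind = kind,
         metadata = metadata),
    class = "DescriptorMatrix"
  )
}

#' @export
dim.DescriptorMatrix <- function(x) dim(x$values)

#' @export
print.DescriptorMatrix <- function(x, ...) {
  cat("<DescriptorMatrix> ", nrow(x$values), " compounds x ",
      ncol(x$values), " features (", x$kind, ")\n", sep = "")
  if (length(x$metadata)) {
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Subset a descriptor matrix by compound id
#'
#' @param m A [descriptor_matrix()].
#' @param ids Character vector of compound ids to keep (order preserved).
#' @return A `DescriptorMatrix` restricted to `ids`.
#' @export
subset_compounds <- function(m, ids) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  miss <- setdiff(ids, m$compound_ids)
  if (length(miss)) {
    stop("unknown compound ids: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  descriptor_matrix(m$values[ids, , drop = FALSE], ids, m$kind,
                    m$feature_names, m$metadata)
}

#' Read a descriptor table from CSV
#'
#' Expects a header row of feature names and a first column of compound ids;
#' every remaining cell must be numeric. This is the ingestion route for
#' descriptor sets computed by external software (e.g. 777-descriptor
#' physicochemical tables or precomputed embedding outputs).
#'
#' @param path CSV file path.
#' @param kind Representation kind; `"auto"` declares the matrix a binary
#'   fingerprint when every cell is 0/1 and continuous otherwise.
#' @return A [descriptor_matrix()].
#' @export
load_descriptor_table <- function(path, kind = c("auto", "binary_fingerprint", "continuous")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("descriptor CSV needs an id column plus at least one feature")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate compound id in ", path, ": ",
         unique(ids[duplicated(ids)])[1L])
  }
  feat <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(feat, as.numeric, numeric(nrow(feat))))
  vals <- matrix(vals, nrow = nrow(feat),
                 dimnames = list(NULL, colnames(feat)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric or blank cell at row ", bad[["row"]],
         ", column '", colnames(feat)[bad[["col"]]], "' in ", path)
  }
  if (kind == "auto") {
    kind <- if (all(vals %in% c(0, 1))) "binary_fingerprint" else "continuous"
  }
  descriptor_matrix(vals, ids, kind)
}

#' Write a descriptor matrix to CSV
#'
#' @param m A [descriptor_matrix()].
#' @param path Output CSV path; first column `compound_id`, then features.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(m, path) {
  stopifnot(inherits(m, "DescriptorMatrix"))
  df <- data.frame(compound_id = m$compound_ids, m$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read labelled compounds from a SMILES table or SDF
#'
#' Accepts CSV/TSV with columns `compound_id`, `smiles` and optionally
#' `label`, or an SDF (V2000) file whose molecule titles become compound
#' ids. Labels, when present, must be 0/1.
#'
#' @param path Input file; format inferred from the extension
#'   (`.sdf` vs anything else).
#' @return A data frame with columns `compound_id`, `smiles` and, when
#'   available, `label`.
#' @export
read_compounds <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | ids == ""] <- paste0("mol", which(is.na(ids) | ids == ""))
    return(data.frame(compound_id = ids, smiles = smi, row.names = NULL))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles")
  if (!all(need %in% names(df))) {
    stop("compound table must contain columns: ", paste(need, collapse = ", "))
  }
  if ("label" %in% names(df) && !all(df$label %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  df
}
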