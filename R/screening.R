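# Library screening: admissibility filtering (organometallics, heavy
# molecules, overlap with the modelling compounds) and probability-binned
# carcinogenicity-concern reporting.

# Elements considered "organic" for admissibility; anything else flags the
# molecule as organometallic/inorganic.
DEFAULT_ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                              "Cl", "Se", "Br", "I")

formula_elements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1L]]
  if (m[1L] == -1L) return(character(0))
  unique(substring(formula, m, m + attr(m, "match.length") - 1L))
}

#' Standard InChIKeys for a set of SMILES
#'
#' @param smiles_list Character vector of SMILES.
#' @return Character vector of InChIKeys (NA for unparseable records).
#' @export
compute_inchikeys <- function(smiles_list) {
  vapply(as.character(smiles_list), function(s) {
    tryCatch({
      ik <- suppressWarnings(
        ChemmineOB::convertFormat("SMILES", "inchikey", paste0(s, "\n")))
      trimws(ik)
    }, error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

#' Filter a compound library for screening admissibility
#'
#' Excludes (1) unparseable structures, (2) molecules containing elements
#' outside the configured organic set (organometallics and inorganics),
#' (3) molecules above the molecular-weight cut-off, and (4) molecules
#' whose InChIKey matches a modelling compound (training/development/test
#' overlap). Every exclusion is logged with its reason; exclusion is never
#' fatal.
#'
#' @param compounds Data frame with columns `compound_id` and `smiles`
#'   (e.g. from [read_compounds()]).
#' @param training_inchikeys Character vector of InChIKeys of the
#'   modelling compounds (may be empty).
#' @param mw_cutoff Molecular-weight cut-off in Da (default 1000).
#' @param organic_elements Allowed element set.
#' @return A list with `admissible` (data frame, the retained rows plus an
#'   `inchikey` column) and `excluded` (data frame with `compound_id`,
#'   `reason`).
#' @export
filter_library <- function(compounds, training_inchikeys = character(0),
                           mw_cutoff = 1000,
                           organic_elements = DEFAULT_ORGANIC_ELEMENTS) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  keep <- logical(nrow(compounds))
  reason <- character(nrow(compounds))
  ik <- rep(NA_character_, nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    s <- compounds$smiles[i]
    props <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", paste0(s, "\n"),
        function(m) ChemmineOB::prop_OB(list(m)), reduce = rbind)),
      error = function(e) NULL)
    if (is.null(props)) { reason[i] <- "unparseable"; next }
    elems <- formula_elements(props$formula)
    if (length(setdiff(elems, organic_elements))) {
      reason[i] <- paste0("organometallic_or_inorganic (",
                          paste(setdiff(elems, organic_elements), collapse = ","), ")")
      next
    }
    if (props$MW > mw_cutoff) {
      reason[i] <- sprintf("heavy_molecule (MW %.1f > %s)", props$MW, mw_cutoff)
      next
    }
    ik[i] <- compute_inchikeys(s)
    if (!is.na(ik[i]) && ik[i] %in% training_inchikeys) {
      reason[i] <- "overlap_with_modelling_set"
      next
    }
    keep[i] <- TRUE
  }
  adm <- compounds[keep, , drop = FALSE]
  adm$inchikey <- ik[keep]
  list(admissible = adm,
       excluded = data.frame(compound_id = compounds$compound_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Probability-binned screening report
#'
#' Splits predicted probabilities into ten intervals of width 0.1
#' (\[0,0.1), ..., \[0.9,1\]) and tallies counts and fractions per
#' interval, plus the number of compounds at or above the risk cut-off
#' (default 0.5) and the high-concern cut-off (default 0.9).
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param risk_cutoff,high_concern_cutoff Inclusive cut-offs for the risk
#'   and high-concern tallies.
#' @return A list of class `ScreeningReport`: `bins` (data frame with
#'   `interval`, `count`, `fraction`), `n_screened`, `n_risk`,
#'   `n_high_concern`.
#' @export
bin_probabilities <- function(probs, risk_cutoff = 0.5, high_concern_cutoff = 0.9) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  edges <- seq(0, 1, by = 0.1)
  idx <- pmin(findInterval(probs, edges, rightmost.closed = TRUE), 10L)
  counts <- tabulate(idx, nbins = 10L)
  labels <- sprintf("[%.1f,%.1f%s", edges[1:10], edges[2:11],
                    c(rep(")", 9), "]"))
  structure(list(
    bins = data.frame(interval = labels, count = counts,
                      fraction = counts / length(probs)),
    n_screened = length(probs),
    n_risk = sum(probs >= risk_cutoff),
    n_high_concern = sum(probs >= high_concern_cutoff)),
    class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat("<ScreeningReport> ", x$n_screened, " screened; ", x$n_risk,
      " at risk (>=0.5 by default); ", x$n_high_concern, " high concern\n",
      sep = "")
  print(x$bins)
  invisible(x)
}
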