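# Synthetic labelled descriptor data with controllable class separation,
# shaped like the modelling problem (863 compounds, ~65% carcinogens):
# class-conditional Bernoulli bits emulate a substructure fingerprint and
# class-shifted Gaussian features emulate a continuous embedding. Every
# pipeline stage is testable offline against data generated here.

#' Specification for a synthetic labelled dataset
#'
#' @param n_compounds Number of compounds (default 863, the modelling-set
#'   scale).
#' @param positive_fraction Fraction of carcinogens (default 0.65; 863
#'   compounds then yield exactly 561 positives).
#' @param n_binary_features Width of the fingerprint-like binary matrix.
#' @param n_continuous_features Width of the embedding-like continuous
#'   matrix.
#' @param n_informative Number of class-associated features in each matrix.
#' @param effect_size For binary features, the gap added to the baseline
#'   bit probability in positives; for continuous features, the positive
#'   class's mean shift in standard-deviation units.
#' @param baseline_bit_prob Baseline Bernoulli probability of informative
#'   and uninformative bits (default 0.3).
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_compounds = 863L, positive_fraction = 0.65,
                           n_binary_features = 64L, n_continuous_features = 50L,
                           n_informative = 20L, effect_size = 0.5,
                           baseline_bit_prob = 0.3, seed = 1L) {
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must lie strictly inside (0, 1)")
  }
  if (n_informative > n_binary_features || n_informative > n_continuous_features) {
    stop("n_informative exceeds a feature count")
  }
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (baseline_bit_prob <= 0 || baseline_bit_prob >= 1) {
    stop("baseline_bit_prob must lie strictly inside (0, 1)")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 positive_fraction = positive_fraction,
                 n_binary_features = as.integer(n_binary_features),
                 n_continuous_features = as.integer(n_continuous_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 baseline_bit_prob = baseline_bit_prob,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic labelled dataset
#'
#' Labels are drawn to match `positive_fraction` exactly (rounded), then
#' shuffled. The first `n_informative` binary features are
#' Bernoulli(`baseline_bit_prob`) in negatives and
#' Bernoulli(`baseline_bit_prob + gap`) in positives with
#' `gap = min(effect_size, 1 - baseline_bit_prob)` (the clamp keeps large
#' continuous mean shifts usable in the same spec); the first
#' `n_informative` continuous features are N(0, 1) in negatives and
#' N(`effect_size`, 1) in positives. All remaining features are
#' class-independent noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `binary` (a binary [descriptor_matrix()]),
#'   `continuous` (a continuous one), `labels` (0/1 integer vector) and
#'   `compound_ids`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  n_pos <- as.integer(round(spec$positive_fraction * n))
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  ids <- sprintf("syn%04d", seq_len(n))

  p0 <- spec$baseline_bit_prob
  gap <- min(spec$effect_size, 1 - p0)
  pb <- spec$n_binary_features
  bprob <- matrix(p0, n, pb)
  if (spec$n_informative > 0) {
    bprob[labels == 1L, seq_len(spec$n_informative)] <- p0 + gap
  }
  bin <- matrix(stats::rbinom(n * pb, 1L, as.vector(bprob)), n, pb)

  pc <- spec$n_continuous_features
  cont <- matrix(stats::rnorm(n * pc), n, pc)
  if (spec$n_informative > 0) {
    shift <- matrix(0, n, pc)
    shift[labels == 1L, seq_len(spec$n_informative)] <- spec$effect_size
    cont <- cont + shift
  }

  list(
    binary = descriptor_matrix(bin, ids, "binary_fingerprint",
                               paste0("bit_", seq_len(pb)),
                               metadata = list(synthetic = TRUE, seed = spec$seed)),
    continuous = descriptor_matrix(cont, ids, "continuous",
                                   paste0("x_", seq_len(pc)),
                                   metadata = list(synthetic = TRUE, seed = spec$seed)),
    labels = labels,
    compound_ids = ids)
}

#' Built-in fixture SMILES
#'
#' A fixed list of 30 valid, structurally diverse organic molecules
#' (aromatics, aliphatics, heterocycles, a few drug-like structures) with
#' arbitrary 0/1 fixture labels, for exercising fingerprinting, similarity
#' and screening code paths without any download.
#'
#' @return A data frame with columns `compound_id`, `smiles`, `label`;
#'   identical on every call.
#' @export
make_fixture_smiles <- function() {
  data.frame(
    compound_id = sprintf("fx%02d", 1:30),
    smiles = c(
      "CCO",                               # ethanol
      "CC(=O)O",                           # acetic acid
      "c1ccccc1",                          # benzene
      "Cc1ccccc1",                         # toluene
      "c1ccc2ccccc2c1",                    # naphthalene
      "CC(=O)Oc1ccccc1C(=O)O",             # aspirin
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O",        # ibuprofen
      "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",      # caffeine
      "c1ccncc1",                          # pyridine
      "c1ccc2[nH]ccc2c1",                  # indole
      "C1CCCCC1",                          # cyclohexane
      "CCCCCCCC",                          # octane
      "C=CC=C",                            # butadiene
      "C#N",                               # hydrogen cyanide
      "ClCCl",                             # dichloromethane
      "ClC(Cl)(Cl)Cl",                     # carbon tetrachloride
      "Nc1ccccc1",                         # aniline
      "Oc1ccccc1",                         # phenol
      "O=C1CCCCC1",                        # cyclohexanone
      "NCCO",                              # ethanolamine
      "OCC(O)CO",                          # glycerol
      "C1CO1",                             # ethylene oxide
      "c1ccc(cc1)N(=O)=O",                 # nitrobenzene (classic SMILES)
      "CC(Cl)CCl",                         # 1,2-dichloropropane
      "c1ccsc1",                           # thiophene
      "c1ccoc1",                           # furan
      "OC(=O)c1ccccc1O",                   # salicylic acid
      "CCN(CC)CC",                         # triethylamine
      "CSC",                               # dimethyl sulfide
      "FC(F)(F)c1ccccc1"                   # benzotrifluoride
    ),
    label = c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L,
              0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L,
              0L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}
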