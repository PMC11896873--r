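# Independent re-implementations ("oracles") of the package's formulas,
# written as directly as possible from their definitions, plus small helpers
# shared across test files.

# Random bit-set fingerprint with the attributes morgan_fp() carries.
rand_bitset <- function(width = 2048L, n_max = 60L) {
  n <- sample.int(n_max, 1)
  structure(sort(sample.int(width, n) - 1L), width = as.integer(width),
            radius = 2L)
}

make_fp <- function(bits, width = 2048L) {
  structure(as.integer(sort(unique(bits))), width = as.integer(width),
            radius = 2L)
}

# Tanimoto by literal set arithmetic.
oracle_tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Eq. 5: SDC = sum_i exp(-3 TD_i / (1 - TD_i)), TD = 1 contributes 0.
oracle_sdc <- function(query, training) {
  s <- 0
  for (f in training) {
    td <- 1 - oracle_tanimoto(query, f)
    s <- s + if (td >= 1) 0 else exp(-3 * td / (1 - td))
  }
  s
}

# Eqs. 1-4 evaluated verbatim.
oracle_metrics <- function(TP, FN, TN, FP) {
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  acc <- (TP + TN) / (TP + TN + FP + FN)
  ba <- (sens + spec) / 2
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       balanced_accuracy = ba, mcc = mcc)
}

# ROC-AUC as the exhaustive concordant-pair probability with half credit
# for ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# A small labeled molecule set with an easily learnable structural signal
# (used by reduced-scale network tests).
tiny_labeled_set <- function(n = 80L, seed = 5L) {
  generate_motif_dataset(n_compounds = n, positive_fraction = 0.5,
                         label_noise = 0, seed = seed)
}

# Reorder the atoms of a parsed molecule by a permutation and rebuild the
# featurized graph, for permutation-invariance checks.
permute_graph <- function(mol, perm) {
  inv <- order(perm)          # inv[old] = new position
  atoms <- mol$atoms[perm, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  bonds <- mol$bonds
  bonds$a1 <- inv[bonds$a1]
  bonds$a2 <- inv[bonds$a2]
  pm <- structure(list(atoms = atoms, bonds = bonds, n_atoms = mol$n_atoms),
                  class = "txscreen_mol")
  txscreen:::featurize_mol(pm)
}
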