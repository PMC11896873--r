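# Seeded synthetic SMILES generators with known structure-label
# relationships. Molecules are assembled from a curated pool of small
# building blocks (alkyl backbones, saturated and aromatic rings,
# heteroatom decorations); positives carry a grafted motif (carboxylic acid
# by default) and negatives are verified motif-free by substructure match,
# so the structural label is exactly recoverable and every downstream stage
# is testable without external data.

SUBSTITUENT_POOL <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C#N", "CO", "CN", "C(F)(F)F", "SC", "CCO", "CCN"
)
RING_POOL <- c(
  "c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccc(F)cc1", "c1ccc(C)cc1",
  "c1ccc(OC)cc1", "C1CCCCC1", "C1CCCC1", "C1CCOCC1", "C1CCNCC1"
)
MOTIF_SMILES <- "C(=O)O"
MOTIF_SMARTS <- "[CX3](=O)[OX2H1]"

# Random backbone + substituents molecule; respects carbon valence by
# capping substituents per backbone position.
assemble_molecule <- function(with_motif, with_ring) {
  len <- sample(3:7, 1)
  capacity <- c(3L, rep(2L, max(len - 2L, 0L)), if (len > 1L) 3L)
  subs <- vector("list", len)
  place <- function(frag) {
    open <- which(vapply(subs, length, integer(1)) < capacity)
    pos <- if (length(open) == 1L) open else sample(open, 1)
    subs[[pos]] <<- c(subs[[pos]], frag)
  }
  if (with_ring) place(sample(RING_POOL, 1))
  for (i in seq_len(sample(1:3, 1))) place(sample(SUBSTITUENT_POOL, 1))
  if (with_motif) place(MOTIF_SMILES)
  paste0(vapply(seq_len(len), function(i) {
    paste0("C", paste0("(", subs[[i]], ")", collapse = ""))
  }, character(1)), collapse = "")
}

contains_motif <- function(smiles, smarts = MOTIF_SMARTS) {
  vapply(smiles, function(s) {
    mol <- tryCatch(ChemmineOB::forEachMol("SMILES", s, identity),
                    error = function(e) NULL)
    if (is.null(mol)) return(NA)
    ChemmineOB::smartsSearch_OB(mol, smarts) > 0
  }, logical(1), USE.NAMES = FALSE)
}

# Draw unique standardized molecules of one structural class.
draw_class <- function(n_wanted, with_motif, ring_prob, exclude = character(),
                       max_tries = 60L * n_wanted) {
  got <- character(0)
  tries <- 0L
  while (length(got) < n_wanted && tries < max_tries) {
    batch <- min(n_wanted - length(got) + 10L, max_tries - tries)
    tries <- tries + batch
    raw <- vapply(seq_len(batch), function(i) {
      assemble_molecule(with_motif, runif(1) < ring_prob)
    }, character(1))
    std <- standardize_smiles(raw)
    cand <- unique(std$canonical_smiles[std$valid])
    cand <- setdiff(cand, c(got, exclude))
    if (length(cand)) {
      has <- contains_motif(cand)
      cand <- cand[!is.na(has) & has == with_motif]
      got <- c(got, cand)
    }
  }
  if (length(got) < n_wanted) {
    abort(sprintf("generation shortfall: produced %d of %d unique molecules",
                  length(got), n_wanted))
  }
  got[seq_len(n_wanted)]
}

#' Generate a synthetic motif-classification dataset
#'
#' Assembles `n_compounds` standardized, deduplicated molecules; a
#' `positive_fraction` share carries the carboxylic-acid motif grafted at a
#' random backbone position, the rest are verified motif-free by
#' substructure match. The observed `label` equals motif presence flipped
#' independently with probability `label_noise`, so the Bayes-optimal
#' accuracy is known by construction. Deterministic per seed.
#'
#' @param n_compounds Total number of molecules.
#' @param positive_fraction Fraction of structural positives.
#' @param label_noise Independent label-flip probability in `[0, 0.5]`.
#' @param seed Seed.
#' @param ring_prob Probability that a molecule carries a ring substituent
#'   (rings define the scaffold classes used by scaffold splitting).
#' @return Standardized dataset tibble with `record_id`, `input_smiles`,
#'   `canonical_smiles`, `motif_present` (the structural truth), `label`
#'   (after noise) and `provenance`.
#' @export
generate_motif_dataset <- function(n_compounds = 600L, positive_fraction = 0.5,
                                   label_noise = 0, seed = 1L,
                                   ring_prob = 0.8) {
  stopifnot(n_compounds >= 2, positive_fraction > 0, positive_fraction < 1,
            label_noise >= 0, label_noise <= 0.5)
  set.seed(seed)
  n_pos <- round(n_compounds * positive_fraction)
  n_neg <- n_compounds - n_pos
  pos <- draw_class(n_pos, with_motif = TRUE, ring_prob = ring_prob)
  neg <- draw_class(n_neg, with_motif = FALSE, ring_prob = ring_prob,
                    exclude = pos)
  smiles <- c(pos, neg)
  motif <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  ord <- sample.int(n_compounds)
  smiles <- smiles[ord]; motif <- motif[ord]
  flip <- runif(n_compounds) < label_noise
  out <- tibble(
    record_id = sprintf("syn%04d", seq_len(n_compounds)),
    input_smiles = smiles,
    canonical_smiles = smiles,
    motif_present = motif,
    label = as.integer(xor(motif, flip)),
    provenance = sprintf("synthetic_motif(seed=%d)", seed)
  )
  attr(out, "mode") <- "inhibitor"
  attr(out, "name") <- sprintf("synthetic_motif_s%d", seed)
  out
}

ACTIVE_CORE_SUBS <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl",
                      "CO", "CN", "C(C)C", "C(F)(F)F", "CCO", "N(C)C", "C#N")

assemble_active <- function() {
  s1 <- sample(ACTIVE_CORE_SUBS, 1)
  if (runif(1) < 0.5) {
    paste0(s1, "c1ccc2ccccc2c1")
  } else {
    s2 <- sample(ACTIVE_CORE_SUBS, 1)
    paste0(s1, "c1ccc2cc(", s2, ")ccc2c1")
  }
}

#' Generate a similarity-screening benchmark
#'
#' Emulates the retrieval evaluation design for data-poor targets: the
#' reference set and the external actives are decorated variants of one
#' fused-ring scaffold family (naphthalene core, potencies at or below 1
#' uM), while the inactives come from disjoint acyclic/monocyclic families
#' (potencies at or above 10 uM). Reference and external sets share no
#' canonical SMILES.
#'
#' @param seed Seed.
#' @param n_reference,n_active,n_inactive Set sizes.
#' @return List of two standardized dataset tibbles: `reference` and
#'   `external` (the latter with a `potency` column in molar units and the
#'   generating `label`).
#' @export
generate_similarity_benchmark <- function(seed = 1L, n_reference = 20L,
                                          n_active = 50L, n_inactive = 150L) {
  stopifnot(n_reference >= 1, n_active >= 1, n_inactive >= 1)
  set.seed(seed)
  n_fam <- n_reference + n_active
  fam <- character(0)
  tries <- 0L
  while (length(fam) < n_fam && tries < 100L * n_fam) {
    tries <- tries + 50L
    raw <- vapply(seq_len(50L), function(i) assemble_active(), character(1))
    std <- standardize_smiles(raw)
    fam <- unique(c(fam, std$canonical_smiles[std$valid]))
  }
  if (length(fam) < n_fam) {
    abort(sprintf("generation shortfall: %d of %d scaffold-family molecules",
                  length(fam), n_fam))
  }
  fam <- fam[seq_len(n_fam)]
  ref_sm <- fam[seq_len(n_reference)]
  act_sm <- fam[n_reference + seq_len(n_active)]
  inact_sm <- draw_class(n_inactive, with_motif = FALSE, ring_prob = 0.7,
                         exclude = fam)
  reference <- tibble(
    record_id = sprintf("ref%03d", seq_len(n_reference)),
    input_smiles = ref_sm, canonical_smiles = ref_sm,
    provenance = sprintf("synthetic_reference(seed=%d)", seed)
  )
  external <- tibble(
    record_id = sprintf("ext%03d", seq_len(n_active + n_inactive)),
    input_smiles = c(act_sm, inact_sm),
    canonical_smiles = c(act_sm, inact_sm),
    label = rep(c(1L, 0L), c(n_active, n_inactive)),
    potency = c(10^runif(n_active, -8, -6), 10^runif(n_inactive, -5, -3)),
    provenance = sprintf("synthetic_external(seed=%d)", seed)
  )
  list(reference = reference, external = external)
}
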