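# Circular (Morgan-style, radius 2) bit fingerprints and Tanimoto
# similarity. The fingerprint is computed by iterative neighborhood hashing:
# every atom starts from an invariant built from its element, degree, formal
# charge, hydrogen count, aromaticity and ring membership; each round folds
# in the sorted (bond class, neighbor identifier) multiset, so the result is
# independent of atom input order. Identifiers from every radius level are
# hashed into a fixed-width bit set.

FP_MOD <- 2^31

fp_hash <- function(xs) {
  h <- 5381
  for (x in xs) h <- (h * 33 + x) %% FP_MOD
  h
}

ELEMENT_ORDER <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                   "B", "Si", "H")

#' Circular fingerprint of a single molecule
#'
#' @param smiles A single valid SMILES string (standardize first for
#'   molecule-identity invariance across SMILES spellings).
#' @param radius Neighborhood radius in bonds (default 2).
#' @param width Bit-set width (default 2048).
#' @return Sorted integer vector of set bit indices in `[0, width)`, with
#'   attributes `width` and `radius`.
#' @examples
#' fp <- morgan_fp("CCO")
#' length(fp)
#' @export
morgan_fp <- function(smiles, radius = 2L, width = 2048L) {
  stopifnot(length(smiles) == 1L, !is.na(smiles), radius >= 0L, width >= 1L)
  mol <- parse_molecules(smiles)[[1]]
  morgan_fp_mol(mol, radius, width)
}

morgan_fp_mol <- function(mol, radius = 2L, width = 2048L) {
  at <- mol$atoms
  bd <- mol$bonds
  n <- mol$n_atoms
  elem <- match(at$symbol, ELEMENT_ORDER, nomatch = length(ELEMENT_ORDER) + 1L)
  inv <- vapply(seq_len(n), function(v) {
    fp_hash(c(elem[v], at$degree[v], at$charge[v] + 8L, at$n_h[v],
              as.integer(at$aromatic[v]), as.integer(at$in_ring[v])))
  }, numeric(1))
  # bond class: 1/2/3 order, 4 aromatic
  bclass <- ifelse(bd$aromatic, 4L, bd$order)
  nbrs <- vector("list", n)
  if (nrow(bd)) {
    for (b in seq_len(nrow(bd))) {
      nbrs[[bd$a1[b]]] <- rbind(nbrs[[bd$a1[b]]], c(bclass[b], bd$a2[b]))
      nbrs[[bd$a2[b]]] <- rbind(nbrs[[bd$a2[b]]], c(bclass[b], bd$a1[b]))
    }
  }
  ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- vapply(seq_len(n), function(v) {
      nb <- nbrs[[v]]
      if (is.null(nb)) return(fp_hash(c(r, inv[v])))
      pairs <- cbind(nb[, 1], inv[nb[, 2]])
      ord <- order(pairs[, 1], pairs[, 2])
      fp_hash(c(r, inv[v], as.vector(t(pairs[ord, , drop = FALSE]))))
    }, numeric(1))
    inv <- new_inv
    ids <- c(ids, inv)
  }
  bits <- sort(unique(as.integer(ids %% width)))
  structure(bits, width = as.integer(width), radius = as.integer(radius))
}

#' Add circular fingerprints to a dataset
#'
#' Computes the radius-`radius` circular fingerprint of every record's
#' `canonical_smiles` and stores it in a `fingerprint` list column.
#'
#' @param data Standardized dataset tibble with a `canonical_smiles` column.
#' @inheritParams morgan_fp
#' @return `data` with an added `fingerprint` list column.
#' @export
add_fingerprints <- function(data, radius = 2L, width = 2048L) {
  stopifnot(is.data.frame(data))
  if (!"canonical_smiles" %in% names(data) || anyNA(data$canonical_smiles)) {
    abort("unstandardized input: run standardize_smiles() first")
  }
  mols <- parse_molecules(data$canonical_smiles)
  data$fingerprint <- lapply(mols, morgan_fp_mol, radius = radius, width = width)
  data
}

#' Tanimoto similarity between two bit fingerprints
#'
#' `|A intersect B| / |A union B|` on set-bit indices. Two empty
#' fingerprints count as identical (similarity 1); an empty against a
#' non-empty one is 0 by the formula.
#'
#' @param a,b Fingerprints as returned by [morgan_fp()] (integer vectors of
#'   set bits with a `width` attribute).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  wa <- attr(a, "width"); wb <- attr(b, "width")
  if (!is.null(wa) && !is.null(wb) && wa != wb) {
    abort("fingerprint width mismatch")
  }
  if (length(a) == 0L && length(b) == 0L) return(1)
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Maximum Tanimoto similarity against a reference set
#'
#' Scores each query by its highest Tanimoto similarity to any member of a
#' reference compound set (the MAX score used for similarity-based
#' screening). Ties are broken by first reference-set order.
#'
#' @param queries,reference Dataset tibbles carrying `record_id` and a
#'   `fingerprint` list column (see [add_fingerprints()]).
#' @return Tibble with `record_id`, `max_score` and `argmax_reference_id`.
#' @export
max_similarity <- function(queries, reference) {
  stopifnot(is.data.frame(queries), is.data.frame(reference))
  if (nrow(reference) == 0L) abort("empty reference set")
  if (!"fingerprint" %in% names(queries) || !"fingerprint" %in% names(reference)) {
    abort("missing 'fingerprint' column: run add_fingerprints() first")
  }
  ref_fps <- reference$fingerprint
  res <- lapply(queries$fingerprint, function(q) {
    sims <- vapply(ref_fps, function(r) tanimoto(q, r), numeric(1))
    j <- which.max(sims)
    list(score = sims[[j]], j = j)
  })
  tibble(
    record_id = queries$record_id,
    max_score = vapply(res, `[[`, numeric(1), "score"),
    argmax_reference_id = reference$record_id[vapply(res, `[[`, integer(1), "j")]
  )
}
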