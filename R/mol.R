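# Molecular graph construction from SMILES via OpenBabel/ChemmineR, plus the
# perception steps (implicit hydrogens, ring membership, aromaticity,
# hybridization, conjugation) that downstream featurization and fingerprints
# consume. The SDF that OpenBabel emits is kekulized, so aromaticity is
# re-perceived here with a Hueckel-style electron count over detected rings.

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Br = 1, I = 1)
ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                 Cl = 35.45, Br = 79.904, I = 126.904)
# V2000 old-style charge codes
CHARGE_CODE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

#' Parse SMILES into annotated molecular graphs
#'
#' Converts each SMILES to a molecular graph with per-atom and per-bond
#' annotations: element, formal charge, degree, implicit hydrogen count,
#' ring membership, aromaticity, hybridization class, bond order,
#' conjugation and stereo flag. Parsed graphs are cached per SMILES string,
#' so repeated calls are cheap.
#'
#' @param smiles Character vector of valid SMILES (typically
#'   `canonical_smiles` from [standardize_smiles()]).
#' @return A list of `mol` objects (one per input), each a list with
#'   tibbles `atoms` and `bonds` and the scalar `n_atoms`.
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  miss <- which(!vapply(smiles, function(s) !is.null(the$mol_cache[[s]]), logical(1)))
  if (length(miss)) {
    uniq <- unique(smiles[miss])
    sdfs <- suppressWarnings(
      ChemmineR::smiles2sdf(setNames(uniq, paste0("m", seq_along(uniq))))
    )
    for (i in seq_along(uniq)) {
      the$mol_cache[[uniq[[i]]]] <- mol_from_sdf(sdfs[[i]])
    }
  }
  for (i in seq_along(smiles)) out[[i]] <- the$mol_cache[[smiles[[i]]]]
  out
}

# Build an annotated graph from one ChemmineR SDF object.
mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n == 0L) abort("empty molecule")
  symbol <- sub("_.*$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(CHARGE_CODE[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  # bond-free molecules get a degenerate placeholder block from the SDF writer
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer(),
                    in_ring = logical(), aromatic = logical(),
                    conjugated = logical(), stereo = integer())
  } else {
    bonds <- tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]),
                    in_ring = FALSE, aromatic = FALSE, conjugated = FALSE,
                    stereo = as.integer(if (ncol(bb) >= 4) bb[, 4] else rep(0, nrow(bb))))
    bonds <- bonds[bonds$a1 > 0L & bonds$a2 > 0L, , drop = FALSE]
  }
  nb <- nrow(bonds)
  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bondsum <- numeric(n)
  for (b in seq_len(nb)) {
    o <- bonds$order[b]
    bondsum[bonds$a1[b]] <- bondsum[bonds$a1[b]] + o
    bondsum[bonds$a2[b]] <- bondsum[bonds$a2[b]] + o
  }
  n_h <- implicit_h(symbol, charge, bondsum)

  # ring perception
  ring_info <- perceive_rings(n, bonds)
  bonds$in_ring <- ring_info$bond_in_ring
  atom_in_ring <- ring_info$atom_in_ring

  arom <- perceive_aromaticity(symbol, bonds, ring_info$rings)
  bonds$aromatic <- arom$bond_aromatic
  atom_aromatic <- arom$atom_aromatic

  # hybridization from bond orders (aromatic counts as sp2)
  n_double <- n_triple <- integer(n)
  for (b in seq_len(nb)) {
    if (bonds$order[b] == 2L) {
      n_double[bonds$a1[b]] <- n_double[bonds$a1[b]] + 1L
      n_double[bonds$a2[b]] <- n_double[bonds$a2[b]] + 1L
    } else if (bonds$order[b] == 3L) {
      n_triple[bonds$a1[b]] <- n_triple[bonds$a1[b]] + 1L
      n_triple[bonds$a2[b]] <- n_triple[bonds$a2[b]] + 1L
    }
  }
  hyb <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
                ifelse(n_double > 0L | atom_aromatic, "sp2", "sp3"))

  # conjugation: a bond is conjugated when it is aromatic or when each end
  # atom is unsaturated through some other bond or is a lone-pair heteroatom
  if (nb > 0L) {
    multi <- n_double + n_triple
    for (b in seq_len(nb)) {
      if (bonds$aromatic[b]) { bonds$conjugated[b] <- TRUE; next }
      own <- as.integer(bonds$order[b] >= 2L)
      e1 <- bonds$a1[b]; e2 <- bonds$a2[b]
      ok1 <- (multi[e1] - own) > 0L || atom_aromatic[e1] || symbol[e1] %in% c("N", "O", "S")
      ok2 <- (multi[e2] - own) > 0L || atom_aromatic[e2] || symbol[e2] %in% c("N", "O", "S")
      # at least one end must actually be unsaturated for a pi system
      unsat <- (multi[e1] - own) > 0L || (multi[e2] - own) > 0L ||
        atom_aromatic[e1] || atom_aromatic[e2]
      bonds$conjugated[b] <- ok1 && ok2 && unsat
    }
  }

  atoms <- tibble(
    idx = seq_len(n), symbol = symbol, charge = as.integer(charge),
    degree = as.integer(degree), n_h = as.integer(n_h),
    in_ring = atom_in_ring, aromatic = atom_aromatic,
    hybridization = hyb,
    mass = unname(ifelse(symbol %in% names(ATOMIC_MASS),
                         ATOMIC_MASS[symbol], 0))
  )
  structure(list(atoms = atoms, bonds = bonds, n_atoms = n), class = "txscreen_mol")
}

implicit_h <- function(symbol, charge, bondsum) {
  val <- unname(DEFAULT_VALENCE[symbol])
  val[is.na(val)] <- 0
  # N+/P+ gain a bond, O-/S-/N- lose one; carbanions/cations both lose
  adj <- ifelse(symbol %in% c("N", "P", "O", "S"), charge, -abs(charge))
  pmax(0L, as.integer(round(val + adj - bondsum)))
}

# Ring membership via bridge detection; explicit rings (for aromaticity) as
# the shortest cycle through each non-bridge bond.
perceive_rings <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) {
    return(list(bond_in_ring = logical(0), atom_in_ring = rep(FALSE, n),
                rings = list()))
  }
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- as.integer(igraph::bridges(g))
  bond_in_ring <- !(seq_len(nb) %in% br)
  atom_in_ring <- rep(FALSE, n)
  atom_in_ring[unique(c(bonds$a1[bond_in_ring], bonds$a2[bond_in_ring]))] <- TRUE
  rings <- list()
  seen <- character()
  for (b in which(bond_in_ring)) {
    g2 <- igraph::delete_edges(g, b)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$a1[b], to = bonds$a2[b])$vpath[[1]]
    )
    if (length(sp) == 0L) next
    ring <- sort(as.integer(sp))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(sp)
    }
  }
  list(bond_in_ring = bond_in_ring, atom_in_ring = atom_in_ring, rings = rings)
}

# Hueckel-style count on each perceived ring of size 5-7 over a kekulized
# graph. Per ring atom: an endocyclic double bond or an exocyclic double
# bond to carbon contributes 1 pi electron; an exocyclic double bond to O/S
# contributes 0 (carbonyl-type, stays sp2); an N/O/S atom with only single
# bonds donates a lone pair (2); a saturated carbon disqualifies the ring.
# Aromatic when the total is 4n+2. Exotic fused systems may be missed; see
# the methods vignette for limitations.
perceive_aromaticity <- function(symbol, bonds, rings) {
  n <- length(symbol)
  nb <- nrow(bonds)
  atom_aromatic <- rep(FALSE, n)
  bond_aromatic <- rep(FALSE, nb)
  if (!length(rings)) {
    return(list(atom_aromatic = atom_aromatic, bond_aromatic = bond_aromatic))
  }
  dbl_partners <- vector("list", n)
  for (b in seq_len(nb)) {
    if (bonds$order[b] == 2L) {
      dbl_partners[[bonds$a1[b]]] <- c(dbl_partners[[bonds$a1[b]]], bonds$a2[b])
      dbl_partners[[bonds$a2[b]]] <- c(dbl_partners[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  for (ring in rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    if (!all(symbol[ring] %in% c("C", "N", "O", "S"))) next
    pi <- 0L; ok <- TRUE
    for (v in ring) {
      dp <- dbl_partners[[v]]
      if (length(dp)) {
        exo <- setdiff(dp, ring)
        if (any(dp %in% ring)) pi <- pi + 1L
        else if (length(exo) && all(symbol[exo] %in% c("O", "S"))) pi <- pi + 0L
        else pi <- pi + 1L
      } else if (symbol[v] %in% c("N", "O", "S")) {
        pi <- pi + 2L
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi %in% c(2L, 6L, 10L)) {
      atom_aromatic[ring] <- TRUE
      in_ring_b <- bonds$a1 %in% ring & bonds$a2 %in% ring
      bond_aromatic[in_ring_b] <- TRUE
    }
  }
  list(atom_aromatic = atom_aromatic, bond_aromatic = bond_aromatic)
}
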