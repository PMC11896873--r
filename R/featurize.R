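# Graph featurization for the directed message-passing network. The exact
# one-hot layout is a documented constant: changing it invalidates trained
# parameter sets, so the dimensions are recorded with every model.
#
# Atom feature vector (length 32):
#   [1:10]  element one-hot over C, N, O, S, P, F, Cl, Br, I, other
#   [11:16] heavy-atom degree one-hot 0..5
#   [17:21] formal charge one-hot -2..+2
#   [22:26] attached-hydrogen count one-hot 0..4
#   [27]    aromatic flag
#   [28:31] hybridization one-hot sp, sp2, sp3, other
#   [32]    atomic mass / 100
#
# Bond feature vector (length 8):
#   [1:4] order class one-hot single, double, triple, aromatic
#   [5]   conjugated
#   [6]   in ring
#   [7:8] stereo class one-hot none, marked (wedge/cis-trans annotated)

ATOM_FDIM <- 32L
BOND_FDIM <- 8L
FEAT_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

one_hot <- function(i, k) { v <- numeric(k); if (!is.na(i) && i >= 1 && i <= k) v[i] <- 1; v }

atom_features <- function(atoms) {
  n <- nrow(atoms)
  X <- matrix(0, n, ATOM_FDIM)
  for (v in seq_len(n)) {
    el <- match(atoms$symbol[v], FEAT_ELEMENTS, nomatch = 10L)
    hyb <- match(atoms$hybridization[v], c("sp", "sp2", "sp3"), nomatch = 4L)
    X[v, ] <- c(
      one_hot(el, 10L),
      one_hot(min(atoms$degree[v], 5L) + 1L, 6L),
      one_hot(atoms$charge[v] + 3L, 5L),
      one_hot(min(atoms$n_h[v], 4L) + 1L, 5L),
      as.numeric(atoms$aromatic[v]),
      one_hot(hyb, 4L),
      atoms$mass[v] / 100
    )
  }
  X
}

bond_features <- function(bonds) {
  nb <- nrow(bonds)
  E <- matrix(0, nb, BOND_FDIM)
  for (b in seq_len(nb)) {
    cls <- if (bonds$aromatic[b]) 4L else min(bonds$order[b], 3L)
    E[b, ] <- c(
      one_hot(cls, 4L),
      as.numeric(bonds$conjugated[b]),
      as.numeric(bonds$in_ring[b]),
      one_hot(if (bonds$stereo[b] == 0L) 1L else 2L, 2L)
    )
  }
  E
}

#' Featurize a molecule as a directed graph
#'
#' Builds the node/edge representation the message-passing network consumes:
#' per-atom and per-bond feature vectors plus, for every bond, two directed
#' edges and the index of each edge's reverse.
#'
#' @param smiles A single valid SMILES string.
#' @return A `mol_graph` list: `atom_features` (n_atoms x 32 matrix),
#'   `bond_features` (n_bonds x 8), `edge_src`/`edge_dst` (directed edge
#'   endpoints, length 2 x n_bonds), `edge_bond` (owning bond of each edge),
#'   `rev_edge` (involution mapping each directed edge to its reverse) and
#'   `n_atoms`.
#' @examples
#' g <- featurize_smiles("CCO")
#' g$n_atoms
#' length(g$edge_src)
#' @export
featurize_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1L, is.character(smiles), !is.na(smiles))
  featurize_mol(parse_molecules(smiles)[[1]])
}

featurize_mol <- function(mol) {
  if (mol$n_atoms == 0L) abort("empty molecule")
  bd <- mol$bonds
  nb <- nrow(bd)
  # directed edges: for bond b, edge 2b-1 runs a1 -> a2 and edge 2b a2 -> a1
  edge_src <- edge_dst <- edge_bond <- integer(2L * nb)
  if (nb > 0L) {
    edge_src[seq(1L, 2L * nb, by = 2L)] <- bd$a1
    edge_dst[seq(1L, 2L * nb, by = 2L)] <- bd$a2
    edge_src[seq(2L, 2L * nb, by = 2L)] <- bd$a2
    edge_dst[seq(2L, 2L * nb, by = 2L)] <- bd$a1
    edge_bond <- rep(seq_len(nb), each = 2L)
  }
  rev_edge <- if (nb > 0L) as.integer(seq_len(2L * nb) + c(1L, -1L)) else integer(0)
  structure(list(
    atom_features = atom_features(mol$atoms),
    bond_features = bond_features(bd),
    edge_src = edge_src, edge_dst = edge_dst, edge_bond = edge_bond,
    rev_edge = rev_edge, n_atoms = mol$n_atoms
  ), class = "mol_graph")
}
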