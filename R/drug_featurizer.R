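#' @title Atom-level drug graph featurization
#' @description Builds the undirected molecular graph with 82-d atom and
#'   6-d bond features from a parsed molecule record.
#' @name drug_featurizer
NULL

## fixed 82-d atom feature partition (documented, swappable in one place):
## element one-hot over 44 common elements + other (45), degree 0-10 (11),
## explicit valence 0-10 (11), implicit valence 0-10 (11), aromaticity
## true/false (2), formal-charge-sign pad (2, reserved; zero when charge
## information is absent from the input format). Total 45+11+11+11+2+2 = 82.
ATOM_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S", "Cl",
  "K", "Ca", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga",
  "Ge", "As", "Se", "Br", "Zr", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In",
  "Sn", "Sb", "Te", "I", "Pt", "Au", "Hg")

one_hot <- function(value, n_slots, other_last = TRUE) {
  v <- numeric(n_slots)
  idx <- if (is.na(value) || value < 1L || value > n_slots) {
    if (other_last) n_slots else NA_integer_
  } else value
  if (!is.na(idx)) v[idx] <- 1
  v
}

#' Featurize atoms of a molecule
#'
#' One 82-d row per atom: one-hot blocks for element (44 + other), degree
#' (0-10), explicit valence (0-10), implicit valence (0-10), aromaticity
#' (true/false) and a reserved 2-slot formal-charge-sign pad.
#' Out-of-vocabulary values map to the trailing slot of their block.
#'
#' @param mol a \code{tribind_molecule}.
#' @return N x 82 numeric matrix.
#' @export
featurize_atoms <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  out <- matrix(0, n, 82L)
  elem_idx <- match(a$element, ATOM_ELEMENTS)
  for (i in seq_len(n)) {
    deg <- a$degree[i]; ev <- a$explicit_valence[i]; iv <- a$implicit_valence[i]
    out[i, ] <- c(
      one_hot(elem_idx[i], 45L),
      one_hot(if (deg > 10L) NA_integer_ else deg + 1L, 11L),
      one_hot(if (ev > 10L) NA_integer_ else ev + 1L, 11L),
      one_hot(if (iv > 10L) NA_integer_ else iv + 1L, 11L),
      if (isTRUE(a$aromatic[i])) c(1, 0) else c(0, 1),
      c(0, 0))
  }
  out
}

#' Featurize bonds of a molecule
#'
#' One 6-d row per undirected bond: one-hot bond type over
#' \{single, double, triple, aromatic\}, then binary conjugation and
#' ring-membership flags.
#'
#' @param mol a \code{tribind_molecule}.
#' @return list with \code{bonds} (|E| x 2 integer matrix) and
#'   \code{features} (|E| x 6 matrix).
#' @export
featurize_bonds <- function(mol) {
  b <- mol$bonds
  m <- nrow(b)
  feat <- matrix(0, m, 6L)
  colnames(feat) <- c("single", "double", "triple", "aromatic",
                      "conjugated", "in_ring")
  for (k in seq_len(m)) {
    type <- if (isTRUE(b$aromatic[k])) 4L else as.integer(round(b$order[k]))
    if (type < 1L || type > 4L) type <- 1L
    feat[k, type] <- 1
    feat[k, 5] <- as.numeric(isTRUE(b$conjugated[k]))
    feat[k, 6] <- as.numeric(isTRUE(b$in_ring[k]))
  }
  list(bonds = cbind(i = b$i, j = b$j), features = feat)
}

#' Build the full drug graph
#'
#' @param mol a \code{tribind_molecule}.
#' @return object of class \code{tribind_drug_graph} with fields
#'   \code{n_atoms}, \code{atom_features} (N x 82), \code{bonds},
#'   \code{bond_features} (|E| x 6) and optional \code{coords}.
#' @export
build_drug_graph <- function(mol) {
  bf <- featurize_bonds(mol)
  structure(list(
    n_atoms = nrow(mol$atoms),
    atom_features = featurize_atoms(mol),
    bonds = bf$bonds,
    bond_features = bf$features,
    coords = mol$coords), class = "tribind_drug_graph")
}

#' @export
print.tribind_drug_graph <- function(x, ...) {
  cat("tribind_drug_graph:", x$n_atoms, "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}
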