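#' @title Pocket-centred heterogeneous interface graph
#' @description The directed residue-atom bipartite graph used by the
#'   affinity head: interface local frames, k-nearest-neighbour edges in
#'   both directions, and 8-d frame-based geometric edge features.
#' @name complex_graph
NULL

#' Build interface local frames for pocket residues and drug atoms
#'
#' Residue frames: origin at the alpha-carbon, z axis toward the nearest
#' drug atom, xz plane spanned with the vector to the preceding residue's
#' alpha-carbon (the succeeding one for the first residue), completed by
#' orthogonalization. Atom frames: origin at the atom, z toward the nearest
#' residue alpha-carbon, xz plane from the vector to the nearest
#' neighbouring atom. Degenerate configurations fall back to Gram-Schmidt
#' against a global axis.
#'
#' @param pocket a \code{tribind_structure} (the pocket residues).
#' @param drug_coords N_d x 3 drug atom coordinates (Å).
#' @return list with \code{residue} and \code{atom} frame lists.
#' @export
build_interface_frames <- function(pocket, drug_coords) {
  ca <- pocket$ca
  np <- nrow(ca)
  nd <- nrow(drug_coords)
  if (np < 1L || nd < 1L) stop("pocket and drug must both be nonempty")
  d_pd <- round(outer(rowSums(ca^2), rep(1, nd)) -
                2 * ca %*% t(drug_coords) +
                outer(rep(1, np), rowSums(drug_coords^2)), 6L)
  res_frames <- vector("list", np)
  for (i in seq_len(np)) {
    zv <- drug_coords[which.min(d_pd[i, ]), ] - ca[i, ]
    ref <- if (i > 1L) ca[i - 1L, ] - ca[i, ]
           else if (np > 1L) ca[2L, ] - ca[1L, ]
           else c(1, 0, 0)
    res_frames[[i]] <- frame_from_zx(ca[i, ], zv, ref)
  }
  atom_frames <- vector("list", nd)
  for (j in seq_len(nd)) {
    zv <- ca[which.min(d_pd[, j]), ] - drug_coords[j, ]
    ref <- if (nd > 1L) {
      dd <- round(rowSums(sweep(drug_coords, 2L, drug_coords[j, ], "-")^2), 6L)
      dd[j] <- Inf
      drug_coords[which.min(dd), ] - drug_coords[j, ]
    } else c(1, 0, 0)
    atom_frames[[j]] <- frame_from_zx(drug_coords[j, ], zv, ref)
  }
  list(residue = res_frames, atom = atom_frames)
}

## frame with given z direction and xz-plane reference vector; rows (x,y,z)
frame_from_zx <- function(origin, z_dir, x_hint) {
  zh <- unitize(z_dir)
  xh <- gs_orth(x_hint, zh)
  if (is.null(xh)) {
    xh <- gs_orth(c(0, 0, 1), zh)
    if (is.null(xh)) xh <- gs_orth(c(1, 0, 0), zh)
  }
  yh <- cross3(zh, xh)
  make_frame(origin, rbind(xh, yh, zh))
}

#' Build bidirectional k-nearest-neighbour interface edges
#'
#' Each pocket residue connects to its k nearest drug atoms (protein-to-drug
#' edges) and each drug atom to its k nearest residues (drug-to-protein
#' edges), by Euclidean alpha-carbon-to-atom distance. Ties break toward the
#' lower index; fewer than k candidates connect to all of them.
#'
#' @param pocket_ca N_p x 3 alpha-carbon coordinates.
#' @param drug_coords N_d x 3 atom coordinates.
#' @param k neighbours per source node (default 6).
#' @return list with integer matrices \code{p2d} (columns res, atom) and
#'   \code{d2p} (columns atom, res).
#' @export
build_hetero_edges <- function(pocket_ca, drug_coords, k = 6L) {
  np <- nrow(pocket_ca); nd <- nrow(drug_coords)
  if (np < 1L || nd < 1L) stop("both node sets must be nonempty")
  ## squared distances rounded to 1e-6 so that exact geometric ties break
  ## by index deterministically, independent of global orientation
  d <- round(outer(rowSums(pocket_ca^2), rep(1, nd)) -
             2 * pocket_ca %*% t(drug_coords) +
             outer(rep(1, np), rowSums(drug_coords^2)), 6L)
  p2d <- do.call(rbind, lapply(seq_len(np), function(i) {
    nb <- order(d[i, ], seq_len(nd))[seq_len(min(k, nd))]
    cbind(res = i, atom = nb)
  }))
  d2p <- do.call(rbind, lapply(seq_len(nd), function(j) {
    nb <- order(d[, j], seq_len(np))[seq_len(min(k, np))]
    cbind(atom = j, res = nb)
  }))
  list(p2d = p2d, d2p = d2p)
}

#' Compute 8-d heterogeneous edge features
#'
#' Protein-to-drug edge (i, j): residue i's position expressed in atom j's
#' local frame (3), the radial-basis distance encoding (1), and the
#' quaternion rotating atom j's frame onto residue i's frame (4).
#' Drug-to-protein edges are the symmetric counterparts (atom position in
#' the residue frame, quaternion residue-to-atom). All features are
#' invariant under global rigid motions of the complex.
#'
#' @param frames from [build_interface_frames()].
#' @param pocket_ca,drug_coords coordinates as in [build_hetero_edges()].
#' @param edges from [build_hetero_edges()].
#' @param sigma radial-basis width (Å).
#' @return list with matrices \code{p2d} and \code{d2p}, each |E| x 8.
#' @export
compute_hetero_edge_features <- function(frames, pocket_ca, drug_coords,
                                         edges, sigma = 1.0) {
  feat_one <- function(src_pos, dst_frame, src_frame) {
    rel <- src_pos - dst_frame$origin
    c(as.numeric(dst_frame$basis %*% rel),
      rbf_distance(vnorm(rel), sigma),
      relative_quaternion(dst_frame, src_frame))
  }
  p2d <- t(apply(edges$p2d, 1L, function(e) {
    feat_one(pocket_ca[e[1], ], frames$atom[[e[2]]], frames$residue[[e[1]]])
  }))
  d2p <- t(apply(edges$d2p, 1L, function(e) {
    feat_one(drug_coords[e[1], ], frames$residue[[e[2]]], frames$atom[[e[1]]])
  }))
  colnames(p2d) <- colnames(d2p) <-
    c("x", "y", "z", "rbf", "qw", "qx", "qy", "qz")
  list(p2d = p2d, d2p = d2p)
}

#' Build the full heterogeneous complex graph
#'
#' @param pocket a \code{tribind_structure} holding the pocket residues.
#' @param drug_coords N_d x 3 drug atom coordinates (Å).
#' @param config a [model_config()] (uses \code{k} and \code{sigma}).
#' @return object of class \code{tribind_hetero_graph}.
#' @export
build_hetero_graph <- function(pocket, drug_coords, config = model_config()) {
  drug_coords <- as.matrix(drug_coords)
  if (nrow(drug_coords) < 2L) stop("drug must have at least 2 atoms")
  frames <- build_interface_frames(pocket, drug_coords)
  edges <- build_hetero_edges(pocket$ca, drug_coords, k = config$k)
  feats <- compute_hetero_edge_features(frames, pocket$ca, drug_coords,
                                        edges, sigma = config$sigma)
  structure(list(
    n_pocket = nrow(pocket$ca),
    n_atoms = nrow(drug_coords),
    edges_p2d = edges$p2d,
    edges_d2p = edges$d2p,
    feat_p2d = feats$p2d,
    feat_d2p = feats$d2p,
    frames = frames), class = "tribind_hetero_graph")
}

#' @export
print.tribind_hetero_graph <- function(x, ...) {
  cat("tribind_hetero_graph:", x$n_pocket, "pocket residues,",
      x$n_atoms, "drug atoms,",
      nrow(x$edges_p2d) + nrow(x$edges_d2p), "directed edges\n")
  invisible(x)
}

#' Pocket residues by distance to the ligand
#'
#' The fallback pocket rule when no pocket file is supplied: residues with
#' any heavy atom within \code{radius} of any ligand heavy atom.
#'
#' @param structure a \code{tribind_structure}.
#' @param drug_coords ligand heavy-atom coordinates.
#' @param radius cutoff (Å), default 10.
#' @return integer vector of residue indices.
#' @export
pocket_by_distance <- function(structure, drug_coords, radius = 10) {
  at <- structure$atom[structure$atom$elesy != "H", , drop = FALSE]
  axyz <- as.matrix(at[, c("x", "y", "z")])
  drug_coords <- as.matrix(drug_coords)
  d2 <- outer(rowSums(axyz^2), rep(1, nrow(drug_coords))) -
    2 * axyz %*% t(drug_coords) +
    outer(rep(1, nrow(axyz)), rowSums(drug_coords^2))
  close_atom <- apply(d2, 1L, min) <= radius^2
  sort(unique(at$res_index[close_atom]))
}
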