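#' @title Residue-level protein graph featurization
#' @description Builds the directed residue graph: contact edges between
#'   alpha-carbons, 8-d rotation-invariant geometric edge features
#'   (local-frame coordinates, radial-basis distance, inter-frame
#'   quaternion), 1024-d sequence embeddings, and 10-d surface descriptors.
#' @name protein_featurizer
NULL

#' Build directed residue contact edges
#'
#' Residues are connected in both directions whenever their alpha-carbons
#' lie within the cutoff; no self edges. Edges are returned in lexicographic
#' (i, j) order.
#'
#' @param structure a \code{tribind_structure} (or an N x 3 Calpha matrix).
#' @param cutoff contact cutoff between alpha-carbons (Å), default 12.
#' @return integer matrix with columns i, j (1-based residue indices).
#' @export
build_residue_edges <- function(structure, cutoff = 12) {
  ca <- if (is.matrix(structure)) structure else structure$ca
  n <- nrow(ca)
  if (n < 1L) stop("need at least one residue")
  d <- as.matrix(stats::dist(ca))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(i = idx[, 1], j = idx[, 2])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Compute 8-d geometric edge features
#'
#' For a directed edge (i, j): the coordinates of residue j's alpha-carbon
#' expressed in residue i's local frame (3), the Gaussian radial-basis
#' encoding of the inter-residue distance (1), and the unit quaternion of
#' the relative rotation between the two frames (4). All entries are
#' invariant under global rigid motions.
#'
#' @param frames list of frames from [build_residue_frames()].
#' @param ca N x 3 alpha-carbon coordinates (Å).
#' @param edges edge matrix from [build_residue_edges()].
#' @param sigma radial-basis width (Å).
#' @return |E| x 8 numeric matrix.
#' @export
compute_edge_features <- function(frames, ca, edges, sigma = 1.0) {
  m <- nrow(edges)
  out <- matrix(0, m, 8L)
  colnames(out) <- c("x", "y", "z", "rbf", "qw", "qx", "qy", "qz")
  for (e in seq_len(m)) {
    i <- edges[e, 1]; j <- edges[e, 2]
    rel <- ca[j, ] - ca[i, ]
    loc <- as.numeric(frames[[i]]$basis %*% rel)
    out[e, 1:3] <- loc
    out[e, 4] <- rbf_distance(vnorm(rel), sigma)
    out[e, 5:8] <- relative_quaternion(frames[[i]], frames[[j]])
  }
  out
}

#' Deterministic stub sequence embedder
#'
#' A drop-in stand-in for a pretrained protein-language-model embedder: each
#' row is a reproducible, position-aware expansion of (residue letter,
#' position) into 1024 values in \[-1, 1\]. The letter component dominates
#' (weight 0.8) so that residue identity remains linearly recoverable
#' downstream, with a position component (weight 0.2) making rows distinct
#' across positions.
#'
#' @param dimension embedding width (1024 to match the modelled encoder).
#' @return an embedder object (class \code{tribind_embedder}) with fields
#'   \code{name}, \code{dimension}, \code{deterministic} and \code{embed}.
#' @export
stub_embedder <- function(dimension = 1024L) {
  cache <- new.env(parent = emptyenv())
  seeded_vec <- function(seed, d) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    stats::runif(d, -1, 1)
  }
  letter_vec <- function(l) {
    key <- paste0("L", l)
    if (is.null(cache[[key]])) {
      cache[[key]] <- seeded_vec((utf8ToInt(l) * 100003L) %% 2147483647L,
                                 dimension)
    }
    cache[[key]]
  }
  pos_vec <- function(p) {
    key <- paste0("P", p)
    if (is.null(cache[[key]])) {
      cache[[key]] <- seeded_vec((p * 7919L + 13L) %% 2147483647L, dimension)
    }
    cache[[key]]
  }
  structure(list(
    name = "stub-hash",
    dimension = as.integer(dimension),
    deterministic = TRUE,
    embed = function(sequence) {
      letters_ <- strsplit(sequence, "")[[1]]
      out <- matrix(0, length(letters_), dimension)
      for (i in seq_along(letters_)) {
        out[i, ] <- 0.8 * letter_vec(letters_[i]) + 0.2 * pos_vec(i)
      }
      out
    }), class = "tribind_embedder")
}

#' Embed a protein sequence
#'
#' @param sequence 1-letter amino-acid string (all chains concatenated in
#'   residue order).
#' @param embedder an embedder object, e.g. [stub_embedder()].
#' @return N x dimension matrix, rows aligned with residue order.
#' @export
embed_sequence <- function(sequence, embedder) {
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  out <- embedder$embed(sequence)
  if (nrow(out) != nchar(sequence)) {
    stop("embedder returned ", nrow(out), " rows for a sequence of length ",
         nchar(sequence))
  }
  out
}

#' Build the full residue graph for a protein
#'
#' Combines sequence embeddings (node features), contact edges with 8-d
#' geometric features, per-residue local frames, and the 10-d surface
#' tensor into the record the protein encoder consumes.
#'
#' @param structure a \code{tribind_structure}.
#' @param embedder sequence embedder (default [stub_embedder()]).
#' @param config a [model_config()].
#' @param surface logical; compute surface descriptors (TRUE) or fill the
#'   surface block with zeros (for speed in geometry-only checks).
#' @return object of class \code{tribind_residue_graph}.
#' @export
build_residue_graph <- function(structure, embedder = stub_embedder(),
                                config = model_config(), surface = TRUE) {
  frames <- build_residue_frames(structure)
  edges <- build_residue_edges(structure, cutoff = config$cutoff)
  efeat <- compute_edge_features(frames, structure$ca, edges,
                                 sigma = config$sigma)
  seq_all <- paste0(structure$residues$letter, collapse = "")
  node <- embed_sequence(seq_all, embedder)
  surf <- if (surface) {
    compute_surface_features(structure,
                             probe = config$surface_probe,
                             n_points = config$surface_points,
                             fit_radius = config$surface_fit_radius)
  } else {
    matrix(0, n_residues(structure), 10L)
  }
  structure(list(
    n_residues = n_residues(structure),
    node_features = node,
    edges = edges,
    edge_features = efeat,
    surface_features = surf,
    frames = frames,
    ca = structure$ca), class = "tribind_residue_graph")
}

#' @export
print.tribind_residue_graph <- function(x, ...) {
  cat("tribind_residue_graph:", x$n_residues, "residues,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Restrict a residue graph to a pocket
#'
#' Keeps the selected residues (renumbered, original order) and the edges
#' among them; node, surface and frame entries are subset accordingly.
#'
#' @param graph a \code{tribind_residue_graph}.
#' @param indices residue indices (1-based, into the graph's residues).
#' @export
subset_residue_graph <- function(graph, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices) || any(indices < 1L | indices > graph$n_residues)) {
    stop("pocket indices out of range")
  }
  keep <- graph$edges[, 1] %in% indices & graph$edges[, 2] %in% indices
  edges <- graph$edges[keep, , drop = FALSE]
  edges[, 1] <- match(edges[, 1], indices)
  edges[, 2] <- match(edges[, 2], indices)
  structure(list(
    n_residues = length(indices),
    node_features = graph$node_features[indices, , drop = FALSE],
    edges = edges,
    edge_features = graph$edge_features[keep, , drop = FALSE],
    surface_features = graph$surface_features[indices, , drop = FALSE],
    frames = graph$frames[indices],
    ca = graph$ca[indices, , drop = FALSE]),
    class = "tribind_residue_graph")
}
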