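#' @title Graph encoders
#' @description The protein graph-attention encoder (blended node/edge
#'   similarity attention with residual updates and surface fusion) and the
#'   drug message-passing encoder. Forward passes are written against the
#'   autodiff tape so the same code serves prediction and training.
#' @name encoders
NULL

## ---- parameter initialization ------------------------------------------

#' Initialize protein encoder parameters
#'
#' Weights are shared across the T message-passing layers. Projection from
#' the 1024-d sequence embeddings to h1, surface projection to h2, message /
#' attention matrices, the residual output transform, and the two-layer
#' surface-fusion MLP.
#'
#' @param config a [model_config()].
#' @param in_dim node feature width (1024).
#' @return named list of matrices, prefixed \code{pe.}.
#' @export
init_protein_encoder_params <- function(config, in_dim = 1024L) {
  h1 <- config$h1; h2 <- config$h2
  list(
    pe.W_in = glorot(in_dim, h1), pe.b_in = matrix(0, 1, h1),
    pe.W_s = glorot(10L, h2), pe.b_s = matrix(0, 1, h2),
    pe.Wv = glorot(h1, h1), pe.We = glorot(8L, h1),
    pe.WQv = glorot(h1, h1), pe.WKv = glorot(h1, h1),
    pe.WQe = glorot(8L, 8L), pe.WKe = glorot(8L, 8L),
    pe.Wout = glorot(h1, h1),
    pe.Wf1 = glorot(h1 + h2, h1), pe.bf1 = matrix(0, 1, h1),
    pe.Wf2 = glorot(h1, h1), pe.bf2 = matrix(0, 1, h1))
}

#' Initialize drug encoder parameters
#' @param config a [model_config()].
#' @return named list of matrices, prefixed \code{de.}.
#' @export
init_drug_encoder_params <- function(config) {
  h3 <- config$h3
  list(
    de.W_in = glorot(82L, h3), de.b_in = matrix(0, 1, h3),
    de.Wu = glorot(h3 + 6L, h3),
    de.WC = glorot(2L * h3, h3))
}

## ---- forward passes (autodiff nodes in, node out) ----------------------

#' Protein encoder forward pass (tape form)
#'
#' Implements, per layer: messages m_ij = alpha_ij (W_v h_j + W_e e_ij)
#' with alpha = lambda * softmax(node-similarity) +
#' (1 - lambda) * softmax(edge-similarity), both normalized over each target
#' node's in-neighbourhood; residual update
#' h <- LeakyReLU(W_out (h + sum_j m_ij)) + h. After T layers the node
#' state is concatenated with the projected surface features and fused by a
#' two-layer MLP.
#'
#' @param graph a \code{tribind_residue_graph}.
#' @param P wrapped parameter nodes (see [ad_wrap_params()]).
#' @param config a [model_config()].
#' @return autodiff node holding the N x h1 residue embeddings.
#' @keywords internal
encode_protein_f <- function(graph, P, config) {
  slope <- config$leaky_slope
  X <- ad_leaf(graph$node_features, track = FALSE)
  S <- ad_leaf(graph$surface_features, track = FALSE)
  H <- ad_leaky_relu(nn_linear(X, P$pe.W_in, P$pe.b_in), slope)
  Sp <- ad_leaky_relu(nn_linear(S, P$pe.W_s, P$pe.b_s), slope)
  n <- graph$n_residues
  has_edges <- nrow(graph$edges) > 0L
  if (has_edges) {
    ei <- graph$edges[, 1]; ej <- graph$edges[, 2]
    Ef <- ad_leaf(graph$edge_features, track = FALSE)
    ## edge-similarity attention is layer-independent (edge features are
    ## static); compute its normalized weights once
    eq <- ad_matmul(Ef, P$pe.WQe)
    ek <- ad_matmul(Ef, P$pe.WKe)
    se <- ad_smul(ad_rowsums(ad_mul(eq, ek)), 1 / sqrt(8))
    alpha_e <- ad_segment_softmax(se, ei)
  }
  for (t in seq_len(config$T)) {
    if (has_edges) {
      hq <- ad_matmul(H, P$pe.WQv)
      hk <- ad_matmul(H, P$pe.WKv)
      sv <- ad_smul(ad_rowsums(ad_mul(ad_gather_rows(hq, ej),
                                      ad_gather_rows(hk, ei))),
                    1 / sqrt(config$h1))
      alpha_v <- ad_segment_softmax(sv, ei)
      alpha <- ad_add(ad_smul(alpha_v, config$lambda),
                      ad_smul(alpha_e, 1 - config$lambda))
      base <- ad_add(ad_matmul(ad_gather_rows(H, ej), P$pe.Wv),
                     ad_matmul(Ef, P$pe.We))
      agg <- ad_segment_sum(ad_mul_colvec(base, alpha), ei, n)
      H <- ad_add(ad_leaky_relu(ad_matmul(ad_add(H, agg), P$pe.Wout), slope),
                  H)
    } else {
      H <- ad_add(ad_leaky_relu(ad_matmul(H, P$pe.Wout), slope), H)
    }
  }
  Z <- ad_cbind(list(H, Sp))
  nn_linear(ad_leaky_relu(nn_linear(Z, P$pe.Wf1, P$pe.bf1), slope),
            P$pe.Wf2, P$pe.bf2)
}

#' Drug encoder forward pass (tape form)
#'
#' Message-passing over the undirected molecular graph: per layer, messages
#' m_ij = LeakyReLU(W_u \[h_j || e_ij\]) flow along both directions of every
#' bond and the update is h <- W_C \[h || sum_j m_ij\].
#'
#' @inheritParams encode_protein_f
#' @param graph a \code{tribind_drug_graph}.
#' @return autodiff node holding the N x h3 atom embeddings.
#' @keywords internal
encode_drug_f <- function(graph, P, config) {
  slope <- config$leaky_slope
  X <- ad_leaf(graph$atom_features, track = FALSE)
  H <- ad_leaky_relu(nn_linear(X, P$de.W_in, P$de.b_in), slope)
  n <- graph$n_atoms
  m <- nrow(graph$bonds)
  if (m > 0L) {
    src <- c(graph$bonds[, 2], graph$bonds[, 1])
    dst <- c(graph$bonds[, 1], graph$bonds[, 2])
    Ef <- ad_leaf(rbind(graph$bond_features, graph$bond_features),
                  track = FALSE)
  }
  for (t in seq_len(config$T)) {
    if (m > 0L) {
      msg <- ad_leaky_relu(
        ad_matmul(ad_cbind(list(ad_gather_rows(H, src), Ef)), P$de.Wu),
        slope)
      agg <- ad_segment_sum(msg, dst, n)
    } else {
      agg <- ad_leaf(matrix(0, n, config$h3), track = FALSE)
    }
    H <- ad_matmul(ad_cbind(list(H, agg)), P$de.WC)
  }
  H
}

## ---- user-facing matrix wrappers ---------------------------------------

#' Encode a protein residue graph
#'
#' @param graph a \code{tribind_residue_graph}.
#' @param params named parameter list from [init_protein_encoder_params()].
#' @param config a [model_config()].
#' @return N x h1 matrix of residue embeddings.
#' @export
encode_protein <- function(graph, params, config = model_config()) {
  check_shapes_protein(params, config, ncol(graph$node_features))
  ad_reset()
  P <- ad_wrap_params(params)
  out <- encode_protein_f(graph, P, config)
  v <- out$value
  ad_reset()
  v
}

#' Encode a drug graph
#'
#' @param graph a \code{tribind_drug_graph}.
#' @param params named parameter list from [init_drug_encoder_params()].
#' @param config a [model_config()].
#' @return N x h3 matrix of atom embeddings.
#' @export
encode_drug <- function(graph, params, config = model_config()) {
  if (nrow(params$de.W_in) != ncol(graph$atom_features)) {
    stop("shape error: drug input projection expects ",
         nrow(params$de.W_in), " columns, graph has ",
         ncol(graph$atom_features))
  }
  ad_reset()
  P <- ad_wrap_params(params)
  out <- encode_drug_f(graph, P, config)
  v <- out$value
  ad_reset()
  v
}

check_shapes_protein <- function(params, config, in_dim) {
  if (nrow(params$pe.W_in) != in_dim) {
    stop("shape error in input projection: weight expects ",
         nrow(params$pe.W_in), "-d node features, graph has ", in_dim)
  }
  if (ncol(params$pe.W_in) != config$h1) {
    stop("shape error: projection width ", ncol(params$pe.W_in),
         " does not match h1 = ", config$h1)
  }
  invisible(TRUE)
}
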