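# shared fixtures, memoized so expensive featurization runs once per suite
.fix <- new.env(parent = emptyenv())

get_fix <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

tiny_cfg <- function(...) desk_config(...)

fix_complex <- function() get_fix("complex", function() make_toy_complex(3))

fix_site_sample <- function() get_fix("site_sample", function() {
  featurize_complex(fix_complex(), "site", tiny_cfg())
})

fix_aff_sample <- function() get_fix("aff_sample", function() {
  featurize_complex(fix_complex(), "affinity", tiny_cfg())
})

seeded_params <- function(task, cfg = tiny_cfg(), seed = 1L) {
  set.seed(seed)
  init_task_params(task, cfg)
}

# build a minimal residue graph by hand (node features random, no surface)
manual_residue_graph <- function(node, edges, efeat, surface = NULL,
                                 ca = NULL) {
  n <- nrow(node)
  if (is.null(surface)) surface <- matrix(0, n, 10)
  structure(list(n_residues = n, node_features = node, edges = edges,
                 edge_features = efeat, surface_features = surface,
                 frames = NULL, ca = ca),
            class = "tribind_residue_graph")
}

# apply a residue permutation to a residue graph (relabelling oracle)
permute_residue_graph <- function(graph, perm) {
  inv <- order(perm) # inv[old] = new position
  g <- graph
  g$node_features <- graph$node_features[perm, , drop = FALSE]
  g$surface_features <- graph$surface_features[perm, , drop = FALSE]
  g$ca <- graph$ca[perm, , drop = FALSE]
  g$frames <- graph$frames[perm]
  g$edges <- cbind(i = inv[graph$edges[, 1]], j = inv[graph$edges[, 2]])
  g$edge_features <- graph$edge_features
  g
}

# independent dense implementation of the protein encoder on a small graph:
# explicit loops over neighbourhoods, softmax by hand (the oracle for the
# graph-attention forward pass)
dense_protein_encoder <- function(graph, params, cfg) {
  lrelu <- function(x) ifelse(x > 0, x, cfg$leaky_slope * x)
  H <- lrelu(sweep(graph$node_features %*% params$pe.W_in, 2,
                   as.numeric(params$pe.b_in), "+"))
  Sp <- lrelu(sweep(graph$surface_features %*% params$pe.W_s, 2,
                    as.numeric(params$pe.b_s), "+"))
  n <- graph$n_residues
  E <- graph$edges
  Ef <- graph$edge_features
  for (t in seq_len(cfg$T)) {
    agg <- matrix(0, n, cfg$h1)
    for (i in seq_len(n)) {
      eids <- which(E[, 1] == i)
      if (!length(eids)) next
      js <- E[eids, 2]
      sv <- vapply(seq_along(eids), function(k) {
        sum((H[js[k], ] %*% params$pe.WQv) *
              (H[i, ] %*% params$pe.WKv)) / sqrt(cfg$h1)
      }, numeric(1))
      se <- vapply(eids, function(e) {
        sum((Ef[e, ] %*% params$pe.WQe) *
              (Ef[e, ] %*% params$pe.WKe)) / sqrt(8)
      }, numeric(1))
      soft <- function(x) { x <- x - max(x); exp(x) / sum(exp(x)) }
      alpha <- cfg$lambda * soft(sv) + (1 - cfg$lambda) * soft(se)
      for (k in seq_along(eids)) {
        msg <- alpha[k] * (H[js[k], ] %*% params$pe.Wv +
                             Ef[eids[k], ] %*% params$pe.We)
        agg[i, ] <- agg[i, ] + msg
      }
    }
    H <- lrelu((H + agg) %*% params$pe.Wout) + H
  }
  Z <- cbind(H, Sp)
  h <- lrelu(sweep(Z %*% params$pe.Wf1, 2, as.numeric(params$pe.bf1), "+"))
  sweep(h %*% params$pe.Wf2, 2, as.numeric(params$pe.bf2), "+")
}

# independent dense drug MPNN oracle
dense_drug_encoder <- function(graph, params, cfg) {
  lrelu <- function(x) ifelse(x > 0, x, cfg$leaky_slope * x)
  H <- lrelu(sweep(graph$atom_features %*% params$de.W_in, 2,
                   as.numeric(params$de.b_in), "+"))
  n <- graph$n_atoms
  for (t in seq_len(cfg$T)) {
    agg <- matrix(0, n, cfg$h3)
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[b, 1]; j <- graph$bonds[b, 2]
      ef <- graph$bond_features[b, ]
      agg[i, ] <- agg[i, ] + lrelu(c(H[j, ], ef) %*% params$de.Wu)
      agg[j, ] <- agg[j, ] + lrelu(c(H[i, ], ef) %*% params$de.Wu)
    }
    H <- cbind(H, agg) %*% params$de.WC
  }
  H
}

# brute-force AUROC by pairwise rank counting
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
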