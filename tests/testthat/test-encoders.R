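small_graph <- function(n = 5L, seed = 1L, cutoff = 6) {
  set.seed(seed)
  ca <- matrix(rnorm(n * 3, sd = 3), n, 3)
  edges <- build_residue_edges(ca, cutoff = cutoff)
  frames <- lapply(seq_len(n), function(i) {
    tribind:::make_frame(ca[i, ], tribind:::random_rotation())
  })
  efeat <- compute_edge_features(frames, ca, edges)
  manual_residue_graph(matrix(rnorm(n * 1024), n), edges, efeat,
                       surface = matrix(runif(n * 10), n), ca = ca)
}

test_that("an isolated node reduces to T residual dense updates", {
  cfg <- tiny_cfg()
  g <- manual_residue_graph(matrix(rnorm(1024), 1),
                            matrix(integer(0), 0, 2),
                            matrix(numeric(0), 0, 8),
                            surface = matrix(runif(10), 1))
  set.seed(3)
  params <- init_protein_encoder_params(cfg)
  out <- encode_protein(g, params, cfg)
  lrelu <- function(x) ifelse(x > 0, x, cfg$leaky_slope * x)
  h <- lrelu(g$node_features %*% params$pe.W_in +
               matrix(params$pe.b_in, 1))
  for (t in 1:cfg$T) h <- lrelu(h %*% params$pe.Wout) + h
  sp <- lrelu(g$surface_features %*% params$pe.W_s +
                matrix(params$pe.b_s, 1))
  z <- cbind(h, sp)
  ref <- lrelu(z %*% params$pe.Wf1 + matrix(params$pe.bf1, 1)) %*%
    params$pe.Wf2 + matrix(params$pe.bf2, 1)
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("protein encoder matches the dense hand-rolled oracle", {
  cfg <- tiny_cfg()
  g <- small_graph(5, seed = 2)
  set.seed(4)
  params <- init_protein_encoder_params(cfg)
  expect_lt(max(abs(encode_protein(g, params, cfg) -
                      dense_protein_encoder(g, params, cfg))), 1e-6)
})

test_that("lambda endpoints reduce to pure node or edge attention", {
  g <- small_graph(5, seed = 5)
  for (lam in c(0, 1)) {
    cfg <- tiny_cfg(lambda = lam)
    set.seed(6)
    params <- init_protein_encoder_params(cfg)
    expect_lt(max(abs(encode_protein(g, params, cfg) -
                        dense_protein_encoder(g, params, cfg))), 1e-6)
  }
})

test_that("protein encoder is permutation-equivariant", {
  cfg <- tiny_cfg()
  g <- small_graph(5, seed = 7)
  set.seed(8)
  params <- init_protein_encoder_params(cfg)
  out <- encode_protein(g, params, cfg)
  perm <- c(3, 1, 5, 2, 4)
  out_p <- encode_protein(permute_residue_graph(g, perm), params, cfg)
  expect_lt(max(abs(out_p - out[perm, ])), 1e-9)
})

test_that("a bond-free atom reduces to dense concatenation updates", {
  cfg <- tiny_cfg()
  g <- build_drug_graph(new_molecule_record(
    atoms = data.frame(element = "C", degree = 0L, explicit_valence = 0L,
                       implicit_valence = 4L, aromatic = FALSE),
    bonds = data.frame(i = integer(0), j = integer(0), order = numeric(0),
                       aromatic = logical(0), conjugated = logical(0),
                       in_ring = logical(0))))
  set.seed(9)
  params <- init_drug_encoder_params(cfg)
  out <- encode_drug(g, params, cfg)
  lrelu <- function(x) ifelse(x > 0, x, cfg$leaky_slope * x)
  h <- lrelu(g$atom_features %*% params$de.W_in +
               matrix(params$de.b_in, 1))
  for (t in 1:cfg$T) h <- cbind(h, matrix(0, 1, cfg$h3)) %*% params$de.WC
  expect_lt(max(abs(out - h)), 1e-6)
})

test_that("drug encoder matches the dense oracle and is equivariant", {
  cfg <- tiny_cfg()
  mol <- make_toy_molecule(seed = 10, n_atoms = 6)
  g <- build_drug_graph(mol)
  set.seed(11)
  params <- init_drug_encoder_params(cfg)
  out <- encode_drug(g, params, cfg)
  expect_lt(max(abs(out - dense_drug_encoder(g, params, cfg))), 1e-6)
  perm <- c(4, 2, 6, 1, 3, 5)
  inv <- order(perm)
  gp <- g
  gp$atom_features <- g$atom_features[perm, , drop = FALSE]
  gp$bonds <- cbind(i = inv[g$bonds[, 1]], j = inv[g$bonds[, 2]])
  out_p <- encode_drug(gp, params, cfg)
  expect_lt(max(abs(out_p - out[perm, ])), 1e-9)
})

test_that("disconnected molecular components do not exchange information", {
  cfg <- tiny_cfg()
  atoms <- data.frame(element = c("C", "C", "O", "N"),
                      degree = c(1L, 1L, 1L, 1L),
                      explicit_valence = c(1L, 1L, 1L, 1L),
                      implicit_valence = c(3L, 3L, 1L, 2L),
                      aromatic = FALSE)
  bonds <- data.frame(i = c(1L, 3L), j = c(2L, 4L), order = 1,
                      aromatic = FALSE, conjugated = FALSE, in_ring = FALSE)
  g1 <- build_drug_graph(new_molecule_record(atoms, bonds))
  atoms2 <- atoms
  atoms2$element[3] <- "S"  # perturb the second component only
  g2 <- build_drug_graph(new_molecule_record(atoms2, bonds))
  set.seed(12)
  params <- init_drug_encoder_params(cfg)
  o1 <- encode_drug(g1, params, cfg)
  o2 <- encode_drug(g2, params, cfg)
  expect_equal(o1[1:2, ], o2[1:2, ])
  expect_gt(max(abs(o1[3, ] - o2[3, ])), 1e-8)
})

test_that("encoder outputs stay finite across many random inits", {
  cfg <- tiny_cfg()
  g <- small_graph(6, seed = 13)
  dg <- build_drug_graph(make_toy_molecule(seed = 13, n_atoms = 7))
  for (s in 1:20) {
    set.seed(s)
    pp <- init_protein_encoder_params(cfg)
    dp <- init_drug_encoder_params(cfg)
    expect_true(all(is.finite(encode_protein(g, pp, cfg))))
    expect_true(all(is.finite(encode_drug(dg, dp, cfg))))
  }
})

test_that("every parameter matrix receives gradient on a random batch", {
  cfg <- tiny_cfg(epochs = 1L)
  for (task in c("occurrence", "site", "affinity")) {
    sample <- if (task == "affinity") fix_aff_sample() else {
      s <- fix_site_sample()
      if (task == "occurrence") s$label <- 1
      s
    }
    set.seed(21)
    params <- init_task_params(task, cfg)
    tribind:::ad_reset()
    P <- tribind:::ad_wrap_params(params)
    fw <- tribind:::sample_forward(sample, P, cfg, task, "focal",
                                   train = FALSE)
    tribind:::ad_backward(fw$loss)
    g <- tribind:::ad_grads(P)
    zero_mats <- names(g)[vapply(g, function(m) all(m == 0), logical(1))]
    expect_length(zero_mats, 0L)
    tribind:::ad_reset()
  }
})
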