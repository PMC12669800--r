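single_residue_pocket <- function(ca = c(0, 0, 0)) {
  at <- data.frame(chain = "A", resno = 1L, insert = "", resid = "ALA",
                   elety = "CA", elesy = "C",
                   x = ca[1], y = ca[2], z = ca[3], stringsAsFactors = FALSE)
  tribind:::build_structure(at)
}

test_that("residue interface frame points z toward the nearest drug atom", {
  pk <- single_residue_pocket()
  drug <- rbind(c(5, 0, 0), c(7, 0, 0))
  fr <- build_interface_frames(pk, drug)
  expect_equal(as.numeric(fr$residue[[1]]$basis[3, ]), c(1, 0, 0))
  expect_true(tribind:::frame_is_orthonormal(fr$residue[[1]]))
  for (f in fr$atom) expect_true(tribind:::frame_is_orthonormal(f))
})

test_that("the first residue's frame uses the succeeding residue", {
  st <- make_toy_protein(5, seed = 1)
  drug <- rbind(c(8, 0, 2), c(9, 1, 2))
  fr <- build_interface_frames(st, drug)
  for (f in fr$residue) expect_true(tribind:::frame_is_orthonormal(f))
})

test_that("interface frames co-rotate under rigid motion of the complex", {
  cx <- fix_complex()
  sa <- fix_aff_sample()
  pk <- extract_pocket(cx$protein,
                       cx$protein$residues[sa$pocket_indices, ])
  fr <- build_interface_frames(pk, cx$drug$coords)
  set.seed(77)
  R <- tribind:::random_rotation(); tr <- c(4, -9, 2)
  pk2 <- transform_structure(pk, R, tr)
  drug2 <- sweep(cx$drug$coords %*% t(R), 2, tr, "+")
  fr2 <- build_interface_frames(pk2, drug2)
  for (i in seq_along(fr$residue)) {
    expect_lt(max(abs(fr2$residue[[i]]$basis -
                        fr$residue[[i]]$basis %*% t(R))), 1e-8)
  }
})

test_that("knn edge counts follow min(k, available) in both directions", {
  ca <- matrix(c(0, 0, 0), 1, 3)
  drug <- rbind(c(3, 0, 0), c(4, 0, 0), c(5, 0, 0))
  e <- build_hetero_edges(ca, drug, k = 6)
  expect_equal(nrow(e$p2d), 3L)  # 1 residue x min(6, 3) atoms
  expect_equal(nrow(e$d2p), 3L)  # 3 atoms x min(6, 1) residues
})

test_that("knn neighbours equal a brute-force distance sort", {
  ca <- cbind(seq(0, 27, by = 3), 0, 0)  # 10 residues on a line
  drug <- matrix(c(-2, 0, 0), 1, 3)
  e <- build_hetero_edges(ca, drug, k = 6)
  got <- e$d2p[e$d2p[, 1] == 1, 2]
  dist_sorted <- order(sqrt(rowSums(sweep(ca, 2, drug[1, ], "-")^2)))
  expect_equal(sort(got), sort(dist_sorted[1:6]))
})

test_that("exact distance ties resolve deterministically", {
  ca <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  drug <- rbind(c(0, 0, 0), c(0, 0, 2))
  e1 <- build_hetero_edges(ca, drug, k = 2)
  e2 <- build_hetero_edges(ca, drug, k = 2)
  expect_identical(e1, e2)
  # all four residues are equidistant from atom 1: lowest indices win
  expect_equal(e1$d2p[e1$d2p[, 1] == 1, 2], c(1L, 2L))
})

test_that("hetero edge features evaluate distances and degeneracies", {
  pk <- single_residue_pocket(c(0, 0, 0))
  drug <- rbind(c(2, 0, 0), c(3.5, 0, 0))
  hg <- build_hetero_graph(pk, drug, model_config())
  # residue -> atom edge at distance 2: phi = exp(-2)
  row <- which(hg$edges_p2d[, 1] == 1 & hg$edges_p2d[, 2] == 1)
  expect_equal(hg$feat_p2d[row, "rbf"], exp(-2), tolerance = 1e-9,
               ignore_attr = TRUE)
  qn <- sqrt(rowSums(hg$feat_p2d[, 5:8]^2))
  expect_lt(max(abs(qn - 1)), 1e-6)
  expect_true(all(hg$feat_p2d[, "rbf"] > 0 & hg$feat_p2d[, "rbf"] <= 1))
  # co-located residue and atom: local coordinates zero, phi = 1
  drug0 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  hg0 <- build_hetero_graph(pk, drug0, model_config())
  r0 <- which(hg0$edges_p2d[, 2] == 1)
  expect_equal(as.numeric(hg0$feat_p2d[r0, 1:4]), c(0, 0, 0, 1))
})

test_that("edge counts satisfy the summation identity", {
  cx <- fix_complex()
  sa <- fix_aff_sample()
  hg <- sa$hetero
  k <- tiny_cfg()$k
  expect_equal(nrow(hg$edges_p2d), hg$n_pocket * min(k, hg$n_atoms))
  expect_equal(nrow(hg$edges_d2p), hg$n_atoms * min(k, hg$n_pocket))
})

test_that("features change when the ligand moves relative to the protein", {
  cx <- fix_complex()
  sa <- fix_aff_sample()
  pk <- extract_pocket(cx$protein,
                       cx$protein$residues[sa$pocket_indices, ])
  hg1 <- build_hetero_graph(pk, cx$drug$coords, tiny_cfg())
  hg2 <- build_hetero_graph(pk, sweep(cx$drug$coords, 2, c(3, 0, 0), "+"),
                            tiny_cfg())
  expect_gt(max(abs(hg1$feat_p2d - hg2$feat_p2d)), 1e-3)
})
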