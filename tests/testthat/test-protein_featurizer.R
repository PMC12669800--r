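make_single_residue <- function(n_xyz, ca_xyz, c_xyz) {
  at <- data.frame(chain = "A", resno = 1L, insert = "", resid = "ALA",
                   elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
                   x = c(n_xyz[1], ca_xyz[1], c_xyz[1]),
                   y = c(n_xyz[2], ca_xyz[2], c_xyz[2]),
                   z = c(n_xyz[3], ca_xyz[3], c_xyz[3]),
                   stringsAsFactors = FALSE)
  tribind:::build_structure(at)
}

test_that("residue frames match a Gram-Schmidt oracle on ideal geometry", {
  st <- make_single_residue(c(-1.458, 0, 0), c(0, 0, 0), c(0.55, 1.42, 0))
  fr <- build_residue_frames(st)[[1]]
  expect_equal(fr$origin, c(0, 0, 0))
  B <- fr$basis
  expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-10)
  expect_equal(det(B), 1, tolerance = 1e-10)
  # oracle: x along C-Ca, y = Gram-Schmidt of N-Ca against x
  xh <- c(0.55, 1.42, 0) / sqrt(0.55^2 + 1.42^2)
  yv <- c(-1.458, 0, 0)
  yv <- yv - sum(yv * xh) * xh
  yh <- yv / sqrt(sum(yv^2))
  expect_equal(as.numeric(B[1, ]), xh, tolerance = 1e-10)
  expect_equal(as.numeric(B[2, ]), yh, tolerance = 1e-10)
})

test_that("frames co-rotate with the structure", {
  st <- make_toy_protein(8, seed = 1)
  fr <- build_residue_frames(st)
  set.seed(5)
  R <- tribind:::random_rotation()
  st2 <- transform_structure(st, R, c(3, -2, 9))
  fr2 <- build_residue_frames(st2)
  for (i in seq_along(fr)) {
    expect_lt(max(abs(fr2[[i]]$basis - fr[[i]]$basis %*% t(R))), 1e-10)
  }
})

test_that("missing backbone atoms trigger an orthonormal fallback frame", {
  st <- make_toy_protein(5, seed = 2)
  st$atom <- st$atom[!(st$atom$res_index == 3 & st$atom$elety == "N"), ]
  expect_warning(fr <- build_residue_frames(st), "fallback")
  B <- fr[[3]]$basis
  expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-8)
  expect_equal(det(B), 1, tolerance = 1e-8)
})

test_that("contact edges obey the cutoff in both directions", {
  ca <- rbind(c(0, 0, 0), c(10, 0, 0))
  e <- build_residue_edges(ca, cutoff = 12)
  expect_equal(unname(e), rbind(c(1L, 2L), c(2L, 1L)))
  ca2 <- rbind(c(0, 0, 0), c(12.5, 0, 0))
  expect_equal(nrow(build_residue_edges(ca2, cutoff = 12)), 0L)
})

test_that("helix edge set equals a brute-force all-pairs scan", {
  st <- make_toy_protein(30, seed = 3)
  e <- build_residue_edges(st, cutoff = 12)
  brute <- NULL
  for (i in 1:30) for (j in 1:30) {
    if (i != j && sqrt(sum((st$ca[i, ] - st$ca[j, ])^2)) <= 12) {
      brute <- rbind(brute, c(i, j))
    }
  }
  brute <- brute[order(brute[, 1], brute[, 2]), ]
  expect_equal(unname(e), unname(brute))
})

test_that("relative quaternions are canonical and match rotation oracles", {
  f <- tribind:::make_frame(c(0, 0, 0), diag(3))
  expect_equal(relative_quaternion(f, f), c(1, 0, 0, 0))
  # frame rotated 180 degrees about its own z axis
  B2 <- rbind(-diag(3)[1, ], -diag(3)[2, ], diag(3)[3, ])
  f2 <- tribind:::make_frame(c(0, 0, 0), B2)
  expect_equal(relative_quaternion(f, f2), c(0, 0, 0, 1), tolerance = 1e-12)
  # arbitrary pair: unit norm, conjugate symmetry up to canonical sign
  set.seed(11)
  g1 <- tribind:::make_frame(c(0, 0, 0), tribind:::random_rotation())
  g2 <- tribind:::make_frame(c(0, 0, 0), tribind:::random_rotation())
  q12 <- relative_quaternion(g1, g2)
  q21 <- relative_quaternion(g2, g1)
  expect_equal(sqrt(sum(q12^2)), 1, tolerance = 1e-10)
  expect_equal(q21, tribind:::canonical_quat(tribind:::quat_conjugate(q12)),
               tolerance = 1e-10)
  bad <- tribind:::make_frame(c(0, 0, 0), diag(3) * 2)
  expect_error(relative_quaternion(bad, f), "orthonormal")
})

test_that("edge features evaluate the radial basis and local coordinates", {
  f1 <- tribind:::make_frame(c(0, 0, 0), diag(3))
  f2 <- tribind:::make_frame(c(1, 0, 0), diag(3))
  ca <- rbind(c(0, 0, 0), c(1, 0, 0))
  e <- rbind(c(1L, 2L), c(2L, 1L))
  feats <- compute_edge_features(list(f1, f2), ca, e, sigma = 1)
  expect_equal(feats[1, "rbf"], exp(-0.5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(as.numeric(feats[1, 1:3]), c(1, 0, 0))
  expect_equal(as.numeric(feats[1, 5:8]), c(1, 0, 0, 0))
  # co-located residues: phi = 1, local coordinates zero
  ca0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  feats0 <- compute_edge_features(list(f1, f1), ca0, e, sigma = 1)
  expect_equal(as.numeric(feats0[1, 1:4]), c(0, 0, 0, 1))
})

test_that("the radial basis is strictly decreasing with phi(0) = 1", {
  d <- seq(0, 15, by = 0.25)
  phi <- rbf_distance(d, sigma = 1)
  expect_equal(phi[1], 1)
  expect_true(all(diff(phi) < 0))
  expect_true(all(phi > 0 & phi <= 1))
})

test_that("edge features are invariant under 20 random rigid motions", {
  st <- make_toy_protein(12, seed = 6)
  fr <- build_residue_frames(st)
  e <- build_residue_edges(st)
  ref <- compute_edge_features(fr, st$ca, e)
  set.seed(20)
  for (k in 1:20) {
    R <- tribind:::random_rotation()
    st2 <- transform_structure(st, R, rnorm(3, 0, 20))
    fr2 <- build_residue_frames(st2)
    feats <- compute_edge_features(fr2, st2$ca, e)
    expect_lt(max(abs(feats - ref)), 1e-5)
  }
})

test_that("frames are orthonormal and right-handed on every fixture", {
  for (seed in 1:3) {
    st <- make_toy_protein(10 + 5 * seed, seed = seed)
    for (fr in build_residue_frames(st)) {
      expect_true(tribind:::frame_is_orthonormal(fr))
    }
  }
})

test_that("the stub embedder is deterministic, position-aware and bounded", {
  emb <- stub_embedder()
  m1 <- embed_sequence("ACD", emb)
  expect_equal(dim(m1), c(3L, 1024L))
  expect_identical(m1, embed_sequence("ACD", stub_embedder()))
  m2 <- embed_sequence("AA", emb)
  expect_gt(max(abs(m2[1, ] - m2[2, ])), 0.01)
  expect_true(all(abs(m1) <= 1))
  expect_error(embed_sequence("", emb), "nonempty")
})

test_that("residue graphs assemble aligned feature blocks", {
  g <- fix_site_sample()$pgraph
  expect_equal(nrow(g$node_features), g$n_residues)
  expect_equal(ncol(g$node_features), 1024L)
  expect_equal(nrow(g$surface_features), g$n_residues)
  expect_equal(nrow(g$edge_features), nrow(g$edges))
  # symmetry: every edge has its reverse, with equal distances
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev <- paste(g$edges[, 2], g$edges[, 1])
  expect_true(all(rev %in% key))
  # quaternion rows are unit-norm
  qn <- sqrt(rowSums(g$edge_features[, 5:8]^2))
  expect_lt(max(abs(qn - 1)), 1e-6)
})
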