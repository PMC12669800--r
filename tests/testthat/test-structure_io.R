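test_that("PDB round trip preserves residue count and Ca coordinates", {
  st <- make_toy_protein(20, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  st2 <- parse_protein_structure(f)
  expect_equal(n_residues(st2), 20L)
  expect_lt(max(abs(st2$ca - st$ca)), 1e-3)
  expect_equal(st2$residues$resid, st$residues$resid)
  expect_equal(st2$sequence, st$sequence)
})

test_that("residues lacking an alpha-carbon are dropped with a warning", {
  st <- make_toy_protein(10, seed = 2)
  drop_row <- which(st$atom$res_index == 5 & st$atom$elety == "CA")
  st$atom <- st$atom[-drop_row, ]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  expect_warning(st2 <- parse_protein_structure(f), "alpha-carbon")
  expect_equal(n_residues(st2), 9L)
  expect_false(5 %in% st2$residues$resno)
})

test_that("mmCIF and PDB renderings agree on Ca coordinates", {
  st <- make_toy_protein(15, seed = 3)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_structure_pdb(st, fp)
  write_structure_cif(st, fc)
  a <- parse_protein_structure(fp)
  b <- parse_protein_structure(fc)
  expect_equal(n_residues(a), n_residues(b))
  expect_lt(max(abs(a$ca - b$ca)), 1e-3)
})

test_that("unparseable and empty structure inputs raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(parse_protein_structure(f))
  expect_error(parse_protein_structure("/no/such/file.pdb"), "no such file")
})

test_that("SMILES parsing matches the reference toolkit on ethane", {
  mol <- parse_small_molecule("CC")
  expect_equal(nrow(mol$atoms), 2L)
  expect_equal(nrow(mol$bonds), 1L)
  expect_equal(mol$atoms$element, c("C", "C"))
  expect_equal(mol$atoms$degree, c(1L, 1L))
  expect_equal(mol$atoms$explicit_valence, c(1L, 1L))
  expect_equal(mol$atoms$implicit_valence, c(3L, 3L))
  expect_false(any(mol$atoms$aromatic))
  expect_false(any(mol$bonds$conjugated))
})

test_that("benzene is perceived aromatic with toolkit-matching valences", {
  mol <- parse_small_molecule("c1ccccc1")
  expect_equal(nrow(mol$atoms), 6L)
  expect_equal(nrow(mol$bonds), 6L)
  expect_true(all(mol$atoms$aromatic))
  expect_true(all(mol$bonds$aromatic))
  expect_true(all(mol$bonds$in_ring))
  expect_true(all(mol$bonds$conjugated))
  # frozen reference values (RDKit): deg 2, explicit 3, implicit 1
  expect_equal(mol$atoms$degree, rep(2L, 6))
  expect_equal(mol$atoms$explicit_valence, rep(3L, 6))
  expect_equal(mol$atoms$implicit_valence, rep(1L, 6))
})

test_that("SDF input keeps coordinates and the same graph as SMILES", {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", "c1ccccc1\n")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(strsplit(txt, "\n")[[1]], f)
  mol <- parse_small_molecule(f)
  ref <- parse_small_molecule("c1ccccc1")
  expect_equal(mol$atoms$element, ref$atoms$element)
  expect_equal(nrow(mol$bonds), nrow(ref$bonds))
  expect_false(is.null(mol$coords))
  expect_equal(dim(mol$coords), c(6L, 3L))
})

test_that("butadiene conjugation matches the reference toolkit", {
  mol <- parse_small_molecule("C=CC=C")
  # frozen RDKit reference: all three bonds conjugated, none in a ring
  expect_equal(nrow(mol$bonds), 3L)
  expect_true(all(mol$bonds$conjugated))
  expect_false(any(mol$bonds$in_ring))
  central <- mol$bonds[mol$bonds$order == 1, ]
  expect_equal(nrow(central), 1L)
})

test_that("invalid molecule input raises a parse error", {
  expect_error(parse_small_molecule("not_a_smiles(((("), "could not parse")
})

test_that("extract_pocket with the full selection is the identity", {
  st <- make_toy_protein(12, seed = 4)
  pk <- extract_pocket(st, st$residues)
  expect_equal(n_residues(pk), 12L)
  expect_equal(pk$ca, st$ca)
  expect_equal(pk$atom$elety, st$atom$elety)
  expect_equal(attr(pk, "parent_indices"), 1:12)
})

test_that("distance-rule pocket equals a brute-force scan", {
  cx <- fix_complex()
  idx <- pocket_by_distance(cx$protein, cx$drug$coords, radius = 8)
  # brute force: explicit double loop over atoms
  at <- cx$protein$atom
  hits <- c()
  for (r in seq_len(n_residues(cx$protein))) {
    rows <- which(at$res_index == r)
    found <- FALSE
    for (a in rows) {
      for (d in seq_len(nrow(cx$drug$coords))) {
        dd <- sqrt(sum((c(at$x[a], at$y[a], at$z[a]) -
                          cx$drug$coords[d, ])^2))
        if (dd <= 8) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, r)
  }
  expect_equal(idx, hits)
  pk <- extract_pocket(cx$protein, cx$protein$residues[idx, ])
  expect_equal(n_residues(pk), length(idx))
  # relative order and atom lists preserved
  expect_equal(pk$residues$resno, cx$protein$residues$resno[idx])
})

test_that("pocket selection errors name offending or empty selections", {
  st <- make_toy_protein(8, seed = 5)
  expect_error(extract_pocket(st, st$residues[0, ]), "empty")
  bad <- data.frame(chain = "A", resno = 99L, insert = "")
  expect_error(extract_pocket(st, bad), "A\\|99")
})

test_that("pocket selection files parse chain:resnum tokens", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "A:3", "A:5B", ""), f)
  sel <- read_pocket_selection(f)
  expect_equal(sel$resno, c(3L, 5L))
  expect_equal(sel$insert, c("", "B"))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("garbage line", f2)
  expect_error(read_pocket_selection(f2), "malformed")
})
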