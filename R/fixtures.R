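#' @title Synthetic fixtures: toy proteins, molecules, complexes
#' @description Deterministic generators for desk-scale testing and
#'   training: idealized helical proteins with N/Calpha/C backbones, random
#'   tree-like small molecules with 3D poses, planted binding sites
#'   (distance rule), and planted affinities (linear in contact count plus
#'   seeded noise). Fixtures do not emulate binding physics; they plant
#'   recoverable statistical structure.
#' @name synthetic_fixtures
NULL

HYDROPHOBIC <- c("L", "I", "V", "F", "W", "M")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## fixture constants, recorded in every manifest
FIXTURE_CONSTANTS <- list(
  helix_rise = 1.5,       # Å per residue
  helix_turn = 100,       # degrees per residue
  helix_radius = 2.3,     # Å
  r_bind = 5.0,           # Å: planted-site contact radius
  affinity_intercept = 4.0,
  affinity_slope = 0.02,  # p-affinity units per contact pair
  affinity_noise_sd = 0.1,
  site_letter_bias = 0.8  # P(hydrophobic letter | site residue)
)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate an idealized helical toy protein
#'
#' Alpha-helix geometry (rise 1.5 Å, 100 degrees per residue, radius
#' 2.3 Å) gives consecutive alpha-carbon separations of about 3.8 Å.
#' Backbone N and C atoms sit at fixed offsets in the local helix frame so
#' residue frames are always constructible; the sequence is drawn uniformly
#' from the 20 standard amino acids.
#'
#' @param n_residues number of residues (>= 4).
#' @param seed RNG seed (sequence only; geometry is deterministic).
#' @return a \code{tribind_structure}.
#' @export
make_toy_protein <- function(n_residues, seed = 1L) {
  if (n_residues < 4L) stop("toy protein needs at least 4 residues")
  cst <- FIXTURE_CONSTANTS
  i <- seq_len(n_residues)
  theta <- (i - 1) * cst$helix_turn * pi / 180
  ca <- cbind(cst$helix_radius * cos(theta),
              cst$helix_radius * sin(theta),
              (i - 1) * cst$helix_rise)
  dtheta <- cst$helix_turn * pi / 180
  tang <- cbind(-cst$helix_radius * sin(theta) * dtheta,
                cst$helix_radius * cos(theta) * dtheta,
                cst$helix_rise)
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-cos(theta), -sin(theta), 0)
  bin <- cbind(tang[, 2] * nrm[, 3] - tang[, 3] * nrm[, 2],
               tang[, 3] * nrm[, 1] - tang[, 1] * nrm[, 3],
               tang[, 1] * nrm[, 2] - tang[, 2] * nrm[, 1])
  n_off <- -0.7 * tang + 0.5 * nrm + 0.3 * bin
  n_off <- 1.46 * n_off / sqrt(rowSums(n_off^2))
  c_off <- 0.8 * tang + 0.4 * nrm - 0.3 * bin
  c_off <- 1.52 * c_off / sqrt(rowSums(c_off^2))
  letters_ <- with_seed(seed, sample(AA20, n_residues, replace = TRUE))
  resid3 <- bio3d::aa123(letters_)
  at <- data.frame(
    chain = "A",
    resno = rep(i, each = 3L),
    insert = "",
    resid = rep(resid3, each = 3L),
    elety = rep(c("N", "CA", "C"), n_residues),
    elesy = rep(c("N", "C", "C"), n_residues),
    x = as.numeric(t(cbind(ca[, 1] + n_off[, 1], ca[, 1], ca[, 1] + c_off[, 1]))),
    y = as.numeric(t(cbind(ca[, 2] + n_off[, 2], ca[, 2], ca[, 2] + c_off[, 2]))),
    z = as.numeric(t(cbind(ca[, 3] + n_off[, 3], ca[, 3], ca[, 3] + c_off[, 3]))),
    stringsAsFactors = FALSE)
  build_structure(at, source = sprintf("toy-helix-n%d-seed%d", n_residues, seed))
}

#' Generate a random tree-like toy molecule with a 3D pose
#'
#' Atoms (C/N/O) are attached one at a time to a random previous atom at
#' 1.5 Å bond length with clash rejection; occasional double bonds are
#' placed where both endpoints have spare valence.
#'
#' @param seed RNG seed.
#' @param n_atoms atom count (default drawn in 5..20).
#' @return a \code{tribind_molecule} with coordinates.
#' @export
make_toy_molecule <- function(seed = 1L, n_atoms = NULL) {
  with_seed(seed * 31L + 7L, {
    n <- if (is.null(n_atoms)) sample(5:20, 1L) else n_atoms
    elements <- sample(c("C", "N", "O"), n, replace = TRUE,
                       prob = c(0.7, 0.15, 0.15))
    maxv <- c(C = 4, N = 3, O = 2)[elements]
    coords <- matrix(0, n, 3L)
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
    used_val <- numeric(n)
    for (a in seq(2L, n)) {
      cand <- which(used_val[seq_len(a - 1L)] < maxv[seq_len(a - 1L)])
      if (!length(cand)) cand <- seq_len(a - 1L)
      parent <- if (length(cand) == 1L) cand else sample(cand, 1L)
      for (try in 1:25) {
        dir <- stats::rnorm(3)
        pos <- coords[parent, ] + 1.5 * dir / vnorm(dir)
        d <- sqrt(rowSums(sweep(coords[seq_len(a - 1L), , drop = FALSE],
                                2L, pos, "-")^2))
        if (all(d > 1.2)) break
      }
      coords[a, ] <- pos
      ord <- 1
      if (stats::runif(1) < 0.25 &&
          used_val[parent] + 2 <= maxv[parent] &&
          used_val[a] + 2 <= maxv[a]) {
        ord <- 2
      }
      bonds <- rbind(bonds, data.frame(i = parent, j = a, order = ord))
      used_val[parent] <- used_val[parent] + ord
      used_val[a] <- used_val[a] + ord
    }
    degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
    expl <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      expl[bonds$i[b]] <- expl[bonds$i[b]] + bonds$order[b]
      expl[bonds$j[b]] <- expl[bonds$j[b]] + bonds$order[b]
    }
    has_pi <- rep(FALSE, n)
    multi <- bonds$order >= 2
    has_pi[unique(c(bonds$i[multi], bonds$j[multi]))] <- TRUE
    new_molecule_record(
      atoms = data.frame(element = elements, degree = degree,
                         explicit_valence = as.integer(expl),
                         implicit_valence = as.integer(pmax(0, maxv - expl)),
                         aromatic = FALSE, stringsAsFactors = FALSE),
      bonds = data.frame(i = bonds$i, j = bonds$j, order = bonds$order,
                         aromatic = FALSE,
                         conjugated = has_pi[bonds$i] & has_pi[bonds$j],
                         in_ring = FALSE),
      coords = coords)
  })
}

#' Assemble a toy protein-drug complex with planted truth
#'
#' The drug is posed adjacent to a randomly chosen face of the helix. The
#' planted binding site is the set of residues with any atom within
#' \code{r_bind} = 5 Å of any drug atom (pose resampled if empty); site
#' residues receive hydrophobic-biased sequence letters, emulating the
#' compositional bias of real binding pockets so that sequence-derived
#' features carry site signal. The planted affinity is
#' \code{4.0 + 0.02 * n_contact_pairs + N(0, 0.1)}.
#'
#' @param seed RNG seed controlling everything in the complex.
#' @param n_residues protein length (default drawn in 30..60).
#' @param n_site_residues if given, the planted site is instead exactly the
#'   this-many residues nearest to the drug (rank-based planting, used for
#'   controlled class-imbalance fixtures).
#' @return list with \code{protein}, \code{drug}, \code{site} (0/1 vector),
#'   \code{affinity}, \code{contacts}, \code{seed}.
#' @export
make_toy_complex <- function(seed = 1L, n_residues = NULL,
                             n_site_residues = NULL) {
  cst <- FIXTURE_CONSTANTS
  n_res <- if (is.null(n_residues)) {
    with_seed(seed * 17L + 3L, sample(30:60, 1L))
  } else n_residues
  protein <- make_toy_protein(n_res, seed = seed)
  drug <- make_toy_molecule(seed = seed)
  pxyz <- as.matrix(protein$atom[, c("x", "y", "z")])
  with_seed(seed * 101L + 19L, {
    site <- integer(0)
    for (attempt in 1:50) {
      anchor <- sample(seq_len(n_res), 1L)
      ca <- protein$ca[anchor, ]
      outward <- unitize(c(ca[1], ca[2], 0))
      offset <- stats::runif(1, 4, 6)
      center <- ca + offset * outward
      pose <- sweep(drug$coords, 2L, colMeans(drug$coords), "-")
      R <- random_rotation()
      pose <- sweep(pose %*% t(R), 2L, center, "+")
      d2 <- outer(rowSums(pxyz^2), rep(1, nrow(pose))) -
        2 * pxyz %*% t(pose) +
        outer(rep(1, nrow(pxyz)), rowSums(pose^2))
      close_pair <- d2 <= cst$r_bind^2
      site <- sort(unique(protein$atom$res_index[rowSums(close_pair) > 0]))
      if (length(site) && min(d2) > 1.0) break
    }
    if (!length(site)) stop("could not pose drug against the helix")
    contacts <- sum(close_pair)
    if (!is.null(n_site_residues)) {
      agg <- tapply(sqrt(apply(d2, 1L, min)), protein$atom$res_index, min)
      res_min_d <- as.numeric(agg[match(seq_len(n_res),
                                        as.numeric(names(agg)))])
      site <- sort(order(res_min_d)[seq_len(n_site_residues)])
    }
    ## compositional bias: binding residues tend hydrophobic
    letters_ <- protein$residues$letter
    for (r in site) {
      letters_[r] <- if (stats::runif(1) < cst$site_letter_bias) {
        sample(HYDROPHOBIC, 1L)
      } else sample(AA20, 1L)
    }
    protein$residues$letter <- letters_
    resid3 <- bio3d::aa123(letters_)
    protein$residues$resid <- resid3
    protein$atom$resid <- resid3[protein$atom$res_index]
    protein$sequence <- vapply(split(letters_, protein$residues$chain),
                               paste0, character(1), collapse = "")
    affinity <- cst$affinity_intercept + cst$affinity_slope * contacts +
      stats::rnorm(1, 0, cst$affinity_noise_sd)
    site_vec <- integer(n_res)
    site_vec[site] <- 1L
    drug$coords <- pose
    list(protein = protein, drug = drug, site = site_vec,
         affinity = affinity, contacts = contacts, seed = seed)
  })
}

#' Featurize a toy complex for a task
#'
#' Builds the residue graph (full protein for occurrence/site; the
#' distance-rule pocket for affinity), the drug graph, and for affinity the
#' heterogeneous interface graph.
#'
#' @param complex from [make_toy_complex()] (or a list with the same
#'   fields).
#' @param task task name.
#' @param config a [model_config()].
#' @param embedder sequence embedder.
#' @param label optional label override (e.g. occurrence 0/1).
#' @return a featurized sample list.
#' @export
featurize_complex <- function(complex, task, config = model_config(),
                              embedder = stub_embedder(), label = NULL) {
  dgraph <- build_drug_graph(complex$drug)
  if (task == "affinity") {
    pidx <- pocket_by_distance(complex$protein, complex$drug$coords,
                               radius = config$pocket_radius)
    pocket <- extract_pocket(complex$protein,
                             complex$protein$residues[pidx, , drop = FALSE])
    pgraph <- build_residue_graph(pocket, embedder, config)
    hetero <- build_hetero_graph(pocket, complex$drug$coords, config)
    lab <- if (is.null(label)) complex$affinity else label
    return(list(pgraph = pgraph, dgraph = dgraph, hetero = hetero,
                label = lab, pocket_indices = pidx))
  }
  pgraph <- build_residue_graph(complex$protein, embedder, config)
  lab <- if (is.null(label)) {
    if (task == "site") complex$site else 1
  } else label
  list(pgraph = pgraph, dgraph = dgraph, label = lab)
}

#' Build a featurized toy dataset for a task
#'
#' Occurrence: half the pairs are matched complexes (label 1), half are
#' mismatched protein/drug combinations (label 0). Site: planted per-residue
#' labels. Affinity: planted p-affinities.
#'
#' @param task task name.
#' @param n number of pairs.
#' @param seed base seed; complex k uses seed + k.
#' @param config a [model_config()].
#' @param embedder sequence embedder.
#' @param n_residues,n_site_residues forwarded to [make_toy_complex()].
#' @return list of featurized samples.
#' @export
make_task_dataset <- function(task, n = 8L, seed = 0L,
                              config = model_config(),
                              embedder = stub_embedder(),
                              n_residues = NULL, n_site_residues = NULL) {
  samples <- vector("list", n)
  for (k in seq_len(n)) {
    cx <- make_toy_complex(seed + k, n_residues = n_residues,
                           n_site_residues = n_site_residues)
    if (task == "occurrence" && k > n / 2) {
      ## mismatched pair: this protein with an unrelated, unposed drug
      decoy <- make_toy_molecule(seed + k + 1000L)
      cx$drug <- decoy
      samples[[k]] <- featurize_complex(cx, task, config, embedder, label = 0)
    } else {
      samples[[k]] <- featurize_complex(cx, task, config, embedder)
    }
  }
  samples
}

#' Write a fixture set to disk
#'
#' Emits PDB and SDF files, a pairs table covering all three task payloads,
#' per-complex site label files, and a JSON manifest recording every
#' constant, seed and planted-truth rule.
#'
#' @param dir output directory (created).
#' @param seed base seed.
#' @param n number of complexes.
#' @return the manifest, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 0L, n = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    cx <- make_toy_complex(seed + k)
    pdb <- file.path(dir, sprintf("protein_%03d.pdb", k))
    sdf <- file.path(dir, sprintf("drug_%03d.sdf", k))
    labf <- file.path(dir, sprintf("site_%03d.txt", k))
    write_structure_pdb(cx$protein, pdb)
    write_molecule_sdf(cx$drug, sdf, name = sprintf("toy-%03d", k))
    res <- cx$protein$residues[cx$site == 1L, , drop = FALSE]
    writeLines(paste0(res$chain, ":", res$resno, res$insert), labf)
    rows[[k]] <- data.frame(
      pair_id = sprintf("pair_%03d", k),
      protein_path = basename(pdb),
      drug = basename(sdf),
      label = 1L,
      affinity_molar = 10^(-cx$affinity),
      measure = "Kd",
      label_file = basename(labf),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  utils::write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(FIXTURE_CONSTANTS,
                list(seed = seed, n_complexes = n,
                     site_rule = "residue has any atom within r_bind of any drug atom",
                     affinity_rule = "intercept + slope * n_contact_pairs + N(0, noise_sd)",
                     generator = "tribind::write_fixture_set"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
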