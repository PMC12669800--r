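#' @title Protein and small-molecule input handling
#' @description Readers and writers for the structural inputs: protein 3D
#'   structures (PDB / mmCIF, via bio3d), small molecules (SMILES / SDF, via
#'   ChemmineR + OpenBabel), pocket selections, and the internal records the
#'   featurizers consume.
#' @name structure_io
NULL

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF file into a residue-ordered protein record. Only
#' polymer ATOM records are kept (waters and heteroatoms are dropped);
#' alternate locations are resolved to the highest-occupancy conformer
#' (ties broken alphabetically, so 'A' wins); residues without a resolvable
#' alpha-carbon are dropped with a warning. Nonstandard residues that do
#' have an alpha-carbon are retained and typed "X" in the sequence so that
#' graph indices stay aligned with the structure.
#'
#' @param path file path; format chosen by extension (.cif/.mmcif vs PDB).
#' @param model_index which model of a multi-model file to use (default 1).
#' @return an object of class \code{tribind_structure}: a list with
#'   \code{atom} (per-atom table), \code{residues} (per-residue table with
#'   chain, number, insertion code, 3-letter type and 1-letter code),
#'   \code{ca} (N x 3 alpha-carbon coordinates, Å) and \code{sequence}
#'   (named per-chain 1-letter strings).
#' @export
parse_protein_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = model_index > 1L, verbose = FALSE)
    else bio3d::read.pdb(path, multi = model_index > 1L, verbose = FALSE),
    error = function(e) stop("failed to parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model_index) {
      stop("model_index ", model_index, " not present in file")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("structure contains no polymer ATOM records")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## resolve altlocs: highest occupancy first, then altloc id
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  keep <- !duplicated(key[ord])
  sel <- sort(seq_len(nrow(at))[ord][keep])
  at <- at[sel, , drop = FALSE]
  build_structure(at, source = path)
}

## assemble a tribind_structure from a bio3d-style atom table (file order)
build_structure <- function(at, source = NA_character_) {
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ridx <- match(rkey, unique(rkey))
  has_ca <- tapply(at$elety == "CA", ridx, any)
  if (!all(has_ca)) {
    drop <- which(!has_ca)
    warning(length(drop), " residue(s) lack an alpha-carbon and were dropped")
    keep <- ridx %in% which(has_ca)
    at <- at[keep, , drop = FALSE]
    rkey <- rkey[keep]
    ridx <- match(rkey, unique(rkey))
  }
  if (!nrow(at)) stop("no residues remain after alpha-carbon filtering")
  first <- !duplicated(ridx)
  residues <- data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resid = at$resid[first],
    stringsAsFactors = FALSE)
  residues$letter <- suppressWarnings(bio3d::aa321(residues$resid))
  residues$letter[is.na(residues$letter)] <- "X"
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ridx[at$elety == "CA"]), , drop = FALSE]
  ca_xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(ca_xyz) <- NULL
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- guess_element(at$elety)
  } else {
    miss <- is.na(elesy) | elesy == ""
    elesy[miss] <- guess_element(at$elety[miss])
  }
  atom <- data.frame(
    res_index = ridx,
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    elesy = normalize_element(elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  seqs <- vapply(split(residues$letter, residues$chain), paste0,
                 character(1), collapse = "")
  structure(list(atom = atom, residues = residues, ca = ca_xyz,
                 sequence = seqs, source = source),
            class = "tribind_structure")
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1L, 1L)
}

normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1L, 1L)),
         tolower(substr(x, 2L, nchar(x))))
}

#' @export
print.tribind_structure <- function(x, ...) {
  cat("tribind_structure:", nrow(x$residues), "residues,",
      nrow(x$atom), "atoms,", length(x$sequence), "chain(s)\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a \code{tribind_structure}.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Write a protein record to PDB
#'
#' @param structure a \code{tribind_structure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atom
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    elety = at$elety, eleno = seq_len(nrow(at)),
    elesy = toupper(at$elesy),
    o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Write a protein record to mmCIF
#'
#' Emits a minimal \code{atom_site} loop sufficient for round-tripping
#' coordinates through standard mmCIF readers.
#'
#' @inheritParams write_structure_pdb
#' @export
write_structure_cif <- function(structure, path) {
  at <- structure$atom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_tribind",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(at)), toupper(at$elesy), at$elety, at$resid, at$chain,
    at$resno, ifelse(at$insert == "", "?", at$insert),
    at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}

#' Extract a pocket sub-structure
#'
#' Returns a structure containing exactly the selected residues, in their
#' original order, with the mapping back to the parent's residue indices
#' kept in \code{attr(, "parent_indices")}.
#'
#' @param structure a \code{tribind_structure}.
#' @param selection a data.frame with columns chain, resno, insert, or a
#'   character vector of \code{"<chain>:<resnum><icode?>"} tokens.
#' @export
extract_pocket <- function(structure, selection) {
  sel <- as_residue_selection(selection)
  if (!nrow(sel)) stop("pocket selection is empty")
  skey <- paste(sel$chain, sel$resno, sel$insert, sep = "|")
  rkey <- paste(structure$residues$chain, structure$residues$resno,
                structure$residues$insert, sep = "|")
  idx <- match(skey, rkey)
  if (anyNA(idx)) {
    stop("selection names residue(s) absent from the structure: ",
         paste(skey[is.na(idx)], collapse = ", "))
  }
  idx <- sort(unique(idx))
  at <- structure$atom[structure$atom$res_index %in% idx, , drop = FALSE]
  at$res_index <- match(at$res_index, idx)
  out <- structure(list(
    atom = at,
    residues = structure$residues[idx, , drop = FALSE],
    ca = structure$ca[idx, , drop = FALSE],
    sequence = vapply(split(structure$residues$letter[idx],
                            structure$residues$chain[idx]),
                      paste0, character(1), collapse = ""),
    source = structure$source), class = "tribind_structure")
  rownames(out$residues) <- NULL
  attr(out, "parent_indices") <- idx
  out
}

as_residue_selection <- function(selection) {
  if (is.data.frame(selection)) {
    if (is.null(selection$insert)) selection$insert <- ""
    selection$insert[is.na(selection$insert)] <- ""
    return(selection[, c("chain", "resno", "insert")])
  }
  m <- regmatches(selection,
                  regexec("^\\s*([A-Za-z0-9]):(-?[0-9]+)([A-Za-z]?)\\s*$",
                          selection))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed residue token(s): ",
         paste(selection[bad], collapse = ", "))
  }
  data.frame(chain = vapply(m, `[`, "", 2L),
             resno = as.integer(vapply(m, `[`, "", 3L)),
             insert = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Read a pocket selection file
#'
#' One residue per line, formatted \code{<chain>:<resnum><icode?>};
#' blank lines and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return residue selection data.frame (chain, resno, insert).
#' @export
read_pocket_selection <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("pocket selection file is empty")
  as_residue_selection(ln)
}

## ---- small molecules ----------------------------------------------------

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)

#' Parse a small molecule from SMILES or SDF
#'
#' SMILES strings are converted through OpenBabel; SDF files are read
#' directly and keep their coordinates. Aromaticity is perceived from ring
#' analysis; implicit valences are filled from standard element valences.
#'
#' @param source a SMILES string, or a path to an SDF file.
#' @return an object of class \code{tribind_molecule}: a list with
#'   \code{atoms} (element, degree, explicit_valence, implicit_valence,
#'   aromatic), \code{bonds} (i, j, order, aromatic, conjugated, in_ring)
#'   and \code{coords} (N x 3 matrix for SDF input, else NULL).
#' @export
parse_small_molecule <- function(source) {
  from_file <- length(source) == 1L && file.exists(source) &&
    grepl("\\.(sdf|mol)$", source, ignore.case = TRUE)
  sdfset <- tryCatch({
    if (from_file) {
      ChemmineR::read.SDFset(source)
    } else {
      txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(source, "\n"))
      if (!nzchar(txt)) stop("conversion produced no output")
      methods::as(ChemmineR::read.SDFstr(strsplit(txt, "\n")[[1]]), "SDFset")
    }
  }, error = function(e) {
    stop("could not parse molecule input '",
         substr(paste(source, collapse = " "), 1, 60),
         "': ", conditionMessage(e))
  })
  if (!length(sdfset)) stop("molecule input '", source, "' yielded no molecule")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) stop("molecule has no atoms")
  element <- normalize_element(sub("_.*$", "", rownames(ab)))
  n <- nrow(ab)
  if (!is.null(bb) && nrow(bb) > 0L) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  if (nrow(bonds) && (any(bonds$i == bonds$j) ||
                      any(bonds$i < 1 | bonds$j < 1 |
                          bonds$i > n | bonds$j > n))) {
    stop("molecule has invalid bond endpoints")
  }
  ## ring and aromaticity perception
  in_ring_bond <- rep(FALSE, nrow(bonds))
  arom_atom <- rep(FALSE, n)
  if (nrow(bonds)) {
    rng <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    ring_sets <- lapply(rng$RINGS, function(r) {
      as.integer(sub("^.*_", "", r))
    })
    arom_flag <- rng$AROMATIC
    for (k in seq_along(ring_sets)) {
      r <- ring_sets[[k]]
      memb <- bonds$i %in% r & bonds$j %in% r
      in_ring_bond <- in_ring_bond | memb
      if (isTRUE(arom_flag[k])) arom_atom[r] <- TRUE
    }
  }
  arom_bond <- if (nrow(bonds)) {
    (arom_atom[bonds$i] & arom_atom[bonds$j] & in_ring_bond) | bonds$order == 4
  } else logical(0)
  ## valence bookkeeping (order 4 = delocalized aromatic, counts 1.5)
  ord_val <- ifelse(bonds$order == 4, 1.5, bonds$order)
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  expl <- rep(0, n)
  for (b in seq_len(nrow(bonds))) {
    expl[bonds$i[b]] <- expl[bonds$i[b]] + ord_val[b]
    expl[bonds$j[b]] <- expl[bonds$j[b]] + ord_val[b]
  }
  expl <- round(expl)
  defv <- DEFAULT_VALENCE[element]
  defv[is.na(defv)] <- 0
  impl <- pmax(0, defv - expl)
  ## conjugation: both endpoints carry pi electrons
  has_pi <- rep(FALSE, n)
  if (nrow(bonds)) {
    multi <- bonds$order >= 2 | arom_bond
    has_pi[unique(c(bonds$i[multi], bonds$j[multi]))] <- TRUE
  }
  conj <- if (nrow(bonds)) arom_bond | (has_pi[bonds$i] & has_pi[bonds$j])
          else logical(0)
  coords <- NULL
  if (from_file) {
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  }
  new_molecule_record(
    atoms = data.frame(element = element, degree = degree,
                       explicit_valence = as.integer(expl),
                       implicit_valence = as.integer(impl),
                       aromatic = arom_atom, stringsAsFactors = FALSE),
    bonds = data.frame(i = bonds$i, j = bonds$j,
                       order = ifelse(bonds$order == 4, 1.5, bonds$order),
                       aromatic = arom_bond, conjugated = conj,
                       in_ring = in_ring_bond),
    coords = coords)
}

#' Construct a molecule record directly
#'
#' Validates the atom/bond tables; used by the parser and by the synthetic
#' fixture generator.
#' @param atoms atom table (element, degree, explicit_valence,
#'   implicit_valence, aromatic).
#' @param bonds bond table (i, j, order, aromatic, conjugated, in_ring).
#' @param coords optional N x 3 coordinate matrix (Å).
#' @export
new_molecule_record <- function(atoms, bonds, coords = NULL) {
  n <- nrow(atoms)
  if (n < 1L) stop("molecule must contain at least one atom")
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop("molecule contains a self-bond")
    if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > n | bonds$j > n)) {
      stop("bond endpoints index atoms outside the molecule")
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L) {
      stop("coords must be an N x 3 matrix matching the atom count")
    }
  }
  structure(list(atoms = atoms, bonds = bonds, coords = coords),
            class = "tribind_molecule")
}

#' @export
print.tribind_molecule <- function(x, ...) {
  cat("tribind_molecule:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds",
      if (!is.null(x$coords)) "(with 3D coordinates)" else "", "\n")
  invisible(x)
}

#' Write a molecule record to an SDF (V2000) file
#'
#' @param mol a \code{tribind_molecule} with coordinates.
#' @param path output file.
#' @param name molecule title line.
#' @export
write_molecule_sdf <- function(mol, path, name = "tribind") {
  coords <- mol$coords
  if (is.null(coords)) coords <- matrix(0, nrow(mol$atoms), 3L)
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  lines <- c(name, "  tribind", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            coords[, 1], coords[, 2], coords[, 3],
                            mol$atoms$element))
  if (m) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i,
                              mol$bonds$j, as.integer(round(mol$bonds$order))))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
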