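# Structure input/output: PDB complexes, MDL MOL/SDF, SMILES.
# bio3d parses ATOM/HETATM records; CONECT records (which bio3d does not
# expose) are read from the raw lines. MOL/SDF parsing goes through
# ChemmineR; SMILES generation through ChemmineOB (OpenBabel).

#' Default HETATM exclusion set
#'
#' Waters, common cryo/buffer components and ions that should not be
#' treated as binding-site-defining ligands.
#' @return Character vector of residue names.
#' @export
default_exclusions <- function() {
  c("HOH", "DOD", "WAT", "SO4", "GOL", "PEG", "EDO", "PO4", "ACT", "DMS",
    "FMT", "NO3", "MPD", "TRS", "NA", "K", "CL", "MG", "CA", "ZN", "MN",
    "FE", "NI", "CU", "CO", "CD", "IOD", "BR")
}

normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

# element from a PDB atom name when the element column is blank
element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("CL", "BR", "SI", "SE", "FE", "ZN", "MG", "MN", "NA"))
    return(normalize_element(two))
  toupper(substr(nm, 1, 1))
}

read_conect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- lines[startsWith(lines, "CONECT")]
  if (length(cl) == 0L) return(NULL)
  out <- list()
  for (l in cl) {
    fields <- c(substr(l, 7, 11), substr(l, 12, 16), substr(l, 17, 21),
                substr(l, 22, 26), substr(l, 27, 31))
    v <- suppressWarnings(as.integer(fields))
    v <- v[!is.na(v)]
    if (length(v) >= 2L)
      for (p in v[-1]) out[[length(out) + 1L]] <- c(v[1], p)
  }
  if (length(out) == 0L) return(NULL)
  m <- do.call(rbind, out)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  unique(m)
}

# distance-based bond perception: bond iff d <= 1.25 * (rcov_i + rcov_j)
perceive_bonds_by_distance <- function(elements, coords, factor = 1.25) {
  n <- length(elements)
  if (n < 2L)
    return(data.frame(i = integer(), j = integer(), order = character()))
  rc <- covalent_radius(elements)
  d <- as.matrix(stats::dist(coords))
  lim <- outer(rc, rc, `+`) * factor
  hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
             order = rep("1", nrow(hit)))
}

#' Read a holo protein-ligand complex from a PDB file
#'
#' Protein `ATOM` records and each `HETATM` residue group (one group = one
#' ligand) are parsed; groups whose residue name is in `exclusions` are
#' dropped. Ligand bonds come from `CONECT` records when present, otherwise
#' they are perceived from interatomic distances against covalent-radius
#' sums. Ligands are returned typed (see [perceive_and_type()]).
#'
#' @param path PDB file.
#' @param exclusions Residue names never treated as ligands.
#' @return An object of class `iso_complex` with fields `protein`
#'   (data frame of protein atoms with residue ids), `ligands` (list of
#'   [iso_mol()]) and `name`.
#' @export
read_pdb_complex <- function(path, exclusions = default_exclusions()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (length(rec) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  for (ln in rec) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54))))))
      stop(sprintf("unparsable coordinate record at line %d of %s", ln, path),
           call. = FALSE)
  }

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | elem == ""
  elem[!blank] <- normalize_element(elem[!blank])
  elem[blank] <- vapply(at$elety[blank], element_from_name, character(1))
  at$element <- elem

  prot <- at[at$type == "ATOM", , drop = FALSE]
  protein <- data.frame(
    element = prot$element, x = prot$x, y = prot$y, z = prot$z,
    atom_name = prot$elety, chain = prot$chain, resno = prot$resno,
    resid = prot$resid, insert = prot$insert, stringsAsFactors = FALSE
  )
  rid <- paste(protein$chain, protein$resno, protein$insert)
  if (nrow(protein) > 0L) {
    # residue ids must be unique per (chain, number, insertion code)
    dup <- tapply(protein$resid, rid, function(r) length(unique(r)) > 1L)
    if (any(dup))
      stop("conflicting residue names for residue id(s): ",
           paste(names(dup)[dup], collapse = ", "), call. = FALSE)
  }

  het <- at[at$type == "HETATM" & !(at$resid %in% exclusions), , drop = FALSE]
  conect <- read_conect(path)
  ligands <- list()
  if (nrow(het) > 0L) {
    grp <- paste(het$chain, het$resno, het$resid, het$insert)
    for (g in unique(grp)) {
      sub <- het[grp == g, , drop = FALSE]
      if (!any(sub$element != "H")) next
      coords <- as.matrix(sub[, c("x", "y", "z")])
      bonds <- NULL
      if (!is.null(conect)) {
        keep <- conect[, 1] %in% sub$eleno & conect[, 2] %in% sub$eleno
        if (any(keep)) {
          idx <- match(conect[keep, , drop = FALSE], sub$eleno)
          m <- matrix(idx, ncol = 2)
          bonds <- data.frame(i = m[, 1], j = m[, 2],
                              order = rep("1", nrow(m)))
        }
      }
      if (is.null(bonds))
        bonds <- perceive_bonds_by_distance(sub$element, coords)
      m <- perceive_aromatic_rings(iso_mol(sub$element, coords, bonds,
                   name = trimws(paste(sub$resid[1], sub$chain[1],
                                       sub$resno[1])),
                   source = list(file = path, ligand = sub$resid[1],
                                 chain = sub$chain[1], resno = sub$resno[1])))
      ligands[[length(ligands) + 1L]] <- perceive_and_type(m)
    }
  }
  if (length(ligands) == 0L)
    stop("no ligands remain after applying the exclusion set in ", path,
         call. = FALSE)
  structure(list(protein = protein, ligands = ligands,
                 name = sub("\\.(pdb|ent)$", "", basename(path)),
                 source = path),
            class = "iso_complex")
}

#' @export
print.iso_complex <- function(x, ...) {
  cat(sprintf("<iso_complex> %s: %d protein atoms, %d ligand(s): %s\n",
              x$name, nrow(x$protein), length(x$ligands),
              paste(vapply(x$ligands, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Extract the binding site of a ligand
#'
#' The binding site is the set of protein residues having at least one
#' heavy atom within `cutoff` Angstrom (closed interval) of any ligand
#' heavy atom.
#'
#' @param complex An `iso_complex`.
#' @param ligand A ligand of the complex: an index into `complex$ligands`
#'   or the [iso_mol()] itself.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return Object of class `iso_site` with fields `residues`, `atoms`
#'   (protein atoms of those residues), `ligand` and `cutoff`.
#' @export
extract_binding_site <- function(complex, ligand = 1L, cutoff = 5.0) {
  stopifnot(inherits(complex, "iso_complex"), cutoff > 0)
  if (inherits(ligand, "iso_mol")) {
    pos <- which(vapply(complex$ligands, function(l)
      identical(l$name, ligand$name), logical(1)))
    if (length(pos) == 0L) stop("ligand does not belong to this complex",
                                call. = FALSE)
    lig <- ligand
  } else {
    lig <- complex$ligands[[ligand]]
  }
  prot <- complex$protein
  ph <- prot[prot$element != "H", , drop = FALSE]
  lxyz <- mol_coords(lig)[heavy_idx(lig), , drop = FALSE]
  if (nrow(ph) == 0L) stop("complex has no protein atoms", call. = FALSE)
  pxyz <- as.matrix(ph[, c("x", "y", "z")])
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), `+`) -
    2 * pxyz %*% t(lxyz)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  near <- mind <= cutoff
  if (!any(near)) stop("no residue within ", cutoff,
                       " A of the ligand (empty site)", call. = FALSE)
  rid_all <- paste(prot$chain, prot$resno, prot$insert)
  rid_heavy <- paste(ph$chain, ph$resno, ph$insert)
  keep_rid <- unique(rid_heavy[near])
  atoms <- prot[rid_all %in% keep_rid, , drop = FALSE]
  res <- unique(atoms[, c("chain", "resno", "resid", "insert")])
  rownames(res) <- rownames(atoms) <- NULL
  structure(list(residues = res, atoms = atoms, ligand = lig,
                 cutoff = cutoff),
            class = "iso_site")
}

#' @export
print.iso_site <- function(x, ...) {
  cat(sprintf("<iso_site> %d residues within %.1f A of %s\n",
              nrow(x$residues), x$cutoff, x$ligand$name))
  invisible(x)
}

# ---- MDL MOL / SDF ----------------------------------------------------

mol_to_molblock <- function(mol) {
  ord <- c(`1` = 1L, `2` = 2L, `3` = 3L, ar = 4L)
  nb <- nrow(mol$bonds)
  lines <- c(
    if (nzchar(mol$name)) mol$name else "molecule",
    "  isoswap",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms(mol), nb)
  )
  for (a in seq_len(n_atoms(mol)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              mol$atoms$x[a], mol$atoms$y[a], mol$atoms$z[a],
                              mol$atoms$element[a]))
  if (nb > 0L)
    for (k in seq_len(nb))
      lines <- c(lines, sprintf("%3d%3d%3d  0",
                                mol$bonds$i[k], mol$bonds$j[k],
                                ord[[mol$bonds$order[k]]]))
  lines <- c(lines, "M  END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a molecule as an MDL MOL (V2000) file
#' @param mol An [iso_mol()].
#' @param path Output file; when `NULL` the MOL block is returned as text.
#' @return `path` (invisibly) or the MOL block text.
#' @export
write_mol <- function(mol, path = NULL) {
  block <- mol_to_molblock(mol)
  if (is.null(path)) return(block)
  writeLines(sub("\n$", "", block), path)
  invisible(path)
}

#' Read a molecule from an MDL MOL/SDF file
#'
#' The first record of the file is parsed with ChemmineR and returned as a
#' typed [iso_mol()]. Bond order 4 is read as aromatic.
#'
#' @param path MOL or SDF file (or a character scalar containing a MOL
#'   block when `text = TRUE`).
#' @param text Treat `path` as MOL block text.
#' @return A typed [iso_mol()].
#' @export
read_mol <- function(path, text = FALSE) {
  if (text) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    writeLines(sub("\n$", "", paste0(path, if (!grepl("\\$\\$\\$\\$", path)) "\n$$$$" else "")), tf)
    path <- tf
  }
  sdfset <- ChemmineR::read.SDFset(path)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- normalize_element(sub("_\\d+$", "", rownames(ab)))
  coords <- ab[, 1:3, drop = FALSE]
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  } else {
    omap <- c("1", "2", "3", "ar")
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = omap[as.integer(bb[, 3])])
  }
  nm <- ChemmineR::sdfid(sdf)
  m <- iso_mol(elements, coords, bonds,
               name = if (length(nm) && nzchar(nm)) nm else "molecule",
               source = list(file = if (text) NA_character_ else path))
  perceive_and_type(aromatize_kekule(m))
}

# ---- SMILES -----------------------------------------------------------

#' Canonical SMILES of a molecule
#'
#' Canonicalization is delegated to OpenBabel, so the output is invariant
#' under atom-order permutation of the input.
#'
#' @param mol A typed [iso_mol()].
#' @return Canonical SMILES string.
#' @export
to_smiles <- function(mol) {
  block <- mol_to_molblock(mol)
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(block, "$$$$\n"))
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

#' Read a molecule from a SMILES string
#'
#' @param smiles SMILES string.
#' @param name Molecule name.
#' @param gen3d Generate 3D coordinates with OpenBabel (slower); otherwise
#'   atoms carry zero coordinates, which is sufficient for purely
#'   topological operations such as fragmentation.
#' @return A typed [iso_mol()].
#' @export
read_smiles <- function(smiles, name = "query", gen3d = FALSE) {
  opts <- data.frame(names = if (gen3d) "gen3D" else character(0),
                     args = if (gen3d) "" else character(0))
  sdf <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste0(smiles, " ", name, "\n"),
                                   options = opts)
  m <- read_mol(sdf, text = TRUE)
  m$name <- name
  m
}
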