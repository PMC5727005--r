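# Deterministic synthetic fixtures: idealized ligands, congruent 6-residue
# pockets, and complex pairs with a planted bioisosteric fragment overlap,
# so the whole mining pipeline is testable without any external structure.

ring_xy <- function(n, radius, center = c(0, 0, 0), start = 0) {
  ang <- start + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

ring_bonds <- function(n, order = "ar", offset = 0L) {
  data.frame(i = offset + seq_len(n),
             j = offset + c(seq_len(n - 1L) + 1L, 1L),
             order = order)
}

make_benzothiophene <- function() {
  # benzo hexagon centered at origin; thiophene fused on the edge at
  # x = 1.204 (regular pentagon of the same 1.39 A side)
  hexv <- ring_xy(6, 1.39, start = -pi / 6)  # vertices at -30,30,...
  # hexv rows: angles -30 (C7a), 30 (C3a), 90, 150, 210, 270
  rp <- 1.39 / (2 * sin(pi / 5))
  ctr <- c(1.2037 + rp * cos(pi / 5), 0, 0)
  pent <- function(a) c(ctr[1] + rp * cos(a), ctr[2] + rp * sin(a), 0)
  coords <- rbind(
    pent(-2 * pi / 5),   # S1
    pent(0),             # C2
    pent(2 * pi / 5),    # C3
    hexv[2, ],           # C3a (30 deg)
    hexv[3, ],           # C4
    hexv[4, ],           # C5
    hexv[5, ],           # C6
    hexv[6, ],           # C7
    hexv[1, ]            # C7a (-30 deg)
  )
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 4),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 1, 9),
    order = "ar")
  list(elements = c("S", rep("C", 8)), coords = coords, bonds = bonds)
}

make_murf_mock <- function() {
  bt <- make_benzothiophene()
  n0 <- length(bt$elements)            # 9; C2 is atom 2
  c2 <- bt$coords[2, ]
  s  <- c2 + c(1.77, 0, 0)             # sulfonyl S
  o1 <- s + c(0.24, 1.16, 0.80)
  o2 <- s + c(0.24, -1.16, 0.80)
  n  <- s + c(1.60, 0, 0)              # sulfonamide N
  ringc <- n + c(2.80, 0, 0)           # dichlorophenyl center
  ph <- ring_xy(6, 1.39, center = ringc, start = pi)  # C1' at 180 deg
  cl1 <- ph[2, ] + 1.72 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  cl2 <- ph[3, ] + 1.72 * c(cos(pi / 3), sin(pi / 3), 0)
  nmo <- ph[4, ] + c(1.41, 0, 0)       # morpholine N on C4'
  moc <- nmo + c(1.45, 0, 0)
  mo <- ring_xy(6, 1.45, center = moc, start = pi)  # N at 180, O at 0
  elements <- c(bt$elements, "S", "O", "O", "N", rep("C", 6),
                "Cl", "Cl", "N", "C", "C", "O", "C", "C")
  coords <- rbind(bt$coords, s, o1, o2, n, ph, cl1, cl2,
                  mo[1, ], mo[2, ], mo[3, ], mo[4, ], mo[5, ], mo[6, ])
  iS <- n0 + 1L; iO1 <- n0 + 2L; iO2 <- n0 + 3L; iN <- n0 + 4L
  iph <- n0 + 4L + seq_len(6)          # C1'..C6'
  icl <- n0 + 10L + 1:2
  imo <- n0 + 12L + seq_len(6)         # N, C, C, O, C, C
  bonds <- rbind(
    bt$bonds,
    data.frame(i = c(2, iS, iS, iS, iN, iph[2], iph[3], iph[4],
                     imo[1], imo[2], imo[3], imo[4], imo[5], imo[6]),
               j = c(iS, iO1, iO2, iN, iph[1], icl[1], icl[2], imo[1],
                     imo[2], imo[3], imo[4], imo[5], imo[6], imo[1]),
               order = c("1", "2", "2", "1", "1", "1", "1", "1",
                         rep("1", 6))),
    ring_bonds(6, "ar", offset = n0 + 4L)
  )
  list(elements = elements, coords = coords, bonds = bonds)
}

.TEMPLATES <- list(
  benzene = function() list(
    elements = rep("C", 6), coords = ring_xy(6, 1.39),
    bonds = ring_bonds(6, "ar")),
  pyridine = function() list(
    elements = c("N", rep("C", 5)), coords = ring_xy(6, 1.39),
    bonds = ring_bonds(6, "ar")),
  cyclohexane = function() list(
    elements = rep("C", 6), coords = ring_xy(6, 1.52),
    bonds = ring_bonds(6, "1")),
  morpholine = function() list(
    elements = c("O", "C", "C", "N", "C", "C"),
    coords = ring_xy(6, 1.45),
    bonds = ring_bonds(6, "1")),
  thiophene = function() list(
    elements = c("S", rep("C", 4)), coords = ring_xy(5, 1.2),
    bonds = ring_bonds(5, "ar")),
  biphenyl = function() {
    a <- ring_xy(6, 1.39)                                   # vertex 1 at x=1.39
    b <- ring_xy(6, 1.39, center = c(4.26, 0, 0), start = pi)
    list(elements = rep("C", 12), coords = rbind(a, b),
         bonds = rbind(ring_bonds(6, "ar"), ring_bonds(6, "ar", 6L),
                       data.frame(i = 1, j = 7, order = "1")))
  },
  ethylbenzene = function() {
    a <- ring_xy(6, 1.39)
    list(elements = rep("C", 8),
         coords = rbind(a, c(2.89, 0, 0), c(3.64, 1.30, 0)),
         bonds = rbind(ring_bonds(6, "ar"),
                       data.frame(i = c(1, 7), j = c(7, 8), order = "1")))
  },
  propylbenzene = function() {
    a <- ring_xy(6, 1.39)
    list(elements = rep("C", 9),
         coords = rbind(a, c(2.89, 0, 0), c(3.64, 1.30, 0),
                        c(5.14, 1.32, 0)),
         bonds = rbind(ring_bonds(6, "ar"),
                       data.frame(i = c(1, 7, 8), j = c(7, 8, 9),
                                  order = "1")))
  },
  sulfonamide = function() list(
    # ethyl-SO2-NH-ethyl: the sulfonyl sits between two rotatable bonds
    elements = c("C", "C", "S", "O", "O", "N", "C", "C"),
    coords = rbind(c(-3.30, 1.25, 0), c(-1.80, 1.25, 0), c(0, 0, 0),
                   c(0.24, 1.16, 0.80), c(0.24, -1.16, 0.80),
                   c(1.60, 0, 0), c(2.35, 1.25, 0), c(3.85, 1.25, 0)),
    bonds = data.frame(i = c(1, 2, 3, 3, 3, 6, 7),
                       j = c(2, 3, 4, 5, 6, 7, 8),
                       order = c("1", "1", "2", "2", "1", "1", "1"))),
  benzothiophene = make_benzothiophene,
  murf_mock = make_murf_mock
)

#' Built-in ligand template names
#' @return Character vector.
#' @export
ligand_templates <- function() names(.TEMPLATES)

#' Build an idealized ligand from a built-in template
#'
#' Output is a pure function of `(template, transform, seed)`: identical
#' arguments give bit-identical coordinates.
#'
#' @param template One of [ligand_templates()].
#' @param transform Optional [iso_transform()] applied to the idealized
#'   coordinates.
#' @param seed Recorded in the molecule's provenance (the templates are
#'   deterministic; the seed does not perturb geometry).
#' @return A typed [iso_mol()].
#' @export
make_ligand <- function(template, transform = NULL, seed = 0L) {
  f <- .TEMPLATES[[template]]
  if (is.null(f))
    stop("unknown ligand template: ", template, " (see ligand_templates())",
         call. = FALSE)
  spec <- f()
  m <- iso_mol(spec$elements, spec$coords, spec$bonds, name = template,
               source = list(template = template, seed = seed))
  m <- perceive_and_type(m)
  if (!is.null(transform)) m <- transpose_ligand(m, transform)
  m
}

# ---- pockets and complexes -------------------------------------------

# residue templates: local atom offsets (centroid near origin) + names
.RES_ATOMS <- list(
  PHE = list(names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             elements = rep("C", 6), coords = ring_xy(6, 1.39)),
  SER = list(names = c("CB", "OG"), elements = c("C", "O"),
             coords = rbind(c(-1.43, 0, 0), c(0, 0, 0))),
  LEU = list(names = c("CB", "CG", "CD1", "CD2"),
             elements = rep("C", 4),
             coords = rbind(c(-0.8, 1.2, 0), c(0, 0, 0),
                            c(1.4, 0.5, 0), c(-0.4, -1.4, 0.4))),
  LYS = list(names = c("CE", "NZ"), elements = c("C", "N"),
             coords = rbind(c(-1.48, 0, 0), c(0, 0, 0))),
  ASP = list(names = c("CG", "OD1", "OD2"), elements = c("C", "O", "O"),
             coords = rbind(c(0, 0, 0), c(0.6, 1.1, 0), c(0.6, -1.1, 0))),
  HIS = list(names = c("CG", "ND1", "CD2", "CE1", "NE2"),
             elements = c("C", "N", "C", "C", "N"),
             coords = ring_xy(5, 1.15))
)

# a 6-residue pocket on a sphere of radius ~6 A around the origin,
# geometry a pure function of the seed
make_pocket <- function(seed, residues = c("PHE", "SER", "LEU", "LYS",
                                           "ASP", "HIS"),
                        radius = 5.0) {
  rng <- local_rng(seed)
  on.exit(rng())
  rows <- list()
  for (r in seq_along(residues)) {
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    ctr <- dirv * (radius + stats::runif(1, -0.4, 0.4))
    rot <- random_rotation()
    tpl <- .RES_ATOMS[[residues[r]]]
    xyz <- sweep(tpl$coords %*% t(rot), 2L, ctr, `+`)
    rows[[r]] <- data.frame(
      element = tpl$elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      atom_name = tpl$names, chain = "A", resno = r,
      resid = residues[r], insert = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# save/restore the global RNG state around seeded fixture generation
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# assemble an iso_complex in memory
fixture_complex <- function(name, protein, ligands) {
  structure(list(protein = protein, ligands = ligands, name = name,
                 source = NA_character_),
            class = "iso_complex")
}

#' Write a complex as a PDB file
#'
#' Protein atoms as `ATOM` records, ligands as `HETATM` groups with
#' `CONECT` records for their bonds.
#'
#' @param complex An `iso_complex`.
#' @param path Output file.
#' @export
write_pdb_complex <- function(complex, path) {
  lines <- character(0)
  serial <- 0L
  fmt <- function(rec, serial, name, resid, chain, resno, x, y, z, el) {
    sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, resid, chain, resno, x, y, z, toupper(el))
  }
  p <- complex$protein
  for (r in seq_len(nrow(p))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, p$atom_name[r], p$resid[r],
                          p$chain[r], p$resno[r], p$x[r], p$y[r], p$z[r],
                          p$element[r]))
  }
  conect <- character(0)
  for (li in seq_along(complex$ligands)) {
    lig <- complex$ligands[[li]]
    base <- serial
    for (a in seq_len(n_atoms(lig))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial,
                            paste0(substr(lig$atoms$element[a], 1, 1), a),
                            "LIG", "A",
                            900L + li, lig$atoms$x[a], lig$atoms$y[a],
                            lig$atoms$z[a], lig$atoms$element[a]))
    }
    if (nrow(lig$bonds) > 0L)
      conect <- c(conect, sprintf("CONECT%5d%5d", base + lig$bonds$i,
                                  base + lig$bonds$j))
  }
  writeLines(c(lines, conect, "END"), path)
  invisible(path)
}

#' Generate a planted complex pair with ground truth
#'
#' Two complexes share a congruent 6-residue pocket; the second is rigidly
#' moved by a random transform. The ligands are placed so the designated
#' fragment pair (the benzene cores of the default ligands) coincides up
#' to a displacement of `planted_overlap` Angstrom once the second complex
#' is aligned back onto the first. Everything is a pure function of
#' `pocket_seed`.
#'
#' @param pocket_seed Integer seed.
#' @param ligA,ligB Ligand template names (defaults `"ethylbenzene"` and
#'   `"propylbenzene"`, whose ring-plus-join fragments coincide exactly).
#' @param planted_overlap Displacement of the planted fragment in Angstrom.
#' @param dir Directory for the two PDB files (`NULL` for none).
#' @return List with the in-memory complexes (`complex_a`, `complex_b`),
#'   file paths (when written), and `truth`: the expected B-to-A
#'   [iso_transform()], the planted fragment pair's core keys, the planted
#'   HD bound, and the recommended `site_cutoff` for mining.
#' @export
make_complex_pair <- function(pocket_seed, ligA = "ethylbenzene",
                              ligB = "propylbenzene", planted_overlap = 0,
                              dir = NULL) {
  stopifnot(planted_overlap >= 0)
  pocket <- make_pocket(pocket_seed)
  la <- make_ligand(ligA)
  lb <- make_ligand(ligB,
                    transform = iso_transform(diag(3),
                                              c(0, 0, planted_overlap)))
  rng <- local_rng(pocket_seed + 1000003L)
  tB <- iso_transform(random_rotation(),
                      stats::rnorm(3, 0, 2) + c(20, 0, 0))
  rng()

  cxa <- fixture_complex(sprintf("cpx%da", pocket_seed), pocket, list(la))
  pb <- pocket
  pxyz <- apply_transform(tB, as.matrix(pb[, c("x", "y", "z")]))
  pb[, c("x", "y", "z")] <- pxyz
  cxb <- fixture_complex(sprintf("cpx%db", pocket_seed), pb,
                         list(transpose_ligand(lb, tB)))

  fa <- fragment_molecule(la)
  fb <- fragment_molecule(lb)
  truth <- list(
    transform = invert_transform(tB),
    query_core_key = core_key(fa[[1]]),
    partner_core_key = core_key(fb[[1]]),
    planted_overlap = planted_overlap,
    hd_bound = planted_overlap + 0.3,
    site_cutoff = 5.0 + planted_overlap
  )
  out <- list(complex_a = cxa, complex_b = cxb, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path_a <- file.path(dir, paste0(cxa$name, ".pdb"))
    out$path_b <- file.path(dir, paste0(cxb$name, ".pdb"))
    write_pdb_complex(cxa, out$path_a)
    write_pdb_complex(cxb, out$path_b)
  }
  out
}

#' Write a complete fixture set to a directory
#'
#' Emits the PDB pair, the two ligands as SDF, a `families.tsv` SCOP
#' mapping (both complexes assigned the same family) and a
#' `ground_truth.json` with the expected transform and planted pair.
#'
#' @param dir Output directory.
#' @param seed Pocket seed.
#' @param planted_overlap Planted fragment displacement in Angstrom.
#' @return The directory, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 7L, planted_overlap = 0) {
  pair <- make_complex_pair(seed, planted_overlap = planted_overlap,
                            dir = dir)
  write_mol(pair$complex_a$ligands[[1]],
            file.path(dir, "ligand_a.mol"))
  write_mol(pair$complex_b$ligands[[1]],
            file.path(dir, "ligand_b.mol"))
  utils::write.table(
    data.frame(pdb_id = c(pair$complex_a$name, pair$complex_b$name),
               chain = "A", family = "FIX.FAM.1"),
    file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- pair$truth
  truth$transform <- transform_to_numbers(truth$transform)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
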