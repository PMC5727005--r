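#' Construct a small molecule
#'
#' The central container of the package: a set of atoms with 3D coordinates
#' and a bond list. Perception (`perceive_and_type()`) fills in ring flags,
#' Sybyl-style atom types, Bondi van der Waals radii, hydrogen-bond
#' donor/acceptor flags and heavy-atom degrees.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`).
#' @param name Molecule name.
#' @param source Free-form provenance (file of origin, ligand identifier).
#' @return An object of class `iso_mol`.
#' @export
iso_mol <- function(elements, coords, bonds, name = "", source = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  n <- length(elements)
  stopifnot(nrow(coords) == n)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(),
                        order = character(), in_ring = logical())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.character(bonds$order),
                        in_ring = if (!is.null(bonds$in_ring)) bonds$in_ring else NA)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond endpoint out of range", call. = FALSE)
    if (any(bonds$i == bonds$j))
      stop("self-bond not allowed", call. = FALSE)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stop("duplicate bonds", call. = FALSE)
    if (!all(bonds$order %in% c("1", "2", "3", "ar")))
      stop("bond order must be one of 1, 2, 3, ar", call. = FALSE)
  }
  atoms <- data.frame(
    element = as.character(elements),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    sybyl = NA_character_, vdw = NA_real_,
    is_donor = NA, is_acceptor = NA, heavy_degree = NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, bonds = bonds, name = name, source = source),
            class = "iso_mol")
}

#' @export
print.iso_mol <- function(x, ...) {
  cat(sprintf("<iso_mol> %s: %d atoms (%d heavy), %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_idx <- function(mol) which(mol$atoms$element != "H")

mol_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

`mol_coords<-` <- function(mol, value) {
  mol$atoms[, c("x", "y", "z")] <- value
  mol
}

# igraph view of the bond graph; vertices carry element, edges carry order.
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0L)
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  igraph::V(g)$element <- mol$atoms$element
  if (nrow(mol$bonds) > 0L) igraph::E(g)$order <- mol$bonds$order
  g
}

# Sum of bond orders per atom, aromatic counting 1.5.
total_bond_order <- function(mol) {
  tot <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    w <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1.5)[mol$bonds$order]
    for (k in seq_len(nrow(mol$bonds))) {
      tot[mol$bonds$i[k]] <- tot[mol$bonds$i[k]] + w[k]
      tot[mol$bonds$j[k]] <- tot[mol$bonds$j[k]] + w[k]
    }
  }
  tot
}

#' Perceive rings, atom types, radii and H-bonding roles
#'
#' Sets, for every atom: ring membership of its bonds (a bond is in a ring
#' iff it is not a bridge of the bond graph), a Sybyl-style type such as
#' `C.3`, `C.ar`, `N.2`, `N.pl3`, `O.3`, `S.o2`, the Bondi van der Waals
#' radius, heavy-atom degree, and hydrogen-bond donor/acceptor flags.
#'
#' Donor perception uses explicit hydrogens when the structure contains any;
#' otherwise hydrogens are inferred from standard valences of N and O
#' (PDB-deposited ligands usually lack hydrogens). Acceptors are N or O atoms
#' with an available lone pair under a simplified rule: every O accepts; N
#' accepts unless its lone pair is delocalized (planar `N.pl3`/`N.am`,
#' aromatic N-H) or its total bond order exceeds 3.
#'
#' @param mol An [iso_mol()].
#' @return The molecule with perception columns filled.
#' @export
perceive_and_type <- function(mol) {
  stopifnot(inherits(mol, "iso_mol"))
  n <- n_atoms(mol)
  el <- mol$atoms$element
  vdw_radius(unique(el))  # reject unsupported elements up front

  # ring flags: a bond is in a ring iff it is not a bridge
  if (nrow(mol$bonds) > 0L) {
    g <- mol_graph(mol)
    br <- igraph::bridges(g)
    in_ring <- rep(TRUE, nrow(mol$bonds))
    in_ring[as.integer(br)] <- FALSE
    mol$bonds$in_ring <- in_ring
  }

  is_h <- el == "H"
  heavy_deg <- integer(n)
  h_count <- integer(n)
  nbrs <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
      if (!is_h[j]) heavy_deg[i] <- heavy_deg[i] + 1L else h_count[i] <- h_count[i] + 1L
      if (!is_h[i]) heavy_deg[j] <- heavy_deg[j] + 1L else h_count[j] <- h_count[j] + 1L
    }
  }

  tot <- total_bond_order(mol)
  aromatic <- logical(n)
  n_double <- integer(n)
  double_to_o <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (mol$bonds$order[k] == "ar") aromatic[c(i, j)] <- TRUE
      if (mol$bonds$order[k] == "2") {
        n_double[c(i, j)] <- n_double[c(i, j)] + 1L
        if (el[j] == "O") double_to_o[i] <- double_to_o[i] + 1L
        if (el[i] == "O") double_to_o[j] <- double_to_o[j] + 1L
      }
    }
  }
  has_triple <- logical(n)
  if (nrow(mol$bonds) > 0L) {
    tr <- mol$bonds$order == "3"
    has_triple[unique(c(mol$bonds$i[tr], mol$bonds$j[tr]))] <- TRUE
  }

  # neighbor is sp2-like (aromatic or carries a double bond): used for N.pl3
  sp2_like <- aromatic | n_double > 0L

  sybyl <- character(n)
  for (a in seq_len(n)) {
    e <- el[a]
    sybyl[a] <- switch(e,
      H = "H",
      C = if (aromatic[a]) "C.ar" else if (has_triple[a]) "C.1"
          else if (n_double[a] > 0L) "C.2" else "C.3",
      N = if (aromatic[a]) "N.ar" else if (has_triple[a]) "N.1"
          else if (n_double[a] > 0L) "N.2"
          else if (any(sp2_like[nbrs[[a]]])) "N.pl3"
          else "N.3",
      O = if (n_double[a] > 0L) "O.2" else "O.3",
      S = if (double_to_o[a] >= 2L) "S.o2" else if (double_to_o[a] == 1L) "S.o"
          else "S.3",
      P = "P.3",
      e  # halogens, B, Si, Se: bare element symbol
    )
  }

  have_explicit_h <- any(is_h)
  implied_h <- numeric(n)
  infer <- el %in% names(.STD_VALENCE) & !have_explicit_h & !aromatic
  implied_h[infer] <- pmax(0, round(.STD_VALENCE[el[infer]] - tot[infer]))
  n_h <- if (have_explicit_h) h_count else implied_h

  is_donor <- el %in% c("N", "O") & n_h > 0
  is_acceptor <- rep(FALSE, n)
  is_acceptor[el == "O"] <- TRUE
  okN <- el == "N" & tot <= 3 &
    !(aromatic & n_h > 0) & !(sybyl %in% c("N.pl3", "N.am", "N.4"))
  is_acceptor[okN] <- TRUE

  mol$atoms$sybyl <- sybyl
  mol$atoms$vdw <- vdw_radius(el)
  mol$atoms$heavy_degree <- heavy_deg
  mol$atoms$is_donor <- is_donor
  mol$atoms$is_acceptor <- is_acceptor
  mol
}

#' Perceive aromatic rings from geometry
#'
#' For structures that carry no bond-order information (PDB ligands built
#' from CONECT records or distance-based perception), 5- and 6-membered
#' rings of C/N/O/S atoms that are planar (RMS deviation from the best
#' plane below `planarity_tol`) with aromatic-range bond lengths are
#' marked aromatic. Molecules that already carry any non-single bond are
#' returned unchanged.
#'
#' @param mol An [iso_mol()].
#' @param planarity_tol RMS planarity tolerance in Angstrom.
#' @return The molecule with qualifying ring bonds set to `"ar"`.
#' @export
perceive_aromatic_rings <- function(mol, planarity_tol = 0.1) {
  if (nrow(mol$bonds) == 0L || any(mol$bonds$order != "1")) return(mol)
  g <- mol_graph(mol)
  br <- as.integer(igraph::bridges(g))
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), br)
  if (length(ring_edges) == 0L) return(mol)
  el <- mol$atoms$element
  xyz <- mol_coords(mol)
  deg <- igraph::degree(g)
  mark <- logical(nrow(mol$bonds))
  seen <- character(0)
  for (e in ring_edges) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    sp <- suppressWarnings(
      igraph::shortest_paths(igraph::delete_edges(g, e), i, j)$vpath[[1]])
    cyc <- as.integer(sp)
    if (length(cyc) < 5L || length(cyc) > 6L) next
    key <- paste(sort(cyc), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!all(el[cyc] %in% c("C", "N", "O", "S"))) next
    if (any(deg[cyc] > 3L)) next
    P <- sweep(xyz[cyc, , drop = FALSE], 2L,
               colMeans(xyz[cyc, , drop = FALSE]))
    if (svd(P)$d[3] / sqrt(length(cyc)) > planarity_tol) next
    nxt <- c(cyc[-1], cyc[1])
    dl <- sqrt(rowSums((xyz[cyc, , drop = FALSE] -
                        xyz[nxt, , drop = FALSE])^2))
    s_bond <- el[cyc] == "S" | el[nxt] == "S"
    ok <- ifelse(s_bond, dl >= 1.30 & dl <= 1.85,
                 dl >= 1.25 & dl <= 1.43)
    if (!all(ok)) next
    for (k in seq_along(cyc)) {
      a <- cyc[k]; b <- nxt[k]
      mark[(mol$bonds$i == a & mol$bonds$j == b) |
           (mol$bonds$i == b & mol$bonds$j == a)] <- TRUE
    }
  }
  mol$bonds$order[mark] <- "ar"
  mol
}

# Kekule -> aromatic normalization: 5/6-rings of C/N/O/S whose alternating
# double bonds (plus lone-pair heteroatoms in 5-rings) complete an aromatic
# sextet are rewritten with aromatic bonds, so connection tables written in
# Kekule form compare equal to aromatic ones.
aromatize_kekule <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(mol)
  g <- mol_graph(mol)
  br <- as.integer(igraph::bridges(g))
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), br)
  if (length(ring_edges) == 0L) return(mol)
  el <- mol$atoms$element
  bond_row <- function(a, b)
    which((mol$bonds$i == a & mol$bonds$j == b) |
          (mol$bonds$i == b & mol$bonds$j == a))
  mark <- logical(nrow(mol$bonds))
  seen <- character(0)
  for (e in ring_edges) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    sp <- suppressWarnings(
      igraph::shortest_paths(igraph::delete_edges(g, e), i, j)$vpath[[1]])
    cyc <- as.integer(sp)
    n <- length(cyc)
    if (n < 5L || n > 6L) next
    key <- paste(sort(cyc), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!all(el[cyc] %in% c("C", "N", "O", "S"))) next
    nxt <- c(cyc[-1], cyc[1])
    rows <- mapply(bond_row, cyc, nxt)
    orders <- mol$bonds$order[rows]
    if (any(orders == "3")) next
    if (all(orders == "ar")) next
    ndouble <- sum(orders == "2")
    # ring atoms without a ring double bond must donate a lone pair
    has_double <- logical(n)
    for (k in seq_len(n)) {
      a <- cyc[k]
      inc <- rows[mol$bonds$i[rows] == a | mol$bonds$j[rows] == a]
      has_double[k] <- any(mol$bonds$order[inc] == "2")
    }
    lone <- el[cyc] %in% c("N", "O", "S") & !has_double
    if (any(!has_double & !lone)) next
    if (2L * ndouble + 2L * sum(lone) != 6L) next
    mark[rows] <- TRUE
  }
  mol$bonds$order[mark] <- "ar"
  mol
}

# Renumber a molecule's atoms by permutation `perm` (new order of old indices).
permute_atoms <- function(mol, perm) {
  stopifnot(length(perm) == n_atoms(mol))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  out <- mol
  out$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(out$atoms) <- NULL
  if (nrow(mol$bonds) > 0L) {
    out$bonds$i <- inv[mol$bonds$i]
    out$bonds$j <- inv[mol$bonds$j]
  }
  out
}
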