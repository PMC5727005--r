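# Fragmentation at rotatable bonds. Each broken bond (a, b) leaves a copy
# of b (a "join atom", with original coordinates and Sybyl type) attached
# to a's fragment and vice versa; all other atoms are "core" atoms.

#' Find rotatable bonds
#'
#' A bond is rotatable when it is a single, non-aromatic, non-ring bond
#' whose two endpoints each have at least two heavy-atom neighbours (so
#' bonds to terminal groups such as methyl or halogen never count). Amide
#' C-N bonds are treated like any other single bond unless
#' `exclude_amides = TRUE`.
#'
#' @param mol A typed [iso_mol()].
#' @param exclude_amides Exempt amide C(=O)-N bonds.
#' @return Integer vector of row indices into `mol$bonds`.
#' @export
find_rotatable_bonds <- function(mol, exclude_amides = FALSE) {
  stopifnot(inherits(mol, "iso_mol"))
  if (anyNA(mol$atoms$heavy_degree))
    stop("molecule must be typed first (perceive_and_type)", call. = FALSE)
  b <- mol$bonds
  if (nrow(b) == 0L) return(integer())
  el <- mol$atoms$element
  deg <- mol$atoms$heavy_degree
  rot <- b$order == "1" & !b$in_ring &
    el[b$i] != "H" & el[b$j] != "H" &
    deg[b$i] >= 2L & deg[b$j] >= 2L
  if (exclude_amides && any(rot)) {
    carbonyl <- vapply(seq_len(n_atoms(mol)), function(a) {
      el[a] == "C" && any(b$order == "2" &
        ((b$i == a & el[b$j] == "O") | (b$j == a & el[b$i] == "O")))
    }, logical(1))
    amide <- (el[b$i] == "N" & carbonyl[b$j]) |
             (el[b$j] == "N" & carbonyl[b$i])
    rot <- rot & !amide
  }
  which(rot)
}

#' Fragment a molecule at its rotatable bonds
#'
#' All rotatable bonds are deleted; each connected component of the
#' remainder becomes one fragment. For every broken bond (a, b), the
#' fragment containing a receives a join-atom copy of b and the fragment
#' containing b a join-atom copy of a. Fragment count therefore equals the
#' number of broken bonds plus one.
#'
#' @param mol A typed, connected [iso_mol()].
#' @param exclude_amides Passed to [find_rotatable_bonds()].
#' @return List of `iso_frag` objects, ordered by smallest parent atom
#'   index. Each has `atoms` (with `orig` parent index and `is_join` flag),
#'   `bonds`, `parent` and `broken` (the broken-bond table).
#' @export
fragment_molecule <- function(mol, exclude_amides = FALSE) {
  stopifnot(inherits(mol, "iso_mol"))
  g <- mol_graph(mol)
  if (igraph::components(g)$no != 1L)
    stop("molecule is disconnected; fragment each component separately",
         call. = FALSE)
  rb <- find_rotatable_bonds(mol, exclude_amides)
  keep <- setdiff(seq_len(nrow(mol$bonds)), rb)
  gcut <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (length(keep))
    gcut <- igraph::add_edges(gcut, rbind(mol$bonds$i[keep],
                                          mol$bonds$j[keep]))
  comp <- igraph::components(gcut)$membership
  broken <- mol$bonds[rb, , drop = FALSE]

  frags <- lapply(sort(unique(comp)), function(cid) {
    core <- which(comp == cid)
    # join atoms: partners of broken bonds with exactly one end in the core
    jrows <- which((broken$i %in% core) != (broken$j %in% core))
    join_orig <- integer(0); join_anchor <- integer(0)
    for (k in jrows) {
      if (broken$i[k] %in% core) {
        join_orig <- c(join_orig, broken$j[k])
        join_anchor <- c(join_anchor, broken$i[k])
      } else {
        join_orig <- c(join_orig, broken$i[k])
        join_anchor <- c(join_anchor, broken$j[k])
      }
    }
    sel <- c(core, join_orig)
    atoms <- mol$atoms[sel, , drop = FALSE]
    rownames(atoms) <- NULL
    atoms$orig <- sel
    atoms$is_join <- c(rep(FALSE, length(core)), rep(TRUE, length(join_orig)))
    # core-core bonds (kept bonds internal to the component)
    bi <- mol$bonds[keep, , drop = FALSE]
    bi <- bi[bi$i %in% core & bi$j %in% core, , drop = FALSE]
    loc <- function(orig) match(orig, core)
    bonds <- data.frame(i = loc(bi$i), j = loc(bi$j),
                        order = bi$order, in_ring = bi$in_ring)
    if (length(join_orig)) {
      att <- data.frame(i = match(join_anchor, core),
                        j = length(core) + seq_along(join_orig),
                        order = "1", in_ring = FALSE)
      bonds <- rbind(bonds, att)
    }
    structure(list(atoms = atoms, bonds = bonds,
                   parent = mol$name,
                   broken = data.frame(core = join_anchor,
                                       partner = join_orig)),
              class = "iso_frag")
  })
  frags[order(vapply(frags, function(f) min(f$atoms$orig[!f$atoms$is_join]),
                     numeric(1)))]
}

#' @export
print.iso_frag <- function(x, ...) {
  cat(sprintf("<iso_frag> of %s: %d core + %d join atoms\n",
              if (nzchar(x$parent)) x$parent else "(unnamed)",
              sum(!x$atoms$is_join), sum(x$atoms$is_join)))
  invisible(x)
}

# fragment atoms/bonds as a plain iso_mol (perception columns preserved)
fragment_to_mol <- function(frag, core_only = FALSE) {
  keep <- if (core_only) which(!frag$atoms$is_join) else
    seq_len(nrow(frag$atoms))
  atoms <- frag$atoms[keep, , drop = FALSE]
  b <- frag$bonds[frag$bonds$i %in% keep & frag$bonds$j %in% keep, ,
                  drop = FALSE]
  m <- iso_mol(atoms$element,
               as.matrix(atoms[, c("x", "y", "z")]),
               data.frame(i = match(b$i, keep), j = match(b$j, keep),
                          order = b$order, in_ring = b$in_ring),
               name = paste0(frag$parent, ":fragment"))
  m$atoms$sybyl <- atoms$sybyl
  m$atoms$vdw <- atoms$vdw
  m$atoms$is_donor <- atoms$is_donor
  m$atoms$is_acceptor <- atoms$is_acceptor
  m$atoms$heavy_degree <- atoms$heavy_degree
  m
}

# aromatic flag per fragment atom, from incident aromatic fragment bonds
frag_aromatic <- function(frag) {
  ar <- logical(nrow(frag$atoms))
  bb <- frag$bonds[frag$bonds$order == "ar", , drop = FALSE]
  ar[unique(c(bb$i, bb$j))] <- TRUE
  ar
}

# fragment-local ring membership (join atoms hang off a single bond and
# are therefore never ring atoms within the fragment)
frag_in_ring <- function(frag) {
  inr <- logical(nrow(frag$atoms))
  bb <- frag$bonds[frag$bonds$in_ring %in% TRUE, , drop = FALSE]
  inr[unique(c(bb$i, bb$j))] <- TRUE
  inr
}

#' Labeled graph of a fragment's core structure
#'
#' Graph over core atoms only; node labels combine element and aromatic
#' flag, edge labels the bond order. Two fragments have the same core
#' structure iff these graphs are isomorphic under labels (see
#' [same_core()]).
#'
#' @param frag An `iso_frag`.
#' @return An igraph object with vertex attribute `label` and edge
#'   attribute `order`.
#' @export
core_graph <- function(frag) {
  core <- which(!frag$atoms$is_join)
  ar <- frag_aromatic(frag)
  g <- igraph::make_empty_graph(n = length(core), directed = FALSE)
  b <- frag$bonds[frag$bonds$i %in% core & frag$bonds$j %in% core, ,
                  drop = FALSE]
  if (nrow(b))
    g <- igraph::add_edges(g, rbind(match(b$i, core), match(b$j, core)))
  igraph::V(g)$label <- paste0(frag$atoms$element[core],
                               ifelse(ar[core], ":ar", ""))
  if (nrow(b)) igraph::E(g)$order <- b$order else
    g <- igraph::set_edge_attr(g, "order", value = character(0))
  g
}

# assign integer colors to two labeled graphs over the union of labels
color_pair <- function(g1, g2) {
  vl <- union(igraph::V(g1)$label, igraph::V(g2)$label)
  el <- union(igraph::E(g1)$order, igraph::E(g2)$order)
  igraph::V(g1)$color <- match(igraph::V(g1)$label, vl)
  igraph::V(g2)$color <- match(igraph::V(g2)$label, vl)
  igraph::E(g1)$color <- match(igraph::E(g1)$order, el)
  igraph::E(g2)$color <- match(igraph::E(g2)$order, el)
  list(g1, g2)
}

labeled_isomorphic <- function(g1, g2) {
  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  if (!identical(sort(igraph::V(g1)$label), sort(igraph::V(g2)$label)))
    return(FALSE)
  gs <- color_pair(g1, g2)
  igraph::isomorphic(gs[[1]], gs[[2]], method = "vf2")
}

#' Do two fragments share the same core structure?
#'
#' @param a,b `iso_frag` objects.
#' @return `TRUE` iff the labeled core graphs are isomorphic.
#' @export
same_core <- function(a, b) {
  labeled_isomorphic(core_graph(a), core_graph(b))
}

# order-invariant fingerprint of the core graph, used as a database index
# bucket key; equality of keys is necessary (not sufficient) for same_core.
core_key <- function(frag) {
  g <- core_graph(frag)
  vl <- igraph::V(g)$label
  deg <- igraph::degree(g)
  vpart <- sort(paste0(vl, "/", deg))
  ep <- igraph::as_edgelist(g)
  epart <- if (nrow(ep)) {
    a <- vl[ep[, 1]]; b <- vl[ep[, 2]]
    sort(paste0(pmin(a, b), "~", igraph::E(g)$order, "~", pmax(a, b)))
  } else character(0)
  paste(c(vpart, "|", epart), collapse = ",")
}

#' Write / read a fragment as SDF with marked join atoms
#'
#' The fragment (core plus join atoms) is written as a single SDF record;
#' the 1-based indices of the join atoms are stored in a `JOIN_ATOMS` data
#' field so the fragment survives a round trip.
#'
#' @param frag An `iso_frag`.
#' @param path Output (input) file.
#' @return `read_fragment_sdf` returns the `iso_frag`.
#' @export
write_fragment_sdf <- function(frag, path) {
  m <- fragment_to_mol(frag)
  block <- write_mol(m)
  joins <- which(frag$atoms$is_join)
  txt <- paste0(block, ">  <JOIN_ATOMS>\n",
                paste(joins, collapse = " "), "\n\n$$$$\n")
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

#' @rdname write_fragment_sdf
#' @export
read_fragment_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- read_mol(path)
  fld <- grep("^>\\s*<JOIN_ATOMS>", lines)
  joins <- if (length(fld)) {
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[fld[1] + 1L]),
                                              "\\s+")[[1]]))
    v[!is.na(v)]
  } else integer(0)
  atoms <- m$atoms
  atoms$orig <- NA_integer_
  atoms$is_join <- seq_len(nrow(atoms)) %in% joins
  anchors <- integer(0); partners <- integer(0)
  for (j in joins) {
    nb <- c(m$bonds$i[m$bonds$j == j], m$bonds$j[m$bonds$i == j])
    nb <- nb[!(nb %in% joins)]
    if (length(nb) != 1L)
      stop("join atom ", j, " must attach to exactly one core atom",
           call. = FALSE)
    anchors <- c(anchors, nb); partners <- c(partners, NA_integer_)
  }
  structure(list(atoms = atoms, bonds = m$bonds, parent = m$name,
                 broken = data.frame(core = anchors, partner = partners)),
            class = "iso_frag")
}

#' Simple count descriptors of a fragment
#'
#' Heavy-atom, donor, acceptor, ring-atom, core and join counts over the
#' fragment's heavy atoms (core plus join).
#'
#' @param frag A typed `iso_frag`.
#' @return List of class `iso_frag_desc` with fields `n_heavy`, `n_donor`,
#'   `n_acceptor`, `n_ring_atoms`, `n_core`, `n_join`.
#' @export
describe_fragment <- function(frag) {
  heavy <- frag$atoms$element != "H"
  inr <- frag_in_ring(frag)
  structure(list(
    n_heavy = sum(heavy),
    n_donor = sum(frag$atoms$is_donor & heavy),
    n_acceptor = sum(frag$atoms$is_acceptor & heavy),
    n_ring_atoms = sum(inr & heavy),
    n_core = sum(!frag$atoms$is_join & heavy),
    n_join = sum(frag$atoms$is_join & heavy)
  ), class = "iso_frag_desc")
}

#' @export
print.iso_frag_desc <- function(x, ...) {
  cat(sprintf(paste0("<descriptors> heavy %d (core %d + join %d), ",
                     "donors %d, acceptors %d, ring atoms %d\n"),
              x$n_heavy, x$n_core, x$n_join, x$n_donor, x$n_acceptor,
              x$n_ring_atoms))
  invisible(x)
}
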