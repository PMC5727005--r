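# Grafting a replacement fragment into a molecule. One reconnecting
# join-atom pair is given explicitly; every remaining severed attachment
# is re-bonded by the valence-aware closest-pair rule: candidate
# (replacement atom, molecule atom) pairs are taken in ascending distance
# order and a single bond is formed whenever both partners still have
# available valence, bonds to hydrogens never counting.

#' Remaining heavy-bonding capacity of an atom
#'
#' The element's maximum heavy-atom bond count (C 4, N 3, O 2, S 2/4/6 by
#' Sybyl type, halogens 1) minus its current number of bonds to heavy
#' atoms; bonds to hydrogen atoms are ignored. Never negative.
#'
#' @param mol A typed [iso_mol()].
#' @param idx Atom index.
#' @return Integer count.
#' @export
available_valence <- function(mol, idx) {
  stopifnot(inherits(mol, "iso_mol"), idx >= 1L, idx <= n_atoms(mol))
  el <- mol$atoms$element
  b <- mol$bonds
  deg <- sum((b$i == idx & el[b$j] != "H") | (b$j == idx & el[b$i] != "H"))
  max(0L, max_heavy_valence(el[idx], mol$atoms$sybyl[idx]) - deg)
}

# rotation taking unit direction a onto unit direction b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: 180 degrees about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Replace a fragment of a molecule with another fragment
#'
#' The core atoms of `old` are removed from `mol`. The `new` fragment is
#' placed by superposing its selected join atom onto the molecule-side
#' attachment atom and aligning the join-to-core bond vector onto the
#' original attachment direction; the primary bond is then formed there.
#' Any further severed attachment of the molecule is reconnected by the
#' closest valence-feasible (replacement atom, molecule atom) pair, taken
#' in ascending distance order. All formed bonds are single bonds.
#'
#' @param mol A typed [iso_mol()].
#' @param old An `iso_frag` obtained by fragmenting `mol` (its `orig`
#'   indices must refer to `mol`).
#' @param new The replacement `iso_frag`.
#' @param join_choice List with `new_join` (row index of the join atom of
#'   `new` to reconnect through) and `attach` (atom index in `mol` of the
#'   attachment atom, i.e. a broken-bond partner of `old`). May be omitted
#'   when both are unambiguous.
#' @return The typed product molecule.
#' @export
replace_fragment <- function(mol, old, new, join_choice = NULL) {
  stopifnot(inherits(mol, "iso_mol"), inherits(old, "iso_frag"),
            inherits(new, "iso_frag"))
  old_core <- old$atoms$orig[!old$atoms$is_join]
  if (is.null(old_core) || anyNA(old_core) ||
      any(old_core < 1L | old_core > n_atoms(mol)))
    stop("'old' does not reference atoms of 'mol'", call. = FALSE)
  partners <- old$broken$partner  # molecule atoms that lose a bond

  new_joins <- which(new$atoms$is_join)
  if (length(new_joins) == 0L)
    stop("replacement fragment has no join atom to reconnect through",
         call. = FALSE)
  if (is.null(join_choice)) {
    if (length(new_joins) > 1L || length(partners) > 1L)
      stop("ambiguous reconnection; give join_choice = list(new_join, ",
           "attach)", call. = FALSE)
    join_choice <- list(new_join = new_joins[1], attach = partners[1])
  }
  nj <- join_choice$new_join; attach <- join_choice$attach
  if (!(nj %in% new_joins))
    stop("join_choice$new_join is not a join atom of 'new'", call. = FALSE)
  if (!(attach %in% partners))
    stop("join_choice$attach is not a severed attachment atom of 'mol'",
         call. = FALSE)

  # geometry of the removed attachment: attachment atom and the removed
  # core atom it was bonded to
  k <- which(old$broken$partner == attach)[1]
  qa <- unlist(mol$atoms[attach, c("x", "y", "z")])
  qc <- unlist(mol$atoms[old$broken$core[k], c("x", "y", "z")])

  # replacement geometry: selected join atom and its anchoring core atom
  arow <- c(new$bonds$i[new$bonds$j == nj], new$bonds$j[new$bonds$i == nj])
  arow <- arow[!new$atoms$is_join[arow]][1]
  pj <- unlist(new$atoms[nj, c("x", "y", "z")])
  pc <- unlist(new$atoms[arow, c("x", "y", "z")])
  R <- rotation_between(pc - pj, qc - qa)

  new_core <- which(!new$atoms$is_join)
  ncoord <- as.matrix(new$atoms[new_core, c("x", "y", "z"), drop = FALSE])
  ncoord <- sweep(ncoord, 2L, pj) %*% t(R)
  ncoord <- sweep(ncoord, 2L, qa, `+`)

  # working molecule: mol minus old core atoms, plus new core atoms
  keep <- setdiff(seq_len(n_atoms(mol)), old_core)
  atoms <- mol$atoms[keep, , drop = FALSE]
  newat <- new$atoms[new_core, , drop = FALSE]
  newat[, c("x", "y", "z")] <- ncoord
  atoms <- rbind(atoms[, c("element", "x", "y", "z")],
                 newat[, c("element", "x", "y", "z")])
  rownames(atoms) <- NULL
  amap <- integer(n_atoms(mol)); amap[keep] <- seq_along(keep)
  nmap <- length(keep) + seq_along(new_core)  # new-core row -> product idx

  bk <- mol$bonds[!(mol$bonds$i %in% old_core | mol$bonds$j %in% old_core),
                  , drop = FALSE]
  bonds <- data.frame(i = amap[bk$i], j = amap[bk$j], order = bk$order)
  bn <- new$bonds[new$bonds$i %in% new_core & new$bonds$j %in% new_core, ,
                  drop = FALSE]
  bonds <- rbind(bonds, data.frame(i = nmap[match(bn$i, new_core)],
                                   j = nmap[match(bn$j, new_core)],
                                   order = bn$order))

  product <- iso_mol(atoms$element, as.matrix(atoms[, c("x", "y", "z")]),
                     bonds, name = paste0(mol$name, ":replaced"),
                     source = mol$source)
  product <- perceive_and_type(product)

  add_bond <- function(p, i, j) {
    p$bonds <- rbind(p$bonds, data.frame(i = i, j = j, order = "1",
                                         in_ring = FALSE))
    p
  }

  # primary bond at the chosen pair
  anchor_idx <- nmap[match(arow, new_core)]
  if (available_valence(product, amap[attach]) < 1L)
    stop("attachment atom ", attach, " (",
         mol$atoms$element[attach], ") has no available valence",
         call. = FALSE)
  product <- add_bond(product, amap[attach], anchor_idx)

  # remaining severed attachments: closest valence-feasible pairs
  rest <- setdiff(partners, attach)
  if (length(rest)) {
    pm <- as.matrix(product$atoms[amap[rest], c("x", "y", "z"),
                                  drop = FALSE])
    nm <- as.matrix(product$atoms[nmap, c("x", "y", "z"), drop = FALSE])
    d <- cross_dist(nm, pm)
    ordp <- order(d)
    done <- rep(FALSE, length(rest))
    for (o in ordp) {
      ai <- (o - 1L) %% nrow(nm) + 1L      # new-fragment atom
      bi <- (o - 1L) %/% nrow(nm) + 1L     # severed molecule atom
      if (done[bi]) next
      ia <- nmap[ai]; ib <- amap[rest[bi]]
      if (available_valence(product, ia) >= 1L &&
          available_valence(product, ib) >= 1L) {
        product <- add_bond(product, ia, ib)
        done[bi] <- TRUE
      }
    }
    if (!all(done))
      stop("no valence-feasible partner for severed attachment at atom ",
           paste(rest[!done], collapse = ", "), " (",
           paste(mol$atoms$element[rest[!done]], collapse = ", "), ")",
           call. = FALSE)
  }

  product <- perceive_and_type(product)
  if (igraph::components(mol_graph(product))$no != 1L)
    stop("replacement left a disconnected product", call. = FALSE)
  product
}

#' Export a product molecule
#'
#' @param mol A typed, connected [iso_mol()].
#' @param format `"smiles"` or `"mol"`.
#' @param path Output file for `"mol"`; ignored for `"smiles"` unless
#'   given, in which case the string is also written there.
#' @return The SMILES string or the MOL block text (invisibly when written
#'   to a file).
#' @export
export_product <- function(mol, format = c("smiles", "mol"), path = NULL) {
  format <- match.arg(format)
  if (igraph::components(mol_graph(mol))$no != 1L)
    stop("product must be connected", call. = FALSE)
  out <- switch(format, smiles = to_smiles(mol), mol = write_mol(mol))
  if (!is.null(path)) {
    writeLines(sub("\n$", "", out), path)
    return(invisible(out))
  }
  out
}
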