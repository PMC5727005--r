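# Independent brute-force oracles used to verify the package's
# implementations; these deliberately avoid the package's own code paths.

# exhaustive one-sided Hausdorff: explicit enumeration of every
# point-to-set nearest distance
bf_one_sided_hd <- function(A, B) {
  worst <- 0
  for (r in seq_len(nrow(A))) {
    dmin <- min(sqrt((B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 +
                     (B[, 3] - A[r, 3])^2))
    if (dmin > worst) worst <- dmin
  }
  worst
}

bf_hausdorff <- function(A, B) max(bf_one_sided_hd(A, B),
                                   bf_one_sided_hd(B, A))

# Bron-Kerbosch with pivoting over an adjacency matrix; returns the size
# of the maximum clique and all maximum cliques (sorted index vectors)
bf_max_cliques <- function(adj) {
  n <- nrow(adj)
  best <- list(size = 0L, cliques = list())
  expand <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      if (length(R) > best$size) {
        best$size <<- length(R); best$cliques <<- list(sort(R))
      } else if (length(R) == best$size) {
        best$cliques <<- c(best$cliques, list(sort(R)))
      }
      return(invisible())
    }
    pux <- c(P, X)
    cnt <- vapply(pux, function(u) sum(adj[u, P]), numeric(1))
    pivot <- pux[which.max(cnt)]
    for (v in P[!adj[pivot, P]]) {
      expand(c(R, v), P[adj[v, P]], X[adj[v, X]])
      P <- setdiff(P, v); X <- c(X, v)
    }
  }
  if (n > 0L) expand(integer(0), seq_len(n), integer(0))
  best
}

# product graph of two labeled point sets, by the alignment definition:
# nodes = same-label (a, b) pairs, edges where |d(a,a') - d(b,b')| <= eps
bf_product_graph <- function(A, B, eps) {
  pairs <- which(outer(A$label, B$label, `==`), arr.ind = TRUE)
  np <- nrow(pairs)
  adj <- matrix(FALSE, np, np)
  if (np >= 2L) {
    dA <- as.matrix(dist(A[, c("x", "y", "z")]))
    dB <- as.matrix(dist(B[, c("x", "y", "z")]))
    for (u in 1:(np - 1)) for (v in (u + 1):np) {
      i <- pairs[u, 1]; j <- pairs[u, 2]
      k <- pairs[v, 1]; l <- pairs[v, 2]
      if (i != k && j != l && abs(dA[i, k] - dB[j, l]) <= eps)
        adj[u, v] <- adj[v, u] <- TRUE
    }
  }
  list(pairs = pairs, adj = adj)
}

random_points <- function(n, spread = 10) {
  matrix(runif(3 * n, -spread, spread), ncol = 3)
}

site_points_df <- function(xyz, labels) {
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], label = labels,
             chain = "A", resno = seq_len(nrow(xyz)), resid = "XXX",
             stringsAsFactors = FALSE)
}

# canonical-SMILES equality as a graph-isomorphism oracle (OpenBabel)
same_molecule <- function(a, b) identical(to_smiles(a), to_smiles(b))

# small hand-built molecules
mk_mol <- function(elements, coords, bonds) {
  perceive_and_type(iso_mol(elements, coords, bonds))
}

mk_methanol <- function() {
  mk_mol(c("C", "O"), rbind(c(0, 0, 0), c(1.43, 0, 0)),
         data.frame(i = 1, j = 2, order = "1"))
}

mk_ethane <- function() {
  mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
         data.frame(i = 1, j = 2, order = "1"))
}

# morpholine with an ethyl on the ring nitrogen (join lands on N side)
mk_n_ethylmorpholine <- function() {
  ring <- make_ligand("morpholine")
  xyz <- rbind(as.matrix(ring$atoms[, c("x", "y", "z")]),
               c(2.9, 0, 0), c(3.65, 1.3, 0))
  # morpholine template: O at vertex 1, N at vertex 4 (x = -1.45)
  xyz[7, ] <- c(-2.95, 0, 0); xyz[8, ] <- c(-3.7, 1.3, 0)
  mk_mol(c(ring$atoms$element, "C", "C"), xyz,
         rbind(ring$bonds[, c("i", "j", "order")],
               data.frame(i = c(4, 7), j = c(7, 8), order = "1")))
}

# morpholine with an ethyl on a ring carbon adjacent to O
mk_c_ethylmorpholine <- function() {
  ring <- make_ligand("morpholine")
  xyz <- rbind(as.matrix(ring$atoms[, c("x", "y", "z")]),
               c(1.45, 2.51, 0), c(2.2, 3.75, 0))
  mk_mol(c(ring$atoms$element, "C", "C"), xyz,
         rbind(ring$bonds[, c("i", "j", "order")],
               data.frame(i = c(2, 7), j = c(7, 8), order = "1")))
}

# thiophene with an ethyl substituent (fragmenting gives thiophene + join)
mk_ethylthiophene <- function() {
  ring <- make_ligand("thiophene")
  xyz <- rbind(as.matrix(ring$atoms[, c("x", "y", "z")]),
               c(0.83, 2.57, 0), c(1.6, 3.8, 0))
  mk_mol(c(ring$atoms$element, "C", "C"), xyz,
         rbind(ring$bonds[, c("i", "j", "order")],
               data.frame(i = c(2, 6), j = c(6, 7), order = "1")))
}

# build a pair record directly (for query-layer tests that need a small
# database with known content)
mk_record <- function(qfrag, pfrag, hd_overall = 0.5, hd_core = 0.4,
                      hd_hbond = NA_real_, relation = "unknown",
                      complex_a = "cplA", complex_b = "cplB") {
  isoswap:::new_pair_record(
    qfrag, pfrag,
    list(overall = hd_overall, core = hd_core, hbond = hd_hbond),
    match_join_atoms(qfrag, pfrag),
    list(complex_a = complex_a, complex_b = complex_b,
         ligand_a = "ligA", ligand_b = "ligB", zscore = NA_real_),
    relation)
}

# a small hand-built pair database with known content: morpholine
# fragments paired with thiophene/benzene under varying family relations,
# plus a toluene-core single fragment
mk_test_db <- function() {
  fmorN <- fragment_molecule(mk_n_ethylmorpholine())[[1]]
  fmorC <- fragment_molecule(mk_c_ethylmorpholine())[[1]]
  fthio <- fragment_molecule(mk_ethylthiophene())[[1]]
  fbenz <- fragment_molecule(make_ligand("ethylbenzene"))[[1]]
  tol <- mk_mol(rep("C", 7),
                rbind(isoswap:::ring_xy(6, 1.39), c(2.9, 0, 0)),
                rbind(isoswap:::ring_bonds(6, "ar"),
                      data.frame(i = 1, j = 7, order = "1")))
  ftol <- fragment_molecule(tol)[[1]]
  pair_db(list(
    mk_record(fmorN, fthio, 0.70, 0.65, relation = "intra",
              complex_a = "p1", complex_b = "p2"),
    mk_record(fmorN, fbenz, 0.90, 0.80, relation = "inter",
              complex_a = "p1", complex_b = "p3"),
    mk_record(fmorC, fbenz, 1.20, 1.10, relation = "unknown",
              complex_a = "p4", complex_b = "p5"),
    mk_record(fmorN, fbenz, 0.85, 0.75, relation = "intra",
              complex_a = "p6", complex_b = "p7"),
    mk_record(ftol, fbenz, 0.60, 0.55, relation = "intra",
              complex_a = "p8", complex_b = "p9")
  ))
}

single_fragment <- function(mol) {
  fr <- fragment_molecule(mol)
  stopifnot(length(fr) >= 1L)
  fr
}
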