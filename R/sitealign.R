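# Binding-site superposition: each site is reduced to labeled functional
# group points (hydrophobic / aromatic / donor / acceptor / donor_acceptor),
# two sites are matched by a distance-consistent maximum clique in the
# product graph of same-label point pairs, and the matched points are
# superposed with the Kabsch algorithm. Alignments are kept when the
# Z-score of their clique score within a batch passes a threshold.

# residue -> (atoms defining the point, label); the point is the centroid
# of whichever of the listed atoms are present.
.SITE_TABLE <- list(
  GLY = list(atoms = "CA", label = "hydrophobic"),
  ALA = list(atoms = "CB", label = "hydrophobic"),
  VAL = list(atoms = c("CB", "CG1", "CG2"), label = "hydrophobic"),
  LEU = list(atoms = c("CB", "CG", "CD1", "CD2"), label = "hydrophobic"),
  ILE = list(atoms = c("CB", "CG1", "CG2", "CD1"), label = "hydrophobic"),
  MET = list(atoms = c("CB", "CG", "SD", "CE"), label = "hydrophobic"),
  PRO = list(atoms = c("CB", "CG", "CD"), label = "hydrophobic"),
  PHE = list(atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             label = "aromatic"),
  TYR = list(atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             label = "aromatic"),
  TRP = list(atoms = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                       "CZ3", "CH2"), label = "aromatic"),
  SER = list(atoms = "OG", label = "donor_acceptor"),
  THR = list(atoms = "OG1", label = "donor_acceptor"),
  CYS = list(atoms = "SG", label = "donor"),
  LYS = list(atoms = "NZ", label = "donor"),
  ARG = list(atoms = c("NE", "NH1", "NH2"), label = "donor"),
  HIS = list(atoms = c("CG", "ND1", "CD2", "CE1", "NE2"),
             label = "donor_acceptor"),
  ASN = list(atoms = c("OD1", "ND2"), label = "donor_acceptor"),
  GLN = list(atoms = c("OE1", "NE2"), label = "donor_acceptor"),
  ASP = list(atoms = c("OD1", "OD2"), label = "acceptor"),
  GLU = list(atoms = c("OE1", "OE2"), label = "acceptor")
)

#' Reduce a binding site to labeled functional-group points
#'
#' One point per residue, at the centroid of the residue's functional-group
#' atoms, labeled from the closed vocabulary hydrophobic / aromatic /
#' donor / acceptor / donor_acceptor. Residues outside the 20 standard
#' amino acids are skipped with a warning.
#'
#' @param site An `iso_site` from [extract_binding_site()].
#' @return Data frame with columns `x`, `y`, `z`, `label`, `chain`,
#'   `resno`, `resid`.
#' @export
describe_site <- function(site) {
  stopifnot(inherits(site, "iso_site"))
  res <- site$residues
  out <- list()
  for (r in seq_len(nrow(res))) {
    entry <- .SITE_TABLE[[res$resid[r]]]
    if (is.null(entry)) {
      warning("unknown residue ", res$resid[r], " skipped", call. = FALSE)
      next
    }
    sel <- site$atoms$chain == res$chain[r] &
      site$atoms$resno == res$resno[r] &
      site$atoms$insert == res$insert[r] &
      site$atoms$atom_name %in% entry$atoms
    if (!any(sel)) next
    ctr <- colMeans(site$atoms[sel, c("x", "y", "z"), drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      x = ctr[1], y = ctr[2], z = ctr[3], label = entry$label,
      chain = res$chain[r], resno = res$resno[r], resid = res$resid[r],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      label = character(), chain = character(),
                      resno = integer(), resid = character()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kabsch least-squares rigid superposition
#'
#' Returns the proper rotation and translation minimizing the RMSD of the
#' points `Q` onto the paired points `P` (`x -> R x + t` maps Q onto P).
#' Mirror (improper) solutions are never returned.
#'
#' @param P,Q Numeric matrices of paired points, same dimensions, at least
#'   3 non-collinear rows.
#' @return An [iso_transform()] with attribute `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- matrix(as.numeric(P), ncol = 3L)
  Q <- matrix(as.numeric(Q), ncol = 3L)
  if (nrow(P) != nrow(Q) || nrow(P) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv <- svd(crossprod(Qc, Pc))  # 3x3 covariance
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear or coincident) point set", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- iso_transform(R, cp - as.numeric(R %*% cq))
  attr(tr, "rmsd") <- sqrt(mean(rowSums((apply_transform(tr, Q) - P)^2)))
  tr
}

# exact maximum clique with deterministic tie-break: among all maximum
# cliques, the lexicographically smallest sorted vertex-index set.
max_clique_lex <- function(g) {
  if (igraph::vcount(g) == 0L) return(integer())
  cl <- igraph::largest_cliques(g)
  if (length(cl) == 0L) return(integer())
  sets <- lapply(cl, function(s) sort(as.integer(s)))
  keys <- vapply(sets, function(s) paste(sprintf("%06d", s), collapse = ","),
                 character(1))
  sets[[which(keys == min(keys))[1]]]
}

#' Align two binding sites by distance-consistent maximum clique
#'
#' Builds the product graph whose nodes are same-label point pairs (a, b)
#' and whose edges connect pairs (a, b), (a', b') when the intra-site
#' distances agree within `eps`; finds an exact maximum clique; superposes
#' the matched points with [kabsch()]. The transform maps site B
#' coordinates into site A's frame.
#'
#' @param A,B Site point data frames from [describe_site()].
#' @param eps Distance-consistency tolerance in Angstrom.
#' @param min_score Minimum clique size for a valid alignment.
#' @return An object of class `iso_alignment` (fields `correspondence`,
#'   `transform`, `score`, `rmsd`, `zscore` initialized `NA`), or `NULL`
#'   when no alignment of at least `min_score` points exists.
#' @export
align_sites <- function(A, B, eps = 2.0, min_score = 4L) {
  stopifnot(eps > 0)
  min_score <- max(as.integer(min_score), 3L)
  if (nrow(A) == 0L || nrow(B) == 0L) return(NULL)
  pairs <- which(outer(A$label, B$label, `==`), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(NULL)
  Au <- as.matrix(A[, c("x", "y", "z")]); Bu <- as.matrix(B[, c("x", "y", "z")])
  dA <- as.matrix(stats::dist(Au)); dB <- as.matrix(stats::dist(Bu))
  np <- nrow(pairs)
  edges <- integer(0)
  for (u in seq_len(np - 1L)) {
    i <- pairs[u, 1]; j <- pairs[u, 2]
    for (v in seq(u + 1L, np)) {
      k <- pairs[v, 1]; l <- pairs[v, 2]
      if (i != k && j != l && abs(dA[i, k] - dB[j, l]) <= eps)
        edges <- c(edges, u, v)
    }
  }
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  clique <- max_clique_lex(g)
  if (length(clique) < min_score) return(NULL)
  corr <- pairs[clique, , drop = FALSE]
  tr <- kabsch(Au[corr[, 1], , drop = FALSE], Bu[corr[, 2], , drop = FALSE])
  structure(list(
    correspondence = data.frame(a = as.integer(corr[, 1]),
                                b = as.integer(corr[, 2])),
    transform = tr, score = length(clique),
    rmsd = attr(tr, "rmsd"), zscore = NA_real_
  ), class = "iso_alignment")
}

#' @export
print.iso_alignment <- function(x, ...) {
  cat(sprintf("<iso_alignment> score %d, rmsd %.3f A, Z %s\n", x$score,
              x$rmsd, ifelse(is.na(x$zscore), "unset",
                             sprintf("%.2f", x$zscore))))
  invisible(x)
}

#' Z-score filter over a batch of alignment scores
#'
#' Standardizes scores against the batch mean and population standard
#' deviation and keeps those at or above `threshold`. With zero spread all
#' Z-scores are defined as 0, so nothing passes a positive threshold.
#'
#' @param scores Numeric vector (batch size at least 2).
#' @param threshold Standard-score threshold (default 2, the similarity
#'   criterion used when mining).
#' @return Integer indices of the retained scores; the Z-scores are
#'   attached as attribute `zscores`.
#' @export
zscore_filter <- function(scores, threshold = 2) {
  stopifnot(length(scores) >= 2L)
  sdev <- sqrt(mean((scores - mean(scores))^2))
  if (sdev == 0) {
    z <- rep(0, length(scores))
    message("zscore_filter: zero score spread; all Z-scores set to 0")
  } else {
    z <- (scores - mean(scores)) / sdev
  }
  kept <- which(z >= threshold)
  attr(kept, "zscores") <- z
  kept
}

#' Transpose a ligand with a site-superposition transform
#'
#' Maps every atom `x -> R x + t`; topology and typing are untouched.
#'
#' @param mol An [iso_mol()].
#' @param t An [iso_transform()].
#' @return The transposed molecule.
#' @export
transpose_ligand <- function(mol, t) {
  stopifnot(inherits(mol, "iso_mol"), inherits(t, "iso_transform"))
  mol_coords(mol) <- apply_transform(t, mol_coords(mol))
  mol
}
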