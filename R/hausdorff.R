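# Van der Waals surface sampling and Hausdorff distances.
# Spheres are sampled on a deterministic Fibonacci lattice; points buried
# inside another atom of the same subset are culled, leaving the outer
# surface of the union of spheres.

fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Sample the van der Waals surface of a fragment
#'
#' Each selected heavy atom's Bondi sphere is sampled with `density`
#' Fibonacci-lattice points; points lying inside any other selected atom's
#' sphere (beyond a 1e-6 tolerance) are removed. The `subset` chooses the
#' atoms: `"all"` = core + join heavy atoms, `"core"` = core only,
#' `"hbond"` = hydrogen-bond donor or acceptor atoms.
#'
#' @param frag A typed `iso_frag`.
#' @param subset One of `"all"`, `"core"`, `"hbond"`.
#' @param density Points per atom sphere (>= 8).
#' @return Numeric matrix of surface points (possibly 0 rows when
#'   `subset = "hbond"` and the fragment has no donor/acceptor atoms; the
#'   attribute `empty_subset` is then `TRUE`).
#' @export
surface_points <- function(frag, subset = c("all", "core", "hbond"),
                           density = 64L) {
  subset <- match.arg(subset)
  stopifnot(inherits(frag, "iso_frag"), density >= 8L)
  heavy <- frag$atoms$element != "H"
  sel <- switch(subset,
    all = heavy,
    core = heavy & !frag$atoms$is_join,
    hbond = heavy & (frag$atoms$is_donor | frag$atoms$is_acceptor))
  idx <- which(sel)
  if (length(idx) == 0L) {
    out <- matrix(numeric(), ncol = 3L)
    attr(out, "empty_subset") <- TRUE
    return(out)
  }
  centers <- as.matrix(frag$atoms[idx, c("x", "y", "z"), drop = FALSE])
  radii <- frag$atoms$vdw[idx]
  unit <- fibonacci_sphere(as.integer(density))
  pts <- vector("list", length(idx))
  for (a in seq_along(idx)) {
    p <- sweep(unit * radii[a], 2L, centers[a, ], `+`)
    if (length(idx) > 1L) {
      others <- setdiff(seq_along(idx), a)
      d2 <- outer(rowSums(p^2), rowSums(centers[others, , drop = FALSE]^2),
                  `+`) - 2 * p %*% t(centers[others, , drop = FALSE])
      buried <- apply(sweep(sqrt(pmax(d2, 0)), 2L, radii[others] - 1e-6,
                            `<`), 1L, any)
      p <- p[!buried, , drop = FALSE]
    }
    pts[[a]] <- p
  }
  out <- do.call(rbind, pts)
  attr(out, "empty_subset") <- FALSE
  out
}

cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' One-sided Hausdorff distance
#'
#' The maximum, over points of `A`, of the distance to the closest point
#' of `B`.
#'
#' @param A,B Non-empty numeric matrices of 3D points.
#' @return Distance in Angstrom.
#' @export
one_sided_hd <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 3L)
  B <- matrix(as.numeric(B), ncol = 3L)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("one_sided_hd is undefined for empty point sets", call. = FALSE)
  # row-wise direct differences: numerically exact nearest distances
  worst <- 0
  for (r in seq_len(nrow(A))) {
    dmin <- min(sqrt((B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 +
                     (B[, 3] - A[r, 3])^2))
    if (dmin > worst) worst <- dmin
  }
  worst
}

#' Hausdorff distance between two point sets
#'
#' `HD(A, B) = max(oHD(A, B), oHD(B, A))`; symmetric and invariant under a
#' common rigid motion of both sets.
#'
#' @param A,B Non-empty numeric matrices of 3D points.
#' @return Distance in Angstrom.
#' @export
hausdorff <- function(A, B) {
  max(one_sided_hd(A, B), one_sided_hd(B, A))
}
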