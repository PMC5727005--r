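# Element tables used for perception: van der Waals radii (Bondi 1964),
# single-bond covalent radii, and maximum heavy-atom bond counts.
# Unknown elements are rejected, never defaulted.

.BONDI_VDW <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
  B = 1.92, Si = 2.10, Se = 1.90
)

.COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
  B = 0.84, Si = 1.11, Se = 1.20
)

# Standard valences used to infer implicit hydrogens on N/O when a
# structure carries no explicit hydrogens (the usual case for PDB ligands).
.STD_VALENCE <- c(N = 3, O = 2)

#' Bondi van der Waals radius of an element
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "O"))
#' @export
vdw_radius <- function(element) {
  r <- .BONDI_VDW[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(r)
}

covalent_radius <- function(element) {
  r <- .COVALENT_RADII[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(r)
}

# Maximum number of bonds to heavy atoms an atom may carry, by Sybyl type
# where the element alone is ambiguous (S). Bonds to hydrogens are ignored.
max_heavy_valence <- function(element, sybyl = NA_character_) {
  stopifnot(length(element) == 1L)
  switch(element,
    C = 4L,
    N = if (identical(sybyl, "N.4")) 4L else 3L,
    O = 2L,
    S = switch(if (is.na(sybyl)) "" else sybyl,
               S.o = 4L, S.o2 = 6L, 2L),
    P = 5L,
    B = 3L,
    Si = 4L,
    F = 1L, Cl = 1L, Br = 1L, I = 1L,
    H = 1L,
    stop("no heavy-valence maximum defined for element: ", element,
         call. = FALSE)
  )
}
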