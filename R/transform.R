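#' Rigid-body transform
#'
#' A proper rotation plus translation, applied as `x -> R x + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector (Angstrom).
#' @return Object of class `iso_transform`.
#' @export
iso_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be proper orthonormal (det +1)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "iso_transform")
}

#' @export
print.iso_transform <- function(x, ...) {
  cat("<iso_transform>\n")
  print(round(cbind(x$rotation, x$translation), 4))
  invisible(x)
}

#' Apply a rigid transform to a coordinate matrix
#' @param t An [iso_transform()].
#' @param xyz Numeric matrix with 3 columns.
#' @return Transformed matrix.
#' @export
apply_transform <- function(t, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(xyz %*% t(t$rotation), 2L, t$translation, `+`)
}

#' Invert a rigid transform
#' @param t An [iso_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  iso_transform(Rt, -as.numeric(Rt %*% t$translation))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [iso_transform()] objects.
#' @return Transform equivalent to applying `b` then `a`.
#' @export
compose_transforms <- function(a, b) {
  iso_transform(a$rotation %*% b$rotation,
                as.numeric(a$rotation %*% b$translation) + a$translation)
}

# 12-number serialization (row-major rotation then translation), the
# interchange format for externally computed site transforms.
transform_to_numbers <- function(t) c(t(t$rotation), t$translation)

transform_from_numbers <- function(v) {
  stopifnot(length(v) == 12L)
  iso_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
}

#' Read rigid transforms from a 12-numbers-per-line text file
#'
#' Each line holds a row-major 3x3 rotation followed by a translation
#' vector. This lets transforms computed by an external binding-site
#' alignment program drive the mining step in place of the built-in aligner.
#'
#' @param path File path.
#' @return List of [iso_transform()] objects.
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != 12L || anyNA(v))
      stop("transform line must contain 12 numbers: ", l, call. = FALSE)
    transform_from_numbers(v)
  })
}

#' Write rigid transforms to a 12-numbers-per-line text file
#' @param transforms List of [iso_transform()] objects.
#' @param path File path.
#' @export
write_transforms <- function(transforms, path) {
  lines <- vapply(transforms, function(t)
    paste(format(transform_to_numbers(t), digits = 17), collapse = " "),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
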