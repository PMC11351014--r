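#' @include AllClasses.R
NULL

# validate an n x 3 coordinate matrix
.checkCoords <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) < 1L)
    stop("coordinates must be a non-empty n x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("coordinates must all be finite", call. = FALSE)
  coords
}

#' Per-atom position strings
#'
#' Formats each atom position as `"<x>,<y>,<z>"` with every component
#' rendered in fixed-point notation with exactly `digits` decimal places
#' (round-half-even, no exponent notation, no leading `+`).  Values that
#' round to zero are normalized to positive zero, so `-0.000` never
#' occurs.  Output order matches atom order.
#'
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param digits non-negative integer, decimal places retained
#'   (default 3).
#' @return character vector with one `"x,y,z"` string per atom.
#' @examples
#' atomPositionStrings(matrix(c(1.23456, -2, 4e-4), 1))  # "1.235,-2.000,0.000"
#' @export
atomPositionStrings <- function(coords, digits = 3L) {
  coords <- .checkCoords(coords)
  digits <- as.integer(digits)
  stopifnot(length(digits) == 1L, !is.na(digits), digits >= 0L)
  rounded <- round(coords, digits)
  rounded[rounded == 0] <- 0   # normalize negative zero
  txt <- matrix(sprintf("%.*f", digits, rounded), nrow = nrow(coords))
  paste(txt[, 1L], txt[, 2L], txt[, 3L], sep = ",")
}

#' Atom-order-invariant conformer hash
#'
#' Implements the four-step coordinate hashing scheme used to deduplicate
#' 3D conformers: (1) round each coordinate to `digits` decimal places,
#' (2) format each atom position as a comma-separated string, (3) sort
#' the position strings lexicographically (plain byte order), (4) join
#' them with semicolons and take the SHA-256 of the result.
#'
#' The hash is invariant under any permutation of the atoms but is
#' deliberately *not* translationally or rotationally invariant, so
#' prealigned conformers (e.g. docking poses) can be told apart.  Use
#' [canonicalizeOrientation()] first if orientation invariance is wanted.
#'
#' @inheritParams atomPositionStrings
#' @return the 64-character lowercase hexadecimal SHA-256 digest.
#' @examples
#' conformerHash(matrix(0, 1, 3))  # SHA-256 of "0.000,0.000,0.000"
#' @export
conformerHash <- function(coords, digits = 3L) {
  strs <- atomPositionStrings(coords, digits)
  joined <- paste(sort(strs, method = "radix"), collapse = ";")
  digest::digest(joined, algo = "sha256", serialize = FALSE)
}

#' Deterministic canonical orientation of a conformer
#'
#' Translates the centroid to the origin and rotates the conformer onto
#' the principal axes of its coordinate covariance, ordered by descending
#' eigenvalue.  The sign of each of the first two axes is chosen so that
#' the coordinate of largest absolute value along that axis is positive;
#' the third axis is their cross product (right-handed frame).  Pairwise
#' interatomic distances are preserved; conformers with coincident atoms
#' (zero covariance) are translated only.
#'
#' Combined with [conformerHash()], this gives a hash that is invariant
#' under rigid-body motion for conformers with non-degenerate principal
#' moments.
#'
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @return an n x 3 matrix of reoriented coordinates.
#' @export
canonicalizeOrientation <- function(coords) {
  coords <- .checkCoords(coords)
  centered <- sweep(coords, 2L, colMeans(coords))
  if (nrow(centered) == 1L || all(abs(centered) < 1e-12)) {
    centered[] <- 0
    return(centered)
  }
  cov <- crossprod(centered) / nrow(centered)
  ev <- eigen(cov, symmetric = TRUE)
  axes <- ev$vectors          # columns ordered by descending eigenvalue
  for (k in 1:2) {
    proj <- centered %*% axes[, k]
    i <- which.max(abs(proj))
    if (proj[[i]] < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3L] <- c(
    axes[2L, 1L] * axes[3L, 2L] - axes[3L, 1L] * axes[2L, 2L],
    axes[3L, 1L] * axes[1L, 2L] - axes[1L, 1L] * axes[3L, 2L],
    axes[1L, 1L] * axes[2L, 2L] - axes[2L, 1L] * axes[1L, 2L]
  )
  centered %*% axes
}
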