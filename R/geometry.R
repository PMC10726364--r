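## Vectorised 3D geometry helpers shared across modules.
## All coordinates are in Angstrom; all angles in degrees unless noted.

#' Row-wise cross product of two n x 3 matrices
#' @noRd
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise Euclidean norm of an n x 3 matrix
#' @noRd
rownorm3 <- function(a) sqrt(rowSums(a * a))

as_mat3 <- function(p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  stopifnot(ncol(p) == 3)
  p
}

#' Signed torsion angle (IUPAC convention), vectorised
#'
#' Computes the dihedral a-b-c-d in degrees in (-180, 180] for each row of
#' four n x 3 coordinate matrices. Positive angles are clockwise when viewed
#' along b to c. Raises an error on degenerate (collinear) geometries, which
#' indicate corrupt input rather than legitimate chemistry.
#'
#' @param a,b,c,d n x 3 matrices (or length-3 vectors) of positions in Angstrom.
#' @return numeric vector of signed torsions in degrees.
#' @noRd
torsion_signed <- function(a, b, c, d) {
  a <- as_mat3(a); b <- as_mat3(b); c <- as_mat3(c); d <- as_mat3(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- rownorm3(b2)
  bad <- rownorm3(n1) < 1e-10 | rownorm3(n2) < 1e-10 | nb2 < 1e-10
  if (any(bad)) {
    stop("degenerate geometry: collinear atoms in torsion definition (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  }
  y <- rowSums((nb2 * b1) * n2)
  x <- rowSums(n1 * n2)
  atan2(y, x) * 180 / pi
}

#' Wrap an angle series to [0, 360)
#'
#' Applies the reporting convention for the inter-ring torsion: 360 degrees
#' is added to any negative value (general values are reduced modulo 360).
#'
#' @param x numeric vector of angles in degrees.
#' @return values in [0, 360).
#' @export
wrap_360 <- function(x) {
  x <- x %% 360
  x[x == 360] <- 0
  x
}

#' Remap angles from [0, 360) to the display interval (-180, 180]
#'
#' Occupancy surfaces are binned on [0, 360); published-style plots often use
#' (-180, 180]. This is a display-only remapping.
#'
#' @param x numeric vector of angles in degrees.
#' @return values in (-180, 180].
#' @export
lambda_display <- function(x) {
  y <- wrap_360(x)
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Random rigid-body transform (rotation + translation)
#' @noRd
random_rigid_transform <- function(max_shift = 20) {
  # uniform random rotation via QR of a Gaussian matrix
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::runif(3, -max_shift, max_shift))
}

apply_rigid <- function(p, tr) {
  as_mat3(p) %*% t(tr$R) + matrix(tr$t, nrow(as_mat3(p)), 3, byrow = TRUE)
}
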