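#' Signed dihedral (torsion) angle of four points
#'
#' Computes the IUPAC signed torsion about the \code{p2}-\code{p3} axis:
#' looking from \code{p2} towards \code{p3}, the angle is positive when
#' \code{p4} is rotated clockwise relative to \code{p1}.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in radians in \code{[-pi, pi)}.
#' @examples
#' torsion_angle(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, -1, 1)) # -pi/2
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n2 <- sqrt(sum(b2^2))
  if (n2 < 1e-12) stop("degenerate geometry: p2 == p3")
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  if (sum(c12^2) < 1e-20 || sum(c23^2) < 1e-20)
    stop("degenerate geometry: collinear points in torsion")
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2) / n2
  wrap_angle(atan2(y, x))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

#' Wrap angles into [-pi, pi)
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval \code{[-pi, pi)}.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y >= pi] <- -pi  # guard against floating point at the seam
  y
}

#' Random rigid-body transform (for invariance testing)
#'
#' Draws a uniformly random proper rotation (QR of a Gaussian matrix with
#' positive-determinant correction) and a random translation.
#'
#' @param translation_sd Standard deviation (Angstrom) of the translation.
#' @return List with a 3x3 rotation matrix \code{R} and 3-vector \code{t};
#'   apply as \code{xyz %*% t(R) + t}.
#' @export
random_rigid_transform <- function(translation_sd = 20) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  R <- qr.Q(qr_d)
  d <- sign(diag(qr.R(qr_d)))
  R <- R %*% diag(d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = translation_sd))
}

apply_rigid <- function(xyz, tf) {
  sweep(xyz %*% t(tf$R), 2, tf$t, "+")
}

# Internal torsion over rows of a K x 3 matrix, vectorised elsewhere;
# used for small fixed point sets only.
dist3 <- function(a, b) sqrt(sum((a - b)^2))
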