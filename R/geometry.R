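#' Signed dihedral (torsion) angle of four points
#'
#' Computes the torsion angle about the `p1`--`p2` axis following the IUPAC
#' convention: trans/anti conformations give \eqn{\pi}, eclipsed (cis) gives 0,
#' and the sign follows the right-hand rule about the `p1`\eqn{\to}`p2` axis.
#' Mirror-image point sets give exactly negated angles.
#'
#' @param p0,p1,p2,p3 Numeric 3-vectors (Cartesian coordinates, any units).
#' @return Angle in radians in the half-open interval \eqn{(-\pi, \pi]}.
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # pi (trans)
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) # 0 (cis)
#' @export
dihedral <- function(p0, p1, p2, p3) {
  b1 <- p1 - p0
  b2 <- p2 - p1
  b3 <- p3 - p2
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1n <- sqrt(sum(n1^2))
  n2n <- sqrt(sum(n2^2))
  b2n <- sqrt(sum(b2^2))
  if (b2n < 1e-12 || n1n < 1e-12 || n2n < 1e-12) {
    stop("undefined dihedral: collinear or coincident points", call. = FALSE)
  }
  m1 <- cross3(n1, b2 / b2n)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(-y, x)
  # map -pi to +pi so the result lies in (-pi, pi]
  if (ang <= -pi + .Machine$double.eps * 4 && ang < 0) ang <- pi
  ang
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms `a`, `b`, `c`, returns the position `d`
#' at bond length `r` from `c`, bond angle `theta` at `c` (angle b-c-d) and
#' torsion `chi` about b-c (dihedral a-b-c-d). The returned point satisfies
#' `dihedral(a, b, c, d) == chi`.
#'
#' @param a,b,c Numeric 3-vectors, previously placed atoms.
#' @param r Bond length c-d (angstrom), > 0.
#' @param theta Bond angle b-c-d in radians.
#' @param chi Torsion a-b-c-d in radians.
#' @return Numeric 3-vector, the new atom position.
#' @keywords internal
place_atom <- function(a, b, c, r, theta, chi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate frame in place_atom: collinear reference atoms", call. = FALSE)
  n <- n / nn
  m <- cross3(n, bc)
  # local displacement; with this frame dihedral(a,b,c,d) == chi
  d_local <- c(
    -r * cos(theta),
    r * sin(theta) * cos(chi),
    r * sin(theta) * sin(chi)
  )
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Pairwise Euclidean distances between rows of two matrices (or one).
row_dist <- function(x, y = x) {
  xs <- rowSums(x^2)
  ys <- rowSums(y^2)
  d2 <- outer(xs, ys, "+") - 2 * x %*% t(y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
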