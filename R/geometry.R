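# Small 3D geometry kernel shared by the oligomer builder, docking and the
# trajectory analytics. Angles in degrees, distances in Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  a / n
}

#' Angle between three points
#' @param a,b,c Numeric 3-vectors; the angle is at `b`.
#' @return Angle in degrees.
#' @export
point_angle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle of four points
#' @param a,b,c,d Numeric 3-vectors.
#' @return Signed torsion a-b-c-d in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Natural-extension (NeRF) placement: position a fourth point at distance r
# from c, with angle(b, c, d) = theta and dihedral(a, b, c, d) = phi.
nerf_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# Pairwise distance matrix between two coordinate sets (rows are points).
cross_dist <- function(A, B) {
  a2 <- rowSums(A * A); b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
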