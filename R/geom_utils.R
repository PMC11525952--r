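# Low-level vector geometry: distances, angles, dihedrals, rigid motions,
# torsion-driven coordinate updates.

.vnorm <- function(v) sqrt(sum(v * v))

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Rodrigues rotation matrix about unit axis by angle (degrees)
.rotation_matrix <- function(axis, angle_deg) {
  a <- axis / .vnorm(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# random proper rotation (uniform via QR of gaussian matrix)
.random_rotation <- function(rng = NULL) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Apply a rigid-body motion to coordinates
#' @param coords N x 3 matrix
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector
#' @return transformed N x 3 matrix
#' @export
rigid_transform <- function(coords, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

.pairwise_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

.min_interatomic_distance <- function(coords, bonds = NULL) {
  d <- .pairwise_dist(coords)
  diag(d) <- Inf
  min(d)
}
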