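# Shared test utilities: random rigid motions and a reference torsion
# evaluator kept independent of the package internals.

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(x, R, t) sweep(x %*% t(R), 2, t, "+")

# Reference four-point dihedral (degrees), textbook formula written
# separately from the package's torsion code.
ref_torsion <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2], b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Superpose y onto x allowing reflection; returns RMSD after best proper
# superposition of (reflected) y.
mirror_rmsd <- function(x, y) {
  y[, 1] <- -y[, 1]
  cx <- colMeans(x); cy <- colMeans(y)
  H <- t(sweep(y, 2, cy)) %*% sweep(x, 2, cx)
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  yr <- sweep(sweep(y, 2, cy) %*% t(R), 2, cx, "+")
  sqrt(mean(rowSums((yr - x)^2)))
}
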