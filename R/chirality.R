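# Coordinate-based chirality indices computed from the alpha-carbon trace.
# These are used to cross-validate the analytic handedness metric h: all
# three are pseudoscalars (they negate exactly under reflection) and vanish
# for planar or collinear traces.

check_ca <- function(ca, min_n = 4L) {
  ca <- as.matrix(ca)
  if (ncol(ca) != 3L) stop("ca must be an N x 3 matrix", call. = FALSE)
  if (!all(is.finite(ca))) stop("ca contains non-finite values", call. = FALSE)
  if (nrow(ca) < min_n)
    stop("need at least ", min_n, " positions, got ", nrow(ca),
         call. = FALSE)
  steps <- diff(ca)
  if (any(sqrt(rowSums(steps^2)) < 1e-12))
    stop("consecutive positions coincide (zero-length step vector)",
         call. = FALSE)
  ca
}

#' Normalised triple-product chirality index
#'
#' Averages the normalised scalar triple product of three consecutive step
#' vectors of the alpha-carbon trace:
#' `(1/N) * sum_{i=2}^{N-2} (v_{i-1} x v_i) . v_{i+1} / (|v_{i-1}||v_i||v_{i+1}|)`
#' with `v_k = P_{k+1} - P_k`. The sum has N-3 terms but is normalised by N,
#' exactly as the index is defined in the literature. Range `[-1, 1]`;
#' negative is left-handed.
#'
#' @param ca N x 3 matrix of ordered alpha-carbon coordinates (angstroms).
#' @return A single number in `[-1, 1]`.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
#' chi1(pts)  # 0.25
#' @export
chi1 <- function(ca) {
  ca <- check_ca(ca)
  n <- nrow(ca)
  v <- diff(ca)                       # (n-1) x 3 step vectors
  len <- sqrt(rowSums(v^2))
  i <- seq_len(n - 3L)                # summand index: steps i, i+1, i+2
  a <- v[i, , drop = FALSE]
  b <- v[i + 1L, , drop = FALSE]
  cc <- v[i + 2L, , drop = FALSE]
  cross <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  triple <- rowSums(cross * cc)
  sum(triple / (len[i] * len[i + 1L] * len[i + 2L])) / n
}

#' Average alpha-carbon trace torsion
#'
#' Averages the signed dihedral angle (radians) defined by each run of four
#' contiguous alpha carbons, using the four-quadrant arctangent:
#' `(1/N) * sum arctan2(|v_i| * v_{i-1} . (v_i x v_{i+1}),
#' (v_{i-1} x v_i) . (v_i x v_{i+1}))`. Each summand lies in `(-pi, pi]`;
#' the sum has N-3 terms and is normalised by N. Negative is left-handed.
#'
#' @inheritParams chi1
#' @return Average torsion in radians.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
#' chi2(pts)  # pi/8: one +90 degree torsion averaged over N = 4
#' @export
chi2 <- function(ca) {
  ca <- check_ca(ca)
  n <- nrow(ca)
  v <- diff(ca)
  len <- sqrt(rowSums(v^2))
  i <- seq_len(n - 3L)
  a <- v[i, , drop = FALSE]
  b <- v[i + 1L, , drop = FALSE]
  cc <- v[i + 2L, , drop = FALSE]
  bxc <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
               b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
               b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  axb <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(atan2(len[i + 1L] * rowSums(a * bxc), rowSums(axb * bxc))) / n
}

#' G0S-type chirality index over atom quadruples
#'
#' The backbone-agnostic chirality index formed by summing, over all ordered
#' quadruples (i, j, k, l) of distinct trace positions, the product of a
#' scalar triple product and two dot products of the pairwise displacement
#' vectors `v_ij = P_j - P_i`, normalised by `4! / (3 N^4)`. Cost grows as
#' N^4, so chains longer than `max_n` are refused.
#'
#' Unlike [chi1()] and [chi2()], this index is not sign-calibrated to twist
#' handedness: it is a shape pseudoscalar whose sign depends on the helix
#' pitch regime, and on alpha-helical CA traces it takes the opposite sign
#' to h. It negates exactly under reflection and vanishes for achiral
#' traces; use chi1/chi2 when a sign comparison with h is wanted.
#'
#' @inheritParams chi1
#' @param max_n Refuse traces longer than this (cost guard); default 30.
#' @return A single number (arbitrary range); negative is left-handed.
#' @export
chi3 <- function(ca, max_n = 30L) {
  ca <- check_ca(ca)
  n <- nrow(ca)
  if (n > max_n)
    stop("chi3 cost grows as N^4; refusing N = ", n, " > max_n = ", max_n,
         call. = FALSE)
  # Pairwise displacement vectors and their norms, indexed [from, to].
  dx <- outer(ca[, 1], ca[, 1], function(a, b) b - a)
  dy <- outer(ca[, 2], ca[, 2], function(a, b) b - a)
  dz <- outer(ca[, 3], ca[, 3], function(a, b) b - a)
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j == i) next
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      for (l in seq_len(n)) {
        if (l == i || l == j || l == k) next
        cx <- dy[i, j] * dz[k, l] - dz[i, j] * dy[k, l]
        cy <- dz[i, j] * dx[k, l] - dx[i, j] * dz[k, l]
        cz <- dx[i, j] * dy[k, l] - dy[i, j] * dx[k, l]
        triple <- cx * dx[i, l] + cy * dy[i, l] + cz * dz[i, l]
        dot1 <- dx[i, j] * dx[j, k] + dy[i, j] * dy[j, k] +
          dz[i, j] * dz[j, k]
        dot2 <- dx[j, k] * dx[k, l] + dy[j, k] * dy[k, l] +
          dz[j, k] * dz[k, l]
        total <- total + triple * dot1 * dot2 /
          ((nrm[i, j] * nrm[j, k] * nrm[k, l])^2 * nrm[i, l])
      }
    }
  }
  factorial(4) / (3 * n^4) * total
}

#' All three chirality indices of an alpha-carbon trace
#'
#' @inheritParams chi3
#' @param include_chi3 Compute the N^4-cost index as well (only for short
#'   traces); default `TRUE` when `nrow(ca) <= max_n`.
#' @return A list with `chi1`, `chi2`, `chi3` (`NA` if skipped) and
#'   `n_residues`.
#' @export
chirality_indices <- function(ca, max_n = 30L,
                              include_chi3 = nrow(as.matrix(ca)) <= max_n) {
  ca <- check_ca(ca)
  list(chi1 = chi1(ca), chi2 = chi2(ca),
       chi3 = if (include_chi3) chi3(ca, max_n) else NA_real_,
       n_residues = nrow(ca))
}
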