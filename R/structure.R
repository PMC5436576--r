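# 3-D backbone construction from internal coordinates, dihedral measurement,
# PDB input/output and the screw-decomposition oracle.
#
# A chain stores one N, CA, C triplet per residue. The first residue sits in
# a canonical frame (N at the origin, CA along +x, C in the xy-plane); every
# reported quantity is frame-invariant, so the choice only pins down
# reproducible coordinates.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension (NeRF-style) placement: position atom D given the three
# preceding atoms A, B, C, the C-D bond length, the B-C-D bond angle and the
# A-B-C-D torsion (degrees).
place_atom <- function(A, B, C, length, angle, torsion) {
  ang <- angle * .deg2rad
  tor <- torsion * .deg2rad
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed torsion angle (degrees, in (-180, 180]) of four points.
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * .rad2deg
  if (ang <= -180) ang <- ang + 360
  ang
}

new_chain <- function(xyz, dihedrals, geom) {
  structure(list(xyz = xyz, n_residues = nrow(xyz) / 3L,
                 dihedrals = dihedrals, geom = geom),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("Backbone chain: %d residues (%d atoms: N, CA, C per residue)\n",
              x$n_residues, nrow(x$xyz)))
  if (!is.null(x$dihedrals))
    cat("  built from recorded per-residue (phi, psi, omega)\n")
  invisible(x)
}

# Coordinate accessors; rows of xyz cycle N, CA, C per residue.
atom_rows <- function(chain, atom = c("N", "CA", "C")) {
  atom <- match.arg(atom)
  off <- match(atom, c("N", "CA", "C"))
  seq.int(off, by = 3L, length.out = chain$n_residues)
}

#' Alpha-carbon coordinates of a chain
#'
#' @param chain A `"backbone_chain"`.
#' @return An N x 3 matrix of CA positions, angstroms.
#' @export
ca_coords <- function(chain) {
  chain$xyz[atom_rows(chain, "CA"), , drop = FALSE]
}

# Core sequential builder. states: data.frame with phi, psi, omega recycled
# cyclically along the chain (row r used for residue r). phi of residue 1 is
# not realisable (no preceding carbonyl) and is simply not used.
build_chain <- function(n, states, geom) {
  geom <- as_backbone_geometry(geom)
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  idx <- function(r) ((r - 1L) %% nrow(states)) + 1L
  xyz <- matrix(NA_real_, nrow = 3L * n, ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  # canonical first residue
  xyz[1L, ] <- c(0, 0, 0)
  xyz[2L, ] <- c(geom$v_n_alpha, 0, 0)
  sa <- geom$sigma_alpha * .deg2rad
  xyz[3L, ] <- xyz[2L, ] + geom$v_alpha_c * c(-cos(sa), sin(sa), 0)
  for (r in seq_len(n - 1L)) {
    s <- states[idx(r), ]
    base <- 3L * (r - 1L)
    # N(r+1): torsion N-CA-C-N(+1) = psi_r, angle at C = sigma_c
    xyz[base + 4L, ] <- place_atom(xyz[base + 1L, ], xyz[base + 2L, ],
                                   xyz[base + 3L, ], geom$v_c_n,
                                   geom$sigma_c, s$psi)
    # CA(r+1): torsion CA-C-N(+1)-CA(+1) = omega_r, angle at N = sigma_n
    xyz[base + 5L, ] <- place_atom(xyz[base + 2L, ], xyz[base + 3L, ],
                                   xyz[base + 4L, ], geom$v_n_alpha,
                                   geom$sigma_n, s$omega)
    # C(r+1): torsion C-N(+1)-CA(+1)-C(+1) = phi_{r+1}, angle at CA
    s2 <- states[idx(r + 1L), ]
    xyz[base + 6L, ] <- place_atom(xyz[base + 3L, ], xyz[base + 4L, ],
                                   xyz[base + 5L, ], geom$v_alpha_c,
                                   geom$sigma_alpha, s2$phi)
  }
  dih <- data.frame(res = seq_len(n),
                    phi = states$phi[vapply(seq_len(n), idx, 1L)],
                    psi = states$psi[vapply(seq_len(n), idx, 1L)],
                    omega = states$omega[vapply(seq_len(n), idx, 1L)])
  new_chain(xyz, dih, geom)
}

#' Build a regular backbone chain
#'
#' Places a poly-glycine backbone of `n` residues in which every residue
#' repeats the same (phi, psi, omega), by sequential internal-coordinate
#' extension from a canonical first residue. [measure_dihedrals()] on the
#' result round-trips the inputs to within 1e-6 degrees.
#'
#' @param n Number of residues (>= 2).
#' @param state A [dihedral_state()] (or list with `phi`, `psi`, `omega` in
#'   degrees).
#' @param geom A [backbone_geometry()].
#' @return A `"backbone_chain"`.
#' @examples
#' ch <- build_regular(12, dihedral_state(-57, -47, 180))
#' dist(ca_coords(ch)[1:2, ])  # ~3.82 A between adjacent CAs
#' @export
build_regular <- function(n, state, geom = backbone_geometry()) {
  st <- as_dihedrals(state)
  build_chain(n, data.frame(phi = st$phi, psi = st$psi, omega = st$omega),
              geom)
}

#' Build a backbone alternating between several dihedral states
#'
#' Residue r takes its dihedrals from `states[[((r - 1) %% length(states)) + 1]]`,
#' cycling through the supplied list along the chain. With a single state
#' this is atom-identical to [build_regular()]. Alternating two states of
#' equal twist magnitude and opposite handedness produces the meandering,
#' net-linear strands observed for peptoid secondary structures.
#'
#' @param states Non-empty list of [dihedral_state()] objects (or lists with
#'   `phi`, `psi`, `omega`).
#' @param n Number of residues (>= 2).
#' @param geom A [backbone_geometry()].
#' @return A `"backbone_chain"`.
#' @examples
#' ch <- build_pattern(list(dihedral_state(-120, 90), dihedral_state(-90, 120)), 16)
#' @export
build_pattern <- function(states, n, geom = backbone_geometry()) {
  if (length(states) == 0L) stop("states must be non-empty", call. = FALSE)
  tab <- do.call(rbind, lapply(states, function(s) {
    st <- as_dihedrals(s)
    data.frame(phi = st$phi, psi = st$psi, omega = st$omega)
  }))
  build_chain(n, tab, geom)
}

#' Measure backbone dihedral angles from coordinates
#'
#' Recovers the per-residue (phi, psi, omega) from a chain's atom positions
#' using the standard torsion definitions: phi_i from C(i-1)-N(i)-CA(i)-C(i),
#' psi_i from N(i)-CA(i)-C(i)-N(i+1) and omega_i from
#' CA(i)-C(i)-N(i+1)-CA(i+1) (omega is indexed to the peptide bond
#' *following* residue i). Angles at the chain ends that lack a neighbour are
#' `NA`, as are torsions over collinear atom triplets. omega is wrapped via
#' [wrap_omega()]; phi and psi are reported in `[-180, 180)`.
#'
#' @param chain A `"backbone_chain"` with >= 2 residues.
#' @param delta Wrap origin for omega; default -90.
#' @return A data frame with columns `res`, `phi`, `psi`, `omega` (degrees).
#' @examples
#' measure_dihedrals(build_regular(4, dihedral_state(-57, -47, 180)))
#' @export
measure_dihedrals <- function(chain, delta = -90) {
  if (!inherits(chain, "backbone_chain"))
    stop("chain must be a backbone_chain", call. = FALSE)
  n <- chain$n_residues
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  xyz <- chain$xyz
  at <- function(r, k) xyz[3L * (r - 1L) + k, ]  # k: 1=N, 2=CA, 3=C
  phi <- psi <- omega <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    if (r > 1L)
      phi[r] <- torsion4(at(r - 1L, 3L), at(r, 1L), at(r, 2L), at(r, 3L))
    if (r < n) {
      psi[r] <- torsion4(at(r, 1L), at(r, 2L), at(r, 3L), at(r + 1L, 1L))
      omega[r] <- torsion4(at(r, 2L), at(r, 3L), at(r + 1L, 1L),
                           at(r + 1L, 2L))
    }
  }
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  ok <- !is.na(omega)
  omega[ok] <- wrap_omega(omega[ok], delta)
  data.frame(res = seq_len(n), phi = wrap180(phi), psi = wrap180(psi),
             omega = omega)
}

# Least-squares rigid superposition (Kabsch) of two 3-point sets; returns
# rotation R and translation t with y ~ R %*% x + t.
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

#' Screw decomposition of a regular chain
#'
#' Independent geometric recovery of the helical parameters: computes the
#' rigid transform superposing each residue's (N, CA, C) triplet onto the
#' next residue's, checks that it is constant along the chain, and
#' decomposes it into a rotation by `alpha` about a screw axis plus a
#' translation along that axis. The reported quantities are orientation
#' invariant: `cos_theta = cos(alpha)`, `abs_d` the magnitude of the axial
#' translation, `h = sign(axial translation) * sin(alpha)`, and the
#' distances of the three atom types from the axis. They match the analytic
#' closed forms to within 1e-6 and serve as the package's internal oracle.
#'
#' @param chain A `"backbone_chain"` built from one repeated state, with at
#'   least 4 residues.
#' @param tol Maximum allowed residue-to-residue variation of the transform
#'   before the chain is declared non-regular; default 1e-6.
#' @return A list with `theta` (degrees in (0, 180), the rotation magnitude),
#'   `d` (signed axial translation for the axis orientation with positive
#'   `sin(alpha)`), `abs_d`, `cos_theta`, `h`, and `rho` (named vector of
#'   N/CA/C axis distances, angstroms).
#' @examples
#' screw_decomposition(build_regular(8, dihedral_state(-57, -47, 180)))
#' @export
screw_decomposition <- function(chain, tol = 1e-6) {
  if (!inherits(chain, "backbone_chain"))
    stop("chain must be a backbone_chain", call. = FALSE)
  n <- chain$n_residues
  if (n < 4L) stop("need at least 4 residues", call. = FALSE)
  res_mat <- function(r) chain$xyz[3L * (r - 1L) + 1:3, , drop = FALSE]
  tr <- kabsch(res_mat(1L), res_mat(2L))
  for (r in 2:(n - 1L)) {
    tr2 <- kabsch(res_mat(r), res_mat(r + 1L))
    if (max(abs(tr2$R - tr$R)) > tol || max(abs(tr2$t - tr$t)) > tol)
      stop("chain is not regular: residue-to-residue transform varies by ",
           "more than ", tol, call. = FALSE)
  }
  R <- tr$R
  cos_a <- (sum(diag(R)) - 1) / 2
  cos_a <- pmin(1, pmax(-1, cos_a))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sin_a <- sqrt(sum(w^2)) / 2
  if (sin_a < 1e-3)
    stop("ill-conditioned screw axis: |sin(alpha)| < 1e-3", call. = FALSE)
  u <- w / (2 * sin_a)               # axis with alpha in (0, 180)
  d_axis <- sum(tr$t * u)
  # A point on the axis: solve (I - R) p = t_perp in the plane normal to u.
  t_perp <- tr$t - d_axis * u
  M <- diag(3) - R + u %*% t(u)
  p0 <- solve(M, t_perp)
  axis_dist <- function(x) {
    v <- x - p0
    sqrt(sum((v - sum(v * u) * u)^2))
  }
  r1 <- res_mat(1L)
  alpha <- acos(cos_a) * .rad2deg
  list(theta = alpha, d = d_axis, abs_d = abs(d_axis), cos_theta = cos_a,
       h = sign(d_axis) * sin_a,
       rho = c(rho_n = axis_dist(r1[1L, ]), rho_alpha = axis_dist(r1[2L, ]),
               rho_c = axis_dist(r1[3L, ])))
}

#' Write a chain as a poly-glycine PDB file
#'
#' Emits standard fixed-width ATOM records (chain A, 1-based residue
#' numbering, occupancy 1.00, B-factor 0.00, element column filled).
#' Optionally adds carbonyl oxygen atoms for viewer friendliness (placed at
#' 1.229 angstroms, 120.5 degrees from the CA-C bond, trans to the next
#' nitrogen); oxygens are never used in any computation and are dropped on
#' reading.
#'
#' @param chain A `"backbone_chain"`.
#' @param path Output file path.
#' @param oxygens Add carbonyl O atoms; default `FALSE`.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(chain, path, oxygens = FALSE) {
  if (!inherits(chain, "backbone_chain"))
    stop("chain must be a backbone_chain", call. = FALSE)
  lines <- character(0)
  serial <- 0L
  rec <- function(name, res, xyz, elem) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), "GLY", "A", res,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
  }
  n <- chain$n_residues
  for (r in seq_len(n)) {
    base <- 3L * (r - 1L)
    lines <- c(lines,
               rec("N", r, chain$xyz[base + 1L, ], "N"),
               rec("CA", r, chain$xyz[base + 2L, ], "C"),
               rec("C", r, chain$xyz[base + 3L, ], "C"))
    if (oxygens && r < n) {
      o <- place_atom(chain$xyz[base + 4L, ], chain$xyz[base + 2L, ],
                      chain$xyz[base + 3L, ], 1.229, 120.5, 180)
      lines <- c(lines, rec("O", r, o, "O"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read backbone N/CA/C coordinates from a PDB file
#'
#' Parses ATOM records (via `bio3d::read.pdb`) and extracts the N, CA and C
#' atoms of each residue of one chain, in residue order. Residues missing
#' any of the three backbone atoms are either skipped with a warning
#' (`strict = FALSE`, the default) or raise an error naming the residue.
#'
#' @param path PDB file path.
#' @param chain_id Chain identifier to extract; `NULL` (default) takes the
#'   first chain present.
#' @param strict Fail on residues with missing backbone atoms.
#' @return A `"backbone_chain"` (no generating dihedrals recorded).
#' @export
read_pdb <- function(path, chain_id = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no ATOM records for chain '", chain_id, "'", call. = FALSE)
  res_ids <- unique(at$resno)
  keep <- list()
  for (res in res_ids) {
    sub <- at[at$resno == res, , drop = FALSE]
    rows <- lapply(c("N", "CA", "C"), function(a) {
      hit <- which(sub$elety == a)
      if (length(hit) == 0L) NULL else sub[hit[1L], c("x", "y", "z")]
    })
    if (any(vapply(rows, is.null, logical(1)))) {
      msg <- paste0("residue ", res, " lacks a backbone atom (need N, CA, C)")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; skipping", call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- do.call(rbind, lapply(rows, as.numeric))
  }
  if (length(keep) == 0L)
    stop("no complete residues found in '", path, "'", call. = FALSE)
  xyz <- do.call(rbind, keep)
  colnames(xyz) <- c("x", "y", "z")
  new_chain(xyz, NULL, NULL)
}

#' Per-residue helical analysis of a chain
#'
#' Measures the dihedrals of every residue and evaluates the exact helical
#' parameters and handedness for each complete (phi, psi, omega) triple,
#' treating each residue as locally regular. Residues with incomplete
#' dihedrals (chain ends) get `NA`s.
#'
#' @param chain A `"backbone_chain"`.
#' @param geom A [backbone_geometry()] used for the analytic step.
#' @return A data frame with columns `res`, `phi`, `psi`, `omega`, `d`,
#'   `theta`, `sin_theta`, `h`, `region`.
#' @examples
#' analyze_chain(build_regular(6, dihedral_state(-57, -47, 180)))
#' @export
analyze_chain <- function(chain, geom = backbone_geometry()) {
  dih <- measure_dihedrals(chain)
  out <- data.frame(dih, d = NA_real_, theta = NA_real_,
                    sin_theta = NA_real_, h = NA_real_,
                    region = NA_character_)
  ok <- stats::complete.cases(dih[, c("phi", "psi", "omega")])
  if (any(ok)) {
    hp <- helical_params_exact(dih$phi[ok], dih$psi[ok], dih$omega[ok], geom)
    hv <- handedness_value(hp$d, hp$theta)
    out$d[ok] <- hp$d
    out$theta[ok] <- hp$theta
    out$sin_theta[ok] <- sin(hp$theta * .deg2rad)
    out$h[ok] <- hv$h
    out$region[ok] <- hv$region
  }
  out
}
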