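# Core helical-parameter geometry: exact and simplified closed forms relating
# backbone dihedral angles (phi, psi, omega) to the per-residue axial
# displacement d and angular displacement theta of the equivalent helix.
#
# All public interfaces take and return angles in degrees; radians are used
# only inside the trigonometric kernels.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

#' Backbone stereochemical constants
#'
#' Bundles the six constants that define one repeating unit of a peptide
#' backbone: the three bond lengths N-CA, CA-C, C-N(+1) and the three bond
#' angles at N, CA and C. Defaults are the standard equilibrium
#' (Engh-Huber-type) values used throughout the package.
#'
#' @param v_n_alpha N-CA bond length in angstroms.
#' @param v_alpha_c CA-C bond length in angstroms.
#' @param v_c_n C-N(+1) peptide bond length in angstroms.
#' @param sigma_n Bond angle at the backbone nitrogen (C-N-CA), degrees.
#' @param sigma_alpha Bond angle at the alpha carbon (N-CA-C), degrees.
#' @param sigma_c Bond angle at the carbonyl carbon (CA-C-N), degrees.
#'
#' @return An object of class `"backbone_geometry"`: a named list of the six
#'   validated constants.
#' @examples
#' geom <- backbone_geometry()
#' geom$v_n_alpha
#' @export
backbone_geometry <- function(v_n_alpha = 1.459, v_alpha_c = 1.525,
                              v_c_n = 1.336, sigma_n = 121.7,
                              sigma_alpha = 111.0, sigma_c = 117.2) {
  vals <- c(v_n_alpha = v_n_alpha, v_alpha_c = v_alpha_c, v_c_n = v_c_n,
            sigma_n = sigma_n, sigma_alpha = sigma_alpha, sigma_c = sigma_c)
  if (!all(is.finite(vals)))
    stop("all geometry constants must be finite numbers", call. = FALSE)
  if (any(vals[1:3] <= 0))
    stop("bond lengths must be strictly positive", call. = FALSE)
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180))
    stop("bond angles must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  structure(as.list(vals), class = "backbone_geometry")
}

#' @export
print.backbone_geometry <- function(x, ...) {
  cat("Backbone geometry (lengths in angstroms, angles in degrees)\n")
  cat(sprintf("  N-CA %.3f  CA-C %.3f  C-N %.3f\n",
              x$v_n_alpha, x$v_alpha_c, x$v_c_n))
  cat(sprintf("  sigma_n %.1f  sigma_alpha %.1f  sigma_c %.1f\n",
              x$sigma_n, x$sigma_alpha, x$sigma_c))
  invisible(x)
}

as_backbone_geometry <- function(geom) {
  if (inherits(geom, "backbone_geometry")) return(geom)
  if (is.null(geom)) return(backbone_geometry())
  do.call(backbone_geometry, as.list(geom))
}

#' Wrap the amide dihedral angle into a declared 360-degree window
#'
#' The half-angle structure of the exact helical-parameter equations means
#' that omega and omega + 360 give sign-opposite results, so a single
#' representative must be fixed. This wraps omega into `[delta, delta + 360)`.
#' The default `delta = -90` keeps both the cis (omega = 0 +/- 5) and trans
#' (omega = 180 +/- 5) populations contiguous: cis maps to 0 (never 360) and
#' trans to 180 (never -180).
#'
#' @param omega Amide dihedral angle(s) in degrees (vectorised).
#' @param delta Start of the wrapping window in degrees; default -90.
#' @return Wrapped angle(s) in `[delta, delta + 360)`. Idempotent.
#' @examples
#' wrap_omega(350)   # -10
#' wrap_omega(-180)  # 180
#' @export
wrap_omega <- function(omega, delta = -90) {
  if (!is.numeric(omega) || !all(is.finite(omega)))
    stop("omega must be finite", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("delta must be a single finite number", call. = FALSE)
  ((omega - delta) %% 360) + delta
}

#' One residue's backbone dihedral state
#'
#' Holds a (phi, psi, omega) triple in degrees. phi and psi are wrapped into
#' the declared Ramachandran frame and omega into `[delta, delta + 360)` via
#' [wrap_omega()].
#'
#' @param phi,psi Backbone dihedral angles in degrees.
#' @param omega Amide dihedral angle in degrees; default 180 (trans).
#' @param delta Wrap origin for omega, degrees; default -90.
#' @param frame Lower edge of the phi/psi frame: -180 for `[-180, 180)` or 0
#'   for `[0, 360)`.
#' @return An object of class `"dihedral_state"`.
#' @examples
#' dihedral_state(-57, -47)          # ideal right-handed alpha helix
#' dihedral_state(-80, 80, omega = 0) # a cis backbone
#' @export
dihedral_state <- function(phi, psi, omega = 180, delta = -90, frame = -180) {
  ang <- c(phi = phi, psi = psi, omega = omega)
  if (!all(is.finite(ang)))
    stop("phi, psi and omega must be finite", call. = FALSE)
  if (!frame %in% c(-180, 0))
    stop("frame must be -180 (for [-180,180)) or 0 (for [0,360))",
         call. = FALSE)
  structure(list(phi = ((phi - frame) %% 360) + frame,
                 psi = ((psi - frame) %% 360) + frame,
                 omega = wrap_omega(omega, delta),
                 delta = delta, frame = frame),
            class = "dihedral_state")
}

#' @export
print.dihedral_state <- function(x, ...) {
  cat(sprintf("Dihedral state: phi %.2f, psi %.2f, omega %.2f deg",
              x$phi, x$psi, x$omega),
      sprintf("(frame [%d,%d), omega in [%g,%g))\n",
              x$frame, x$frame + 360, x$delta, x$delta + 360))
  invisible(x)
}

# Accept either a dihedral_state or raw numbers; returns list(phi, psi, omega).
as_dihedrals <- function(state, phi = NULL, psi = NULL, omega = NULL) {
  if (inherits(state, "dihedral_state"))
    return(state[c("phi", "psi", "omega")])
  if (is.list(state)) return(state[c("phi", "psi", "omega")])
  list(phi = state, psi = psi, omega = omega)
}

# The four geometry-only term weights of the exact equations. Each summand of
# the closed forms pairs one of these with a half-angle sine/cosine of
# (+phi+psi+omega), (+phi-psi+omega), (+phi+psi-omega), (-phi+psi+omega).
geom_weights <- function(geom) {
  hn <- geom$sigma_n * .deg2rad / 2
  ha <- geom$sigma_alpha * .deg2rad / 2
  hc <- geom$sigma_c * .deg2rad / 2
  list(
    A = sin(hn) * sin(ha) * sin(hc),
    B = sin(hn) * cos(ha) * cos(hc),
    C = cos(hn) * sin(ha) * cos(hc),
    D = cos(hn) * cos(ha) * sin(hc),
    # length prefactors of the axial-displacement equation, same term order
    LA = (+geom$v_n_alpha + geom$v_alpha_c + geom$v_c_n),
    LB = (+geom$v_n_alpha - geom$v_alpha_c + geom$v_c_n),
    LC = (+geom$v_n_alpha + geom$v_alpha_c - geom$v_c_n),
    LD = (-geom$v_n_alpha + geom$v_alpha_c + geom$v_c_n))
}

# Right-hand side of the exact cos(theta/2) expression. Vectorised over
# phi/psi/omega (degrees).
cos_half_theta_rhs <- function(phi, psi, omega, geom) {
  w <- geom_weights(geom)
  p <- phi * .deg2rad / 2
  q <- psi * .deg2rad / 2
  o <- omega * .deg2rad / 2
  cos(+p + q + o) * w$A -
    cos(+p - q + o) * w$B -
    cos(+p + q - o) * w$C -
    cos(-p + q + o) * w$D
}

# Right-hand side of the exact d*sin(theta/2) expression, angstroms.
d_sin_half_theta_rhs <- function(phi, psi, omega, geom) {
  w <- geom_weights(geom)
  p <- phi * .deg2rad / 2
  q <- psi * .deg2rad / 2
  o <- omega * .deg2rad / 2
  w$LA * sin(+p + q + o) * w$A -
    w$LB * sin(+p - q + o) * w$B -
    w$LC * sin(+p + q - o) * w$C -
    w$LD * sin(-p + q + o) * w$D
}

# Convert the two closed-form right-hand sides into (d, theta). x is
# cos(theta/2), y is d*sin(theta/2). Shared by the exact and simplified paths.
# `partial = TRUE` marks degenerate cells NA instead of erroring (used by
# sweeps over non-physical custom geometries).
dtheta_from_rhs <- function(x, y, partial = FALSE) {
  drift <- abs(x) - 1
  if (any(drift > 1e-12))
    stop("cos(theta/2) left [-1, 1] by more than 1e-12; ",
         "inconsistent geometry or corrupted input", call. = FALSE)
  x <- pmin(1, pmax(-1, x))
  half <- acos(x)              # radians, [0, pi]
  s <- sin(half)
  bad <- s < 1e-12             # theta ~ 0 or ~ 360: axis direction undefined
  if (any(bad)) {
    if (!partial)
      stop("degenerate geometry: theta is 0 (mod 360), so the axial ",
           "displacement d is undefined", call. = FALSE)
    s[bad] <- NA_real_
  }
  data.frame(d = y / s, theta = 2 * half * .rad2deg)
}

#' Exact helical parameters of a regular backbone
#'
#' Evaluates the exact closed forms for the per-residue angular displacement
#' theta and axial displacement d of the helix traced by a regular backbone
#' with dihedrals (phi, psi, omega) and stereochemistry `geom`. theta is
#' recovered as `2*acos(x)` with the cosine clamped to `[-1, 1]` when within
#' 1e-12 of the boundary; d as the axial right-hand side divided by
#' `sin(theta/2)`.
#'
#' Mirror antisymmetry holds exactly: `(-phi, -psi, -omega)` gives the same
#' theta and a negated d. theta = 0 (mod 360) makes d undefined and raises an
#' error; such conformations are unattainable for physical backbone geometry.
#'
#' @param phi,psi Dihedral angles in degrees (vectorised), or a
#'   `"dihedral_state"` as the first argument.
#' @param omega Amide dihedral in degrees, assumed already wrapped (see
#'   [wrap_omega()]); default 180.
#' @param geom A [backbone_geometry()].
#' @return A data frame with columns `d` (angstroms, signed) and `theta`
#'   (degrees in `[0, 360)`).
#' @examples
#' helical_params_exact(-57, -47, 180)    # ~3.6 residues/turn, ~1.56 A rise
#' helical_params_exact(-100, -100, 180)  # negative d: left-handed twist
#' @export
helical_params_exact <- function(phi, psi, omega = 180,
                                 geom = backbone_geometry()) {
  if (inherits(phi, "dihedral_state")) {
    st <- as_dihedrals(phi)
  } else {
    st <- list(phi = phi, psi = psi, omega = omega)
  }
  if (!all(is.finite(c(st$phi, st$psi, st$omega))))
    stop("phi, psi and omega must be finite", call. = FALSE)
  geom <- as_backbone_geometry(geom)
  dtheta_from_rhs(cos_half_theta_rhs(st$phi, st$psi, st$omega, geom),
                  d_sin_half_theta_rhs(st$phi, st$psi, st$omega, geom))
}

# Printed two-coefficient reductions at equilibrium geometry. Row order:
# (coef of basis1, coef of basis2) for cos(theta/2), then for d*sin(theta/2).
# trans uses sin/sin then cos/cos of (phi+psi)/2 and (phi-psi)/2; cis the
# converse.
.simplified_published <- list(
  trans = list(theta = c(-0.8235, 0.0222), d = c(2.9986, -0.6575)),
  cis   = list(theta = c(0.4052, -0.4932), d = c(2.3093, 0.0028)))

#' Simplified helical parameters from the published two-coefficient forms
#'
#' Evaluates the simplified closed forms obtained by substituting equilibrium
#' bond lengths and angles into the exact equations at omega = 180 (trans) or
#' omega = 0 (cis), using the published four coefficients verbatim. Agrees
#' with [helical_params_exact()] at the default geometry to within the
#' coefficient rounding (about 2e-3 on `cos(theta/2)` and on
#' `d*sin(theta/2)`).
#'
#' @param phi,psi Dihedral angles in degrees (vectorised).
#' @param mode `"trans"` (omega = 180) or `"cis"` (omega = 0).
#' @return A data frame with columns `d` (angstroms) and `theta` (degrees).
#' @examples
#' helical_params_simplified(-57, -47, "trans")
#' helical_params_simplified(0, 0, "trans")  # theta = 180, d = 2.3411
#' @export
helical_params_simplified <- function(phi, psi, mode = c("trans", "cis")) {
  mode <- match.arg(mode)
  if (!all(is.finite(c(phi, psi))))
    stop("phi and psi must be finite", call. = FALSE)
  s <- (phi + psi) * .deg2rad / 2
  t <- (phi - psi) * .deg2rad / 2
  k <- .simplified_published[[mode]]
  if (mode == "trans") {
    x <- k$theta[1] * sin(s) + k$theta[2] * sin(t)
    y <- k$d[1] * cos(s) + k$d[2] * cos(t)
  } else {
    x <- k$theta[1] * cos(s) + k$theta[2] * cos(t)
    y <- k$d[1] * sin(s) + k$d[2] * sin(t)
  }
  dtheta_from_rhs(x, y)
}

#' Re-derive the simplified-form coefficients from an arbitrary geometry
#'
#' Reduces the exact equations at a fixed omega to their two-coefficient
#' forms by evaluating them at basis points of `s = (phi+psi)/2` and
#' `t = (phi-psi)/2` and solving the resulting linear systems; no symbolic
#' algebra is involved. A two-term reduction exists only when omega is 0 or
#' 180 (mod 360): there the half-angle factor `sin(omega/2)` or
#' `cos(omega/2)` kills one of the two basis pairs. For trans-like omega the
#' `cos(theta/2)` form uses the sine pair and the `d*sin(theta/2)` form the
#' cosine pair; for cis-like omega the pairing is reversed.
#'
#' With the default geometry this reproduces the published coefficients
#' (-0.8235, 0.0222, 2.9986, -0.6575 for trans; 0.4052, -0.4932, 2.3093,
#' 0.0028 for cis) to four decimal places before rounding.
#'
#' @param omega Amide dihedral in degrees; must be 0 or 180 modulo 360
#'   (within `tol`).
#' @param geom A [backbone_geometry()].
#' @param tol Tolerance (degrees) on omega being exactly cis/trans.
#' @return Named numeric vector `c(a_cos, b_cos, a_d, b_d)`: the
#'   coefficients of the first and second basis function of the
#'   `cos(theta/2)` form, then of the `d*sin(theta/2)` form. The basis pair
#'   used for each form is recorded in the `"basis"` attribute.
#' @examples
#' round(derive_simplified_coefficients(180), 4)
#' round(derive_simplified_coefficients(0), 4)
#' @export
derive_simplified_coefficients <- function(omega, geom = backbone_geometry(),
                                           tol = 1e-9) {
  geom <- as_backbone_geometry(geom)
  if (!is.finite(omega)) stop("omega must be finite", call. = FALSE)
  half <- omega * .deg2rad / 2
  trans_like <- abs(cos(half)) <= sin(tol * .deg2rad / 2) + 1e-15
  cis_like <- abs(sin(half)) <= sin(tol * .deg2rad / 2) + 1e-15
  if (!trans_like && !cis_like)
    stop("a two-coefficient reduction exists only for omega = 0 or 180 ",
         "(mod 360); got omega = ", omega, call. = FALSE)

  # Basis points expressed as (phi, psi) giving (s, t) = (90,0), (0,90),
  # (0,0) and (180,0). Evaluating the exact forms there isolates each
  # coefficient: the sine pair reads off directly at (90,0)/(0,90); the
  # cosine pair is the 2x2 system { a + b, -a + b } at (0,0)/(180,0).
  eval_pair <- function(f, pair) {
    if (pair == "sin") {
      c(f(90, 90), f(90, -90))
    } else {
      f00 <- f(0, 0)
      f180 <- f(180, 180)
      m <- matrix(c(1, -1, 1, 1), 2, 2)  # rows: cos(s),cos(t) at s=0;180, t=0
      if (abs(det(m)) < 1e-12)
        stop("singular basis system", call. = FALSE)
      as.numeric(solve(m, c(f00, f180)))
    }
  }
  f_theta <- function(p, q) cos_half_theta_rhs(p, q, omega, geom)
  f_d <- function(p, q) d_sin_half_theta_rhs(p, q, omega, geom)
  theta_basis <- if (trans_like) "sin" else "cos"
  d_basis <- if (trans_like) "cos" else "sin"
  out <- c(eval_pair(f_theta, theta_basis), eval_pair(f_d, d_basis))
  names(out) <- c("a_cos", "b_cos", "a_d", "b_d")
  attr(out, "basis") <- c(cos_half_theta = theta_basis,
                          d_sin_half_theta = d_basis)
  out
}

#' Distance between adjacent backbone atoms of the same type
#'
#' For a regular backbone, adjacent atoms of one type (say consecutive alpha
#' carbons) are separated by a distance fixed by the six stereochemical
#' constants and a single dihedral: omega for alpha carbons, phi for carbonyl
#' carbons and psi for nitrogens. This is the square root of the quantity
#' that also equals `2*rho^2*(1 - cos(theta)) + d^2` for that atom type's
#' helix radius rho.
#'
#' @param state A `"dihedral_state"`, or a list with elements `phi`, `psi`,
#'   `omega` (degrees; only the one relevant to `atom_type` is used).
#' @param geom A [backbone_geometry()].
#' @param atom_type `"alpha"`, `"c"` or `"n"`.
#' @return Distance in angstroms (vectorised over the relevant dihedral).
#' @examples
#' same_type_distance(dihedral_state(-57, -47, 180))           # ~3.8 A
#' same_type_distance(list(phi = 0, psi = 0, omega = 0))       # ~2.8 A (cis)
#' @export
same_type_distance <- function(state, geom = backbone_geometry(),
                               atom_type = c("alpha", "c", "n")) {
  atom_type <- match.arg(atom_type)
  geom <- as_backbone_geometry(geom)
  st <- as_dihedrals(state)
  # Subscript cycling: the base formula is written for alpha carbons in terms
  # of (v_alpha_c, v_c_n, v_n_alpha, sigma_c, sigma_n, tau = omega); the
  # cycles (alpha->c, c->n, n->alpha) and (alpha->n, c->alpha, n->c) give the
  # carbonyl-carbon (tau = phi) and nitrogen (tau = psi) versions.
  par <- switch(atom_type,
    alpha = list(v1 = geom$v_alpha_c, v2 = geom$v_c_n, v3 = geom$v_n_alpha,
                 s_c = geom$sigma_c, s_n = geom$sigma_n, tau = st$omega),
    c     = list(v1 = geom$v_c_n, v2 = geom$v_n_alpha, v3 = geom$v_alpha_c,
                 s_c = geom$sigma_n, s_n = geom$sigma_alpha, tau = st$phi),
    n     = list(v1 = geom$v_n_alpha, v2 = geom$v_alpha_c, v3 = geom$v_c_n,
                 s_c = geom$sigma_alpha, s_n = geom$sigma_c, tau = st$psi))
  if (is.null(par$tau) || !all(is.finite(par$tau)))
    stop("the dihedral relevant to atom_type '", atom_type,
         "' is missing or non-finite", call. = FALSE)
  cc <- cos(par$s_c * .deg2rad); cn <- cos(par$s_n * .deg2rad)
  sq <- par$v1^2 + par$v2^2 + par$v3^2 -
    2 * par$v2 * (par$v1 * cc + par$v3 * cn) +
    2 * par$v1 * par$v3 *
      (cc * cn - sin(par$s_c * .deg2rad) * sin(par$s_n * .deg2rad) *
         cos(par$tau * .deg2rad))
  sqrt(sq)
}

#' Helix radii of the three backbone atom types
#'
#' Given the helical parameters (d, theta) of a regular backbone, the radius
#' of the cylinder hosting all atoms of one type is
#' `sqrt((d_i^2 - d^2) / (2 - 2*cos(theta)))`, where `d_i` is the
#' [same_type_distance()] of that type. If `d` and `theta` are omitted they
#' are computed from the exact equations.
#'
#' @param state A `"dihedral_state"` or list with `phi`, `psi`, `omega`.
#' @param geom A [backbone_geometry()].
#' @param d,theta Optional helical parameters (angstroms / degrees);
#'   computed from `state` when `NULL`.
#' @param types Atom types to report; default all three.
#' @return Named numeric vector of radii (`rho_n`, `rho_alpha`, `rho_c` for
#'   the requested types) in angstroms. A radicand below -1e-9 signals an
#'   inconsistent (d, theta); within 1e-9 of zero it is clamped to 0.
#' @examples
#' helix_radii(dihedral_state(-57, -47, 180))  # rho_alpha ~ 2.29 A
#' @export
helix_radii <- function(state, geom = backbone_geometry(), d = NULL,
                        theta = NULL, types = c("n", "alpha", "c")) {
  geom <- as_backbone_geometry(geom)
  st <- as_dihedrals(state)
  if (is.null(d) || is.null(theta)) {
    hp <- helical_params_exact(st$phi, st$psi, st$omega, geom)
    d <- hp$d
    theta <- hp$theta
  }
  denom <- 2 - 2 * cos(theta * .deg2rad)
  if (denom < 1e-15)
    stop("theta is 0 (mod 360): helix radii are undefined", call. = FALSE)
  one <- function(type) {
    di <- same_type_distance(st, geom, type)
    rad <- (di^2 - d^2) / denom
    if (rad < -1e-9)
      stop("negative squared radius for atom type '", type,
           "': (d, theta) are inconsistent with this geometry",
           call. = FALSE)
    sqrt(max(rad, 0))
  }
  types <- match.arg(types, several.ok = TRUE)
  out <- vapply(types, one, numeric(1))
  names(out) <- paste0("rho_", types)
  out
}

#' All helical parameters of one backbone state
#'
#' Convenience wrapper returning d, theta, the three helix radii and the
#' handedness classification for a single (phi, psi, omega) state.
#'
#' @inheritParams helix_radii
#' @param mode `"exact"` or `"simplified"` (published trans/cis
#'   coefficients; requires omega 0 or 180).
#' @return A list of class `"helical_params"` with elements `d`, `theta`,
#'   `rho_n`, `rho_alpha`, `rho_c`, `sin_theta`, `h` (NA when undefined) and
#'   `region`.
#' @examples
#' helical_params(dihedral_state(-57, -47, 180))
#' @export
helical_params <- function(state, geom = backbone_geometry(),
                           mode = c("exact", "simplified")) {
  mode <- match.arg(mode)
  geom <- as_backbone_geometry(geom)
  st <- as_dihedrals(state)
  if (mode == "exact") {
    hp <- helical_params_exact(st$phi, st$psi, st$omega, geom)
  } else {
    m <- omega_mode(st$omega)
    hp <- helical_params_simplified(st$phi, st$psi, m)
  }
  rho <- helix_radii(st, geom, hp$d, hp$theta)
  hv <- handedness_value(hp$d, hp$theta)
  structure(c(list(d = hp$d, theta = hp$theta), as.list(rho),
              list(sin_theta = sin(hp$theta * .deg2rad),
                   h = hv$h, region = as.character(hv$region))),
            class = "helical_params")
}

# Map a wrapped omega onto the simplified-form mode, erroring otherwise.
omega_mode <- function(omega, tol = 1e-9) {
  if (abs(wrap_omega(omega) - 180) <= tol) return("trans")
  if (abs(wrap_omega(omega)) <= tol) return("cis")
  stop("simplified mode requires omega = 0 (cis) or 180 (trans); got ",
       omega, call. = FALSE)
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("Helical parameters: d %.4f A, theta %.4f deg (%.2f res/turn)\n",
              x$d, x$theta, 360 / x$theta))
  cat(sprintf("  radii (N, CA, C): %.4f %.4f %.4f A\n",
              x$rho_n, x$rho_alpha, x$rho_c))
  h <- if (is.na(x$h)) "undefined" else sprintf("%.4f", x$h)
  cat(sprintf("  handedness h = %s (%s)\n", h, x$region))
  invisible(x)
}
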