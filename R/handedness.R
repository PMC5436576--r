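# Backbone twist handedness h = sgn(d) * sin(theta) and the four-quadrant
# classification of (d, theta) space.

#' Handedness of a helix from its (d, theta) parameters
#'
#' Computes `h = (d / |d|) * sin(theta)` and classifies the conformation.
#' h ranges over `[-1, 1]`: negative values are left-handed twists, positive
#' right-handed, and |h| measures the extent of twist. Two special flat
#' families exist: at d = 0 the backbone is perfectly flat and maximally
#' curved (ring-like) and `|d|^-1` makes h undefined (returned as `NA`,
#' region `"flat_circular"`); at theta = 180 the backbone is flat and
#' optimally extended, h = 0 (region `"flat_extended"`).
#'
#' The two equivalent screw representations `(d, theta)` and
#' `(-d, 360 - theta)` give identical h.
#'
#' @param d Axial displacement(s), angstroms (signed). Vectorised.
#' @param theta Angular displacement(s), degrees in `[0, 360)`.
#' @param eps_d Tolerance on |d| below which h is undefined; default 1e-9 A.
#' @param eps_theta Tolerance on |sin(theta)| below which the conformation is
#'   classified flat-extended; default 1e-9.
#' @return A data frame with columns `h` (numeric, `NA` when undefined) and
#'   `region` (`"right"`, `"left"`, `"flat_extended"` or `"flat_circular"`).
#' @examples
#' handedness_value(1, 90)    # h = +1, right
#' handedness_value(-1, 90)   # h = -1, left
#' handedness_value(2, 180)   # h = 0, flat_extended
#' handedness_value(0, 150)   # undefined, flat_circular
#' @export
handedness_value <- function(d, theta, eps_d = 1e-9, eps_theta = 1e-9) {
  if (!all(is.finite(d)) || !all(is.finite(theta)))
    stop("d and theta must be finite", call. = FALSE)
  if (any(theta < 0 | theta >= 360))
    stop("theta must lie in [0, 360) degrees", call. = FALSE)
  n <- max(length(d), length(theta))
  d <- rep_len(d, n)
  theta <- rep_len(theta, n)
  st <- sin(theta * .deg2rad)
  h <- sign(d) * st
  region <- ifelse(h > 0, "right", ifelse(h < 0, "left", "flat_extended"))
  flat <- abs(st) <= eps_theta
  h[flat] <- 0
  region[flat] <- "flat_extended"
  undef <- abs(d) <= eps_d
  h[undef] <- NA_real_
  region[undef] <- "flat_circular"
  data.frame(h = h, region = region)
}

#' Handedness of a backbone dihedral state
#'
#' Composes the helical-parameter equations with [handedness_value()]:
#' computes (d, theta) for each (phi, psi, omega) and returns h with its
#' region label.
#'
#' @param phi,psi Dihedral angles in degrees (vectorised), or a
#'   `"dihedral_state"` as the first argument.
#' @param omega Amide dihedral, degrees (wrapped); default 180.
#' @param geom A [backbone_geometry()].
#' @param mode `"exact"` equations or the `"simplified"` published
#'   trans/cis forms (omega must then be 0 or 180).
#' @return A data frame with columns `d`, `theta`, `h`, `region`.
#' @examples
#' backbone_handedness(-57, -47)        # right-handed alpha helix, h ~ +0.99
#' backbone_handedness(-100, -100)      # left-handed, h ~ -0.95
#' @export
backbone_handedness <- function(phi, psi, omega = 180,
                                geom = backbone_geometry(),
                                mode = c("exact", "simplified")) {
  mode <- match.arg(mode)
  if (inherits(phi, "dihedral_state")) {
    st <- as_dihedrals(phi)
  } else {
    st <- list(phi = phi, psi = psi, omega = omega)
  }
  if (mode == "exact") {
    hp <- helical_params_exact(st$phi, st$psi, st$omega, geom)
  } else {
    hp <- helical_params_simplified(st$phi, st$psi, omega_mode(st$omega[1]))
  }
  cbind(hp, handedness_value(hp$d, hp$theta))
}
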