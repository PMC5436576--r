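# Ramachandran-space surveys of helical parameters and handedness, boundary
# curve extraction, sign-region counting, frame conversion and the Cartesian
# (theta, d) envelope.

parse_frame <- function(frame) {
  if (is.character(frame)) {
    parts <- suppressWarnings(as.numeric(strsplit(frame, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || any(!is.finite(parts)))
      stop("frame string must look like 'lo:hi', e.g. '-180:180'",
           call. = FALSE)
    frame <- parts
  }
  frame <- as.numeric(frame)
  if (length(frame) == 1L) frame <- c(frame, frame + 360)
  if (length(frame) != 2L || frame[2] - frame[1] != 360)
    stop("frame must span exactly 360 degrees (lo, lo + 360)", call. = FALSE)
  frame
}

#' Survey helical parameters over a Ramachandran grid
#'
#' Evaluates (d, theta, sin(theta), h, region) at every node of a square
#' (phi, psi) grid for one fixed (wrapped) omega. Endpoints are inclusive at
#' both edges, so the default 2-degree grid over `[-180, 180]` has 181 x 181
#' cells with a duplicated seam, matching the conventional printed grid
#' `{-180, -178, ..., 178, 180}`. Cells where h is undefined (d = 0) are
#' flagged, not dropped. Fully deterministic.
#'
#' @param omega Amide dihedral in degrees (wrapped via [wrap_omega()]).
#' @param step Grid spacing in degrees; must divide 360. Default 2.
#' @param frame Frame of the grid: `c(-180, 180)`, `c(0, 360)` or a
#'   `"lo:hi"` string.
#' @param geom A [backbone_geometry()].
#' @param mode `"exact"` or `"simplified"` (the latter requires omega 0 or
#'   180).
#' @return An object of class `"rama_grid"`: list with `omega`, `step`,
#'   `frame`, `mode` and `cells`, a data frame with columns `phi`, `psi`,
#'   `d`, `theta`, `sin_theta`, `h`, `region`.
#' @examples
#' g <- rama_grid(180, step = 30)
#' subset(g$cells, phi == -60 & psi == -60)
#' @export
rama_grid <- function(omega = 180, step = 2, frame = c(-180, 180),
                      geom = backbone_geometry(),
                      mode = c("exact", "simplified")) {
  mode <- match.arg(mode)
  frame <- parse_frame(frame)
  if (!is.finite(step) || step <= 0 || (360 / step) %% 1 != 0)
    stop("step must be a positive divisor of 360", call. = FALSE)
  omega <- wrap_omega(omega)
  ax <- seq(frame[1], frame[2], by = step)
  cells <- expand.grid(phi = ax, psi = ax, KEEP.OUT.ATTRS = FALSE)
  if (mode == "exact") {
    hp <- helical_params_exact(cells$phi, cells$psi, omega, geom)
  } else {
    hp <- helical_params_simplified(cells$phi, cells$psi, omega_mode(omega))
  }
  hv <- handedness_value(hp$d, hp$theta)
  cells <- cbind(cells, hp,
                 sin_theta = sin(hp$theta * .deg2rad), hv)
  structure(list(omega = omega, step = step, frame = frame, mode = mode,
                 geom = as_backbone_geometry(geom), cells = cells),
            class = "rama_grid")
}

#' @export
print.rama_grid <- function(x, ...) {
  cat(sprintf(
    "Ramachandran survey: omega %g deg, step %g deg, frame [%g, %g], %s mode\n",
    x$omega, x$step, x$frame[1], x$frame[2], x$mode))
  cat(sprintf("  %d cells; regions: %s\n", nrow(x$cells),
              paste(names(table(x$cells$region)), table(x$cells$region),
                    collapse = ", ", sep = " ")))
  invisible(x)
}

#' Image plot of a handedness survey
#'
#' @param x A `"rama_grid"`.
#' @param what Cell column to plot; default `"h"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.rama_grid <- function(x, what = "h", ...) {
  ax <- seq(x$frame[1], x$frame[2], by = x$step)
  z <- matrix(x$cells[[what]], nrow = length(ax))
  graphics::image(ax, ax, z, xlab = expression(phi), ylab = expression(psi),
                  main = sprintf("%s at omega = %g", what, x$omega), ...)
  invisible(x)
}

# Field values used for boundary extraction: smooth scalars whose zero sets
# are theta = 180 (cos(theta/2) = 0) and d = 0 (d*sin(theta/2) = 0), free of
# branch artifacts at the theta wrap.
grid_fields <- function(grid) {
  ax <- seq(grid$frame[1], grid$frame[2], by = grid$step)
  if (grid$mode == "exact") {
    f <- function(p, q) cos_half_theta_rhs(p, q, grid$omega, grid$geom)
    g <- function(p, q) d_sin_half_theta_rhs(p, q, grid$omega, grid$geom)
  } else {
    m <- omega_mode(grid$omega)
    f <- function(p, q) {
      k <- .simplified_published[[m]]$theta
      s <- (p + q) * .deg2rad / 2; t <- (p - q) * .deg2rad / 2
      if (m == "trans") k[1] * sin(s) + k[2] * sin(t)
      else k[1] * cos(s) + k[2] * cos(t)
    }
    g <- function(p, q) {
      k <- .simplified_published[[m]]$d
      s <- (p + q) * .deg2rad / 2; t <- (p - q) * .deg2rad / 2
      if (m == "trans") k[1] * cos(s) + k[2] * cos(t)
      else k[1] * sin(s) + k[2] * sin(t)
    }
  }
  pp <- outer(ax, ax, function(a, b) a)
  qq <- outer(ax, ax, function(a, b) b)
  list(ax = ax, theta_pi = matrix(f(pp, qq), nrow = length(ax)),
       d_zero = matrix(g(pp, qq), nrow = length(ax)))
}

#' Extract the d = 0 and theta = 180 boundary curves of a survey
#'
#' Traces the zero contours of the smooth fields `cos(theta/2)` (whose zero
#' set is theta = 180 degrees: flat, optimally extended backbones) and
#' `d*sin(theta/2)` (zero set d = 0: flat, maximally curved backbones) over
#' the survey grid, using marching-squares linear interpolation on grid
#' edges. For a trans survey the two families never intersect; on a cis
#' survey they approach intersection near `phi = -psi ~ +/-35` degrees.
#'
#' @param grid A [rama_grid()].
#' @return A data frame of class `"boundary_curves"` with columns `kind`
#'   (`"d_zero"` or `"theta_pi"`), `segment_id`, `phi`, `psi`. May be empty.
#' @examples
#' bc <- boundary_curves(rama_grid(180, step = 10))
#' table(bc$kind)
#' @export
boundary_curves <- function(grid) {
  if (!inherits(grid, "rama_grid"))
    stop("grid must be a rama_grid", call. = FALSE)
  fl <- grid_fields(grid)
  seg <- function(z, kind) {
    cl <- grDevices::contourLines(fl$ax, fl$ax, z, levels = 0)
    if (length(cl) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(cl), function(i) {
      data.frame(kind = kind, segment_id = i, phi = cl[[i]]$x,
                 psi = cl[[i]]$y)
    }))
  }
  out <- rbind(seg(fl$theta_pi, "theta_pi"), seg(fl$d_zero, "d_zero"))
  if (is.null(out))
    out <- data.frame(kind = character(), segment_id = integer(),
                      phi = numeric(), psi = numeric())
  class(out) <- c("boundary_curves", "data.frame")
  out
}

#' Count connected regions of constant handedness sign
#'
#' Labels the 4-connected components of `sign(h)` over the survey grid as
#' plotted (no periodic wrap-around). Cells with undefined h or
#' `|h| <= 1e-12` are excluded from every component, as is the duplicated
#' seam row/column of an inclusive-endpoint grid (to avoid double counting).
#'
#' @param grid A [rama_grid()].
#' @return A list with `n_regions` and `sizes` (cell count per component,
#'   named by handedness sign).
#' @examples
#' count_sign_regions(rama_grid(180, step = 10))$n_regions  # >= 4
#' @export
count_sign_regions <- function(grid) {
  if (!inherits(grid, "rama_grid"))
    stop("grid must be a rama_grid", call. = FALSE)
  ax <- seq(grid$frame[1], grid$frame[2], by = grid$step)
  m <- length(ax)
  h <- matrix(grid$cells$h, nrow = m)      # [phi, psi]
  sgn <- matrix(0L, m, m)
  sgn[!is.na(h) & h > 1e-12] <- 1L
  sgn[!is.na(h) & h < -1e-12] <- -1L
  drop_seam <- m >= 2L && isTRUE(all.equal(ax[m], ax[1] + 360))
  nr <- if (drop_seam) m - 1L else m
  sgn <- sgn[seq_len(nr), seq_len(nr), drop = FALSE]
  labels <- matrix(0L, nr, nr)
  nlab <- 0L
  sizes <- integer(0)
  signs <- integer(0)
  queue <- integer(nr * nr)
  for (start in which(sgn != 0L & labels == 0L)) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    target <- sgn[start]
    qhead <- 1L; qtail <- 1L
    queue[1L] <- start
    labels[start] <- nlab
    count <- 0L
    while (qhead <= qtail) {
      cell <- queue[qhead]; qhead <- qhead + 1L
      count <- count + 1L
      i <- ((cell - 1L) %% nr) + 1L
      j <- ((cell - 1L) %/% nr) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                      c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > nr) next
        idx <- (nb[2] - 1L) * nr + nb[1]
        if (labels[idx] == 0L && sgn[idx] == target) {
          labels[idx] <- nlab
          qtail <- qtail + 1L
          queue[qtail] <- idx
        }
      }
    }
    sizes <- c(sizes, count)
    signs <- c(signs, target)
  }
  names(sizes) <- ifelse(signs > 0, "right", "left")
  list(n_regions = nlab, sizes = sizes)
}

#' Re-express a survey in the other Ramachandran frame
#'
#' Pure re-indexing: each cell's phi and psi labels are shifted by a
#' multiple of 360 degrees to land in the target frame; no helical parameter
#' is recomputed, so the multiset of (d, theta, h) values is unchanged.
#' Because an inclusive-endpoint grid carries a duplicated seam, the seam of
#' the source frame is collapsed on conversion and the target frame's seam
#' is re-duplicated from its own first row/column; at those seam cells the
#' stored (d, theta) may be the equivalent screw representation
#' `(-d, 360 - theta)` of a direct evaluation, with identical h.
#'
#' @param grid A [rama_grid()].
#' @param target_frame Target frame, e.g. `c(0, 360)` or `"0:360"`.
#' @return A `"rama_grid"` in the target frame.
#' @examples
#' g <- frame_convert(rama_grid(180, step = 30), c(0, 360))
#' @export
frame_convert <- function(grid, target_frame) {
  if (!inherits(grid, "rama_grid"))
    stop("grid must be a rama_grid", call. = FALSE)
  target <- parse_frame(target_frame)
  if ((target[1] - grid$frame[1]) %% grid$step != 0)
    stop("target frame is not commensurate with the grid step",
         call. = FALSE)
  lo <- target[1]
  cells <- grid$cells
  cells$phi <- ((cells$phi - lo) %% 360) + lo
  cells$psi <- ((cells$psi - lo) %% 360) + lo
  # collapse duplicates created by the source seam, keep first occurrence
  cells <- cells[!duplicated(cells[, c("phi", "psi")]), , drop = FALSE]
  cells <- cells[order(cells$psi, cells$phi), , drop = FALSE]
  # re-duplicate the target seam (phi or psi = lo copied to lo + 360)
  hi_phi <- cells[cells$phi == lo, , drop = FALSE]
  hi_phi$phi <- lo + 360
  hi_psi <- cells[cells$psi == lo, , drop = FALSE]
  hi_psi$psi <- lo + 360
  corner <- cells[cells$phi == lo & cells$psi == lo, , drop = FALSE]
  if (nrow(corner)) { corner$phi <- lo + 360; corner$psi <- lo + 360 }
  cells <- rbind(cells, hi_phi, hi_psi, corner)
  cells <- cells[order(cells$psi, cells$phi), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(omega = grid$omega, step = grid$step, frame = target,
                 mode = grid$mode, geom = grid$geom, cells = cells),
            class = "rama_grid")
}

#' Attainable (theta, d) envelope for a band of omega values
#'
#' Sweeps the full (phi, psi) grid across `omega` in
#' `[center - halfwidth, center + halfwidth]` and collects the attainable
#' (theta, d, h) triplets for the universal Cartesian (theta, d) map. The
#' trans band never attains theta = 0 nor the point (theta, d) = (180, 0);
#' the cis band does contain near-(180, 0) points, the two-residue-ring
#' conformations unique to cis backbones.
#'
#' @param omega_center Centre of the omega band, degrees.
#' @param omega_halfwidth Half-width of the band, degrees (>= 0); default 5.
#' @param step (phi, psi) grid spacing, degrees; default 5.
#' @param omega_step Spacing of the omega sweep, degrees; default 1.
#' @param geom A [backbone_geometry()].
#' @return A data frame of class `"thetad_envelope"` with columns `phi`,
#'   `psi`, `omega`, `theta`, `d`, `h`.
#' @examples
#' env <- thetad_envelope(180, 0, step = 30)
#' range(env$theta)
#' @export
thetad_envelope <- function(omega_center, omega_halfwidth = 5, step = 5,
                            omega_step = 1, geom = backbone_geometry()) {
  if (omega_halfwidth < 0) stop("halfwidth must be >= 0", call. = FALSE)
  omegas <- wrap_omega(seq(omega_center - omega_halfwidth,
                           omega_center + omega_halfwidth,
                           by = if (omega_halfwidth > 0) omega_step else 1))
  omegas <- unique(omegas)
  ax <- seq(-180, 180, by = step)
  base <- expand.grid(phi = ax, psi = ax, KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(omegas, function(om) {
    hp <- helical_params_exact(base$phi, base$psi, om, geom)
    hv <- handedness_value(hp$d, hp$theta)
    data.frame(base, omega = om, theta = hp$theta, d = hp$d, h = hv$h)
  }))
  rownames(out) <- NULL
  class(out) <- c("thetad_envelope", "data.frame")
  out
}

# ---- CSV serialisation with the external column conventions ----

#' Write survey objects as CSV
#'
#' Serialises surveys with stable, unit-suffixed column names:
#' map CSVs carry `phi_deg, psi_deg, omega_deg, theta_deg, d_angstrom,
#' sin_theta, h, region`; boundary CSVs `kind, segment_id, phi_deg,
#' psi_deg`; envelope CSVs `theta_deg, d_angstrom, h`. Output is
#' deterministic (byte-identical across runs).
#'
#' @param x A `"rama_grid"`, `"boundary_curves"` or `"thetad_envelope"`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_survey_csv <- function(x, path) {
  if (inherits(x, "rama_grid")) {
    out <- data.frame(phi_deg = x$cells$phi, psi_deg = x$cells$psi,
                      omega_deg = x$omega, theta_deg = x$cells$theta,
                      d_angstrom = x$cells$d, sin_theta = x$cells$sin_theta,
                      h = x$cells$h, region = x$cells$region)
  } else if (inherits(x, "boundary_curves")) {
    out <- data.frame(kind = x$kind, segment_id = x$segment_id,
                      phi_deg = x$phi, psi_deg = x$psi)
  } else if (inherits(x, "thetad_envelope")) {
    out <- data.frame(theta_deg = x$theta, d_angstrom = x$d, h = x$h)
  } else {
    stop("unsupported object for CSV serialisation", call. = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
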