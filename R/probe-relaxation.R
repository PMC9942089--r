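# N/m -> eV/Angstrom^2
NM_TO_EV_A2 <- 16.0217663

#' CO probe tip model
#'
#' The CO probe hangs a lever arm `delta` below the tip pivot (the
#' outermost metal atom); lateral forces tilt it by a polar angle theta
#' against a torsional spring of stiffness `kappa`.  `kappa` is quoted
#' in N/m, the experimentally reported effective lateral stiffness.
#'
#' @param kappa torsional/lateral stiffness, N/m (typical 0.4-1.0)
#' @param delta lever arm, Angstrom (default 3.02)
#' @return object of class `afm_tip_model`
#' @export
tip_model <- function(kappa = 0.4, delta = 3.02) {
  stopifnot(kappa > 0, delta > 0)
  structure(list(kappa = kappa, delta = delta), class = "afm_tip_model")
}

kappa_ev_a2 <- function(tip) tip$kappa / NM_TO_EV_A2

#' Torsional spring energy of a tilted probe
#'
#' `E = 0.5 * kappa * (delta * theta)^2`, with `kappa` converted from
#' N/m to eV/Angstrom^2.
#'
#' @param theta polar tilt angle, rad, in `[0, pi/2)`
#' @param tip an [tip_model()]
#' @return energy, eV
#' @export
tilt_energy <- function(theta, tip = tip_model()) {
  stopifnot(all(theta >= 0), all(theta < pi / 2))
  0.5 * kappa_ev_a2(tip) * (tip$delta * theta)^2
}

#' Scan configuration
#'
#' @param dz z step of the approach, Angstrom (default 0.1)
#' @param force_tol convergence threshold on the generalized force norm,
#'   eV/Angstrom (default 1e-6)
#' @param max_iter relaxation iteration cap per step
#' @param heights constant-height image heights, Angstrom, strictly
#'   increasing (measured from the mean atomic plane to the probe's
#'   closest approach)
#' @param pixels lateral raster resolution (default 256)
#' @param theta_cap small-angle cap on the tilt, rad
#' @return object of class `afm_scan_config`
#' @export
scan_config <- function(dz = 0.1, force_tol = 1e-6, max_iter = 3000L,
                        heights = seq(2.8, 3.7, by = 0.1),
                        pixels = 256L, theta_cap = 0.5) {
  stopifnot(dz > 0, force_tol > 0, max_iter >= 1,
            length(heights) >= 1, all(diff(heights) > 0), pixels >= 1)
  structure(list(dz = dz, force_tol = force_tol,
                 max_iter = as.integer(max_iter), heights = heights,
                 pixels = as.integer(pixels), theta_cap = theta_cap),
            class = "afm_scan_config")
}

ff_grid_meta <- function(ff) {
  g <- ff$E_total
  list(values = g$values, origin = g$origin, spacing = grid_spacing(g),
       zmin = g$origin[3], zmax = g$origin[3] + g$cell[3, 3] *
         (1 - 1 / g$shape[3]))
}

#' Relax the probe at one pivot position
#'
#' Minimizes interpolated grid energy at the displaced apex plus the
#' torsional spring energy over tilt angles, by damped gradient descent
#' on the lever sphere (deterministic, theta = 0 start).
#'
#' @param pivot length-3 pivot position, Angstrom.  The untilted probe
#'   apex sits at `pivot - c(0, 0, delta)`.
#' @param ff an `afm_force_field`
#' @param tip an [tip_model()]
#' @param cfg an [scan_config()]
#' @return list with `probe_position`, `pivot`, `theta`, `phi`,
#'   `energy` (eV, field + spring), `converged`, `theta_capped`
#' @export
relax_probe <- function(pivot, ff, tip = tip_model(), cfg = scan_config()) {
  m <- ff_grid_meta(ff)
  z_apex <- pivot[3] - tip$delta
  res <- relax_zscan_cpp(m$values, m$origin, m$spacing,
                         matrix(pivot[1:2], 1, 2), z_apex,
                         tip$delta, kappa_ev_a2(tip), cfg$force_tol,
                         cfg$max_iter, cfg$theta_cap, 0.02)
  dx <- res$dx[1, 1]; dy <- res$dy[1, 1]
  r <- sqrt(dx^2 + dy^2)
  theta <- asin(min(r / tip$delta, 1))
  phi <- if (r < 1e-12) 0 else atan2(dy, dx)
  probe <- c(pivot[1] + dx, pivot[2] + dy,
             z_apex + tip$delta - sqrt(max(tip$delta^2 - r^2, 0)))
  list(probe_position = probe, pivot = pivot, theta = theta, phi = phi,
       energy = res$energy[1, 1], converged = res$flags[1, 1] != 1L,
       theta_capped = res$flags[1, 1] == 2L)
}

# z ladder covering [z_lo, z_hi] in cfg$dz steps with one extra step at
# each end for the centered force derivative; returned far -> near
zscan_levels <- function(z_lo, z_hi, dz) {
  n <- ceiling((z_hi - z_lo) / dz)
  rev(seq(z_lo - dz, by = dz, length.out = n + 3))
}

#' Relaxed force curve along z at one lateral position
#'
#' Approaches from far to near in `cfg$dz` steps, relaxing the probe at
#' each step (warm-started from the previous one), then differentiates
#' the relaxed total energy numerically:
#' `F_z = -(E(z+dz) - E(z-dz)) / (2 dz)` (one-sided at the ends).
#'
#' @param xy length-2 lateral position, Angstrom
#' @param ff an `afm_force_field`
#' @param tip an [tip_model()]
#' @param cfg an [scan_config()]; its `heights` bound the z range
#' @param z_range optional explicit `c(z_lo, z_hi)` for the untilted
#'   apex height (overrides `cfg$heights`)
#' @return data.frame with `z` (apex height, ascending), `energy` (eV),
#'   `fz` (eV/Angstrom), `disp` (lateral probe displacement, Angstrom),
#'   `converged`
#' @export
z_scan <- function(xy, ff, tip = tip_model(), cfg = scan_config(),
                   z_range = NULL) {
  if (is.null(z_range)) z_range <- range(cfg$heights)
  m <- ff_grid_meta(ff)
  zl <- zscan_levels(z_range[1], z_range[2], cfg$dz)
  if (min(zl) < m$zmin || max(zl) > m$zmax)
    stop("z-scan range outside grid support")
  res <- relax_zscan_cpp(m$values, m$origin, m$spacing,
                         matrix(xy, 1, 2), zl, tip$delta,
                         kappa_ev_a2(tip), cfg$force_tol, cfg$max_iter,
                         cfg$theta_cap, 0.02)
  zs <- rev(zl)                      # ascending
  E <- rev(res$energy[, 1])
  fz <- -num_deriv(E, cfg$dz)
  data.frame(z = zs, energy = E, fz = fz,
             disp = rev(res$disp[, 1]),
             converged = rev(res$flags[, 1]) != 1L)
}

# centered first derivative, one-sided at the ends
num_deriv <- function(y, h) {
  n <- length(y)
  d <- numeric(n)
  if (n == 1L) return(d)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (y[2] - y[1]) / h
  d[n] <- (y[n] - y[n - 1]) / h
  d
}

#' Constant-height relaxed F_z image
#'
#' Rasters the cell laterally at `cfg$pixels` x `cfg$pixels` positions
#' (periodic in xy) and reports the relaxed vertical force at the
#' requested apex height, computed from per-pixel z-scans.
#'
#' @param ff an `afm_force_field`
#' @param tip an [tip_model()]
#' @param cfg an [scan_config()]
#' @param height apex height of the map, Angstrom
#' @return `pixels x pixels` matrix of F_z, eV/Angstrom (row = y)
#' @export
scan_image <- function(ff, tip = tip_model(), cfg = scan_config(),
                       height = cfg$heights[1]) {
  sc <- scan_field(ff, tip, cfg, z_range = c(height, height))
  iz <- which.min(abs(sc$z - height))
  matrix(sc$fz[iz, ], cfg$pixels, cfg$pixels, byrow = TRUE)
}

# Batched relaxed z-scans over the full lateral raster.
# Returns z (ascending), energy/fz/disp matrices (n_z x n_pixels,
# pixel index = x fastest then y), flags.
scan_field <- function(ff, tip, cfg, z_range) {
  m <- ff_grid_meta(ff)
  g <- ff$E_total
  L <- diag(g$cell)
  px <- (seq_len(cfg$pixels) - 0.5) * L[1] / cfg$pixels
  py <- (seq_len(cfg$pixels) - 0.5) * L[2] / cfg$pixels
  xy <- cbind(rep(px, times = cfg$pixels), rep(py, each = cfg$pixels))
  zl <- zscan_levels(z_range[1], z_range[2], cfg$dz)
  if (min(zl) < m$zmin || max(zl) > m$zmax)
    stop("scan z range outside grid support")
  res <- relax_zscan_cpp(m$values, m$origin, m$spacing, xy, zl,
                         tip$delta, kappa_ev_a2(tip), cfg$force_tol,
                         cfg$max_iter, cfg$theta_cap, 0.02)
  nz <- length(zl)
  E <- res$energy[nz:1, , drop = FALSE]
  fz <- apply(E, 2, num_deriv, h = cfg$dz)
  if (is.null(dim(fz))) fz <- matrix(fz, nrow = nz)
  list(z = rev(zl), energy = E, fz = -fz,
       disp = res$disp[nz:1, , drop = FALSE],
       flags = res$flags[nz:1, , drop = FALSE], xy = xy)
}

#' Export a force curve as a plain-text table
#'
#' @param curve data.frame from [z_scan()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_force_curve <- function(curve, path) {
  utils::write.table(format(curve, digits = 10), path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
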