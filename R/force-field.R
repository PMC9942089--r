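#' Short-range overlap parameters
#'
#' Prefactor and exponent of the density-overlap Pauli term
#' `E_SR(R) = V0 * integral rho_sample(r)^alpha rho_tip(r - R)^alpha dV`.
#'
#' @param V0 prefactor, eV.Angstrom^3 (default 18)
#' @param alpha exponent (default 1)
#' @return list with `V0`, `alpha`
#' @export
sr_params <- function(V0 = 18, alpha = 1) {
  stopifnot(V0 > 0, alpha > 0)
  list(V0 = V0, alpha = alpha)
}

# periodic FFT cross-correlation:
# out[k] = sum_m a[m] * b[m - k] * dV   (all indices wrapped)
fft_cross_correlation <- function(a, b, dV) {
  n <- prod(dim(a))
  Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / n * dV
}

#' Attractive van der Waals energy grid
#'
#' Pairwise `-C6 / r^6` attraction between the probe and every atom,
#' as in the original probe-particle scheme; the repulsive wall is
#' carried by the short-range overlap term instead, so `r` is clamped
#' below each element's minimum-approach radius to its boundary value.
#' Lateral distances use the periodic minimum image.
#'
#' @param mol a centered `afm_molecule`
#' @param spec a [grid_spec()] for the probe-position lattice
#' @param table element table (per-element C6 and clamp radii)
#' @param c6_probe probe dispersion coefficient, eV.Angstrom^6;
#'   combined per pair as `sqrt(c6_elem * c6_probe)`
#' @return a `grid3d` of energies, eV, everywhere <= 0
#' @export
vdw_energy_grid <- function(mol, spec = grid_spec(), table = element_table(),
                            c6_probe = 9.6) {
  g <- empty_grid(spec)
  if (is.null(mol) || nrow(mol$atoms) == 0L) return(g)
  pars <- element_params(mol$atoms$element, table)
  acc <- g$values
  for (i in seq_len(nrow(mol$atoms))) {
    r2 <- min_image_r2(g, c(mol$atoms$x[i], mol$atoms$y[i],
                            mol$atoms$z[i]))
    r2 <- pmax(r2, pars$rmin[i]^2)
    acc <- acc - sqrt(pars$c6[i] * c6_probe) / r2^3
  }
  g$values <- acc
  g
}

#' Electrostatic energy grid
#'
#' Interaction of the tip differential charge density with the sample
#' electrostatic potential,
#' `E_ES(R) = integral V_sample(r) * drho_tip(r - R) dV`, evaluated as a
#' periodic FFT cross-correlation over the cell.  The output grid is
#' indexed by probe apex position on the sample lattice.
#'
#' @param v_sample a `grid3d` potential in volts (eV per e)
#' @param tip an `afm_tip_density` (offset-indexed, commensurate grid)
#' @return a `grid3d` of energies, eV
#' @export
es_energy_grid <- function(v_sample, tip) {
  tg <- if (inherits(tip, "afm_tip_density")) tip$grid else tip
  if (!two_grids_commensurate(v_sample, tg))
    stop("sample potential and tip density grids are not commensurate")
  out <- v_sample
  out$values <- fft_cross_correlation(v_sample$values, tg$values,
                                      voxel_volume(v_sample))
  out
}

#' Short-range density-overlap energy grid
#'
#' Pauli repulsion from the overlap of the (alpha-powered) probe and
#' sample electron densities, scaled by `V0` and evaluated by FFT
#' cross-correlation.  With `alpha = 1` this is a plain bilinear density
#' correlation.  Both densities must be non-negative, so the result is
#' non-negative everywhere.
#'
#' @param rho_sample sample electron density `grid3d`, e/Angstrom^3
#' @param rho_tip probe electron density `grid3d` (offset-indexed)
#' @param params [sr_params()]
#' @return a `grid3d` of energies, eV, everywhere >= 0
#' @export
sr_energy_grid <- function(rho_sample, rho_tip, params = sr_params()) {
  if (!two_grids_commensurate(rho_sample, rho_tip))
    stop("sample and tip density grids are not commensurate")
  if (min(rho_sample$values) < -1e-12 || min(rho_tip$values) < -1e-12)
    stop("densities must be non-negative for the overlap term")
  a <- pmax(rho_sample$values, 0)^params$alpha
  b <- pmax(rho_tip$values, 0)^params$alpha
  out <- rho_sample
  v <- params$V0 * fft_cross_correlation(a, b, voxel_volume(rho_sample))
  out$values <- pmax(v, 0)  # clip FFT round-off below zero
  out
}

#' Assemble the total probe-position energy grids
#'
#' Voxelwise sum of the van der Waals, electrostatic and short-range
#' parts on their shared probe-position lattice; the parts are retained
#' for diagnostics.  A missing part counts as zero.
#'
#' @param vdw,es,sr `grid3d` energy grids (any may be NULL)
#' @param params [sr_params()] used for the SR part (metadata)
#' @return An object of class `afm_force_field` with fields `E_vdw`,
#'   `E_es`, `E_sr`, `E_total` and `sr_params`.
#' @export
assemble_force_field <- function(vdw = NULL, es = NULL, sr = NULL,
                                 params = sr_params()) {
  parts <- Filter(Negate(is.null), list(vdw = vdw, es = es, sr = sr))
  if (!length(parts)) stop("at least one energy grid is required")
  ref <- parts[[1]]
  for (p in parts)
    if (!two_grids_commensurate(ref, p))
      stop("energy grids do not share one lattice")
  zero <- ref; zero$values <- array(0, ref$shape)
  if (is.null(vdw)) vdw <- zero
  if (is.null(es)) es <- zero
  if (is.null(sr)) sr <- zero
  total <- ref
  total$values <- vdw$values + es$values + sr$values
  structure(list(E_vdw = vdw, E_es = es, E_sr = sr, E_total = total,
                 sr_params = params),
            class = "afm_force_field")
}

#' @export
print.afm_force_field <- function(x, ...) {
  cat(sprintf("<afm_force_field> %d x %d x %d, E_total range [%.4g, %.4g] eV\n",
              x$E_total$shape[1], x$E_total$shape[2], x$E_total$shape[3],
              min(x$E_total$values), max(x$E_total$values)))
  invisible(x)
}

#' Build the full force field for a molecule from synthetic fields
#'
#' Convenience pipeline: synthetic electron density, smeared core
#' charge, periodic Poisson potential, synthetic tip densities, and the
#' three energy grids assembled into one `afm_force_field`.
#'
#' @param mol a centered `afm_molecule`
#' @param spec a [grid_spec()]
#' @param params [sr_params()]
#' @param tip_params [tip_density_params()]
#' @return an `afm_force_field`
#' @export
build_force_field <- function(mol, spec = grid_spec(),
                              params = sr_params(),
                              tip_params = tip_density_params()) {
  rho_e <- synthetic_electron_density(mol, spec)
  rho_n <- nuclear_charge_density(mol, spec)
  net <- rho_n
  net$values <- rho_n$values - rho_e$values
  # remove the residual quadrature charge as a uniform background
  # (jellium) so the periodic Poisson problem is exactly neutral
  net$values <- net$values - grid_integral(net) / prod(diag(net$cell))
  vs <- poisson_potential(net)
  tip <- synthetic_tip_density(spec = spec)
  rho_t <- synthetic_tip_electron_density(spec = spec)
  assemble_force_field(vdw = vdw_energy_grid(mol, spec),
                       es = es_energy_grid(vs, tip),
                       sr = sr_energy_grid(rho_e, rho_t, params),
                       params = params)
}

#' Interpolated total energy at arbitrary probe positions
#'
#' Trilinear interpolation of the total energy grid; x and y wrap
#' periodically, z must stay inside the grid support.
#'
#' @param ff an `afm_force_field`
#' @param pos numeric length-3 position or n x 3 matrix, Angstrom
#' @return energy value(s), eV
#' @export
energy_at <- function(ff, pos) {
  pos <- rbind(pos)
  g <- ff$E_total
  interp_trilinear_cpp(g$values, g$origin, grid_spacing(g), pos)
}

#' Interpolated force at arbitrary probe positions
#'
#' `-grad E_total` by central differences of the interpolated field
#' with step `h` (default 0.02 Angstrom).
#'
#' @param ff an `afm_force_field`
#' @param pos numeric length-3 position or n x 3 matrix, Angstrom
#' @param h finite-difference step, Angstrom
#' @return n x 3 matrix of force components, eV/Angstrom
#' @export
force_at <- function(ff, pos, h = 0.02) {
  pos <- rbind(pos)
  g <- ff$E_total
  out <- matrix(0, nrow(pos), 3)
  for (k in 1:3) {
    dp <- dm <- pos
    dp[, k] <- dp[, k] + h
    dm[, k] <- dm[, k] - h
    out[, k] <- -(interp_trilinear_cpp(g$values, g$origin, grid_spacing(g),
                                       dp) -
                  interp_trilinear_cpp(g$values, g$origin, grid_spacing(g),
                                       dm)) / (2 * h)
  }
  out
}
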