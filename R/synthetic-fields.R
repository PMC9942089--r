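# Coulomb constant 1/(4 pi eps0) in eV.Angstrom per e^2
KE_EV_A <- 14.399645

#' Synthetic sample electron density
#'
#' Atom-centered stand-in for a first-principles valence density: each
#' atom contributes an isotropic single-exponential profile
#' `rho_a(r) = N_val * exp(-r/lambda) / (8 pi lambda^3)` (unit norm),
#' with the decay length `lambda` taken from the element table (half the
#' covalent radius) so that heavier, more diffuse atoms carry visibly
#' more density.  Periodic minimum-image distances are used, and the
#' total integrates to the summed valence electron count.
#'
#' @param mol a centered `afm_molecule`
#' @param spec a [grid_spec()]; spacing must be at most 0.5 Angstrom
#' @param table element table
#' @return a `grid3d` density in e/Angstrom^3 (non-negative)
#' @export
synthetic_electron_density <- function(mol, spec = grid_spec(),
                                       table = element_table()) {
  if (spec$spacing > 0.5)
    stop("grid spacing ", spec$spacing,
         " A too coarse for atomic densities (max 0.5 A)")
  g <- empty_grid(spec)
  if (is.null(mol) || nrow(mol$atoms) == 0L) return(g)
  pars <- element_params(mol$atoms$element, table)
  acc <- g$values
  for (i in seq_len(nrow(mol$atoms))) {
    r <- sqrt(min_image_r2(g, c(mol$atoms$x[i], mol$atoms$y[i],
                                mol$atoms$z[i])))
    lam <- pars$decay[i]
    acc <- acc + pars$valence[i] * exp(-r / lam) / (8 * pi * lam^3)
  }
  g$values <- acc
  g
}

#' Smeared core (ionic) charge density
#'
#' Each atom contributes `+N_val` of positive charge as a normalized
#' Gaussian of width `smear_sigma`, so the molecule's total charge
#' (cores minus electrons) vanishes for neutral molecules.  The width
#' must resolve on the lattice: at least twice the voxel spacing.
#'
#' @param mol a centered `afm_molecule`
#' @param spec a [grid_spec()]
#' @param smear_sigma Gaussian smearing width, Angstrom
#' @param table element table
#' @return a `grid3d` charge density in e/Angstrom^3 (non-negative)
#' @export
nuclear_charge_density <- function(mol, spec = grid_spec(),
                                   smear_sigma = 2.5 * spec$spacing,
                                   table = element_table()) {
  if (smear_sigma < 2 * spec$spacing)
    stop("smear_sigma ", smear_sigma, " A under-resolved: need >= 2x the ",
         spec$spacing, " A spacing")
  g <- empty_grid(spec)
  if (is.null(mol) || nrow(mol$atoms) == 0L) return(g)
  pars <- element_params(mol$atoms$element, table)
  norm <- (2 * pi * smear_sigma^2)^(-1.5)
  acc <- g$values
  for (i in seq_len(nrow(mol$atoms))) {
    r2 <- min_image_r2(g, c(mol$atoms$x[i], mol$atoms$y[i],
                            mol$atoms$z[i]))
    acc <- acc + pars$valence[i] * norm * exp(-r2 / (2 * smear_sigma^2))
  }
  g$values <- acc
  g
}

fft_wavevectors <- function(n, L) {
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  2 * pi * f / L
}

#' Electrostatic potential of a periodic charge distribution
#'
#' Solves the periodic Poisson equation by spectral inversion:
#' `V_hat(k) = 4 pi ke rho_hat(k) / |k|^2`, with the zero-frequency
#' component set to zero (zero-mean potential).  Input must be close to
#' neutral, since the periodic problem has no solution for a net
#' charge.
#'
#' @param total_charge a `grid3d` of net charge density (cores minus
#'   electrons), e/Angstrom^3
#' @param tol neutrality tolerance on the integrated charge, e
#' @return a `grid3d` potential in volts (eV per e), zero mean
#' @export
poisson_potential <- function(total_charge, tol = 1e-3) {
  q <- grid_integral(total_charge)
  if (abs(q) > tol)
    stop(sprintf("charge distribution not neutral: net charge %.3g e", q))
  g <- total_charge
  n <- g$shape; L <- diag(g$cell)
  k2 <- outer(outer(fft_wavevectors(n[1], L[1])^2,
                    fft_wavevectors(n[2], L[2])^2, "+"),
              fft_wavevectors(n[3], L[3])^2, "+")
  rho_hat <- fft(g$values)
  green <- 4 * pi * KE_EV_A / k2
  green[1, 1, 1] <- 0
  g$values <- Re(fft(rho_hat * green, inverse = TRUE)) / prod(n)
  g
}

#' Parameters of the synthetic tip differential charge density
#'
#' Two opposite-signed Gaussian lobes on the tip axis (apex at the
#' origin, tip body toward +z) plus an optional axial quadrupole term
#' built as a balanced second difference of Gaussians.  The lobe
#' amplitudes must balance so the net charge is zero.
#'
#' @param q_neg,q_pos lobe charges, e (both positive numbers; the
#'   negative lobe enters with a minus sign)
#' @param z_neg,z_pos lobe centers on the axis, Angstrom from the apex
#' @param s_neg,s_pos lobe Gaussian widths, Angstrom
#' @param quad axial quadrupole strength, e.Angstrom^2 (0 disables)
#' @param quad_z,quad_a quadrupole center and half-spacing, Angstrom
#' @param balance_tol tolerated amplitude imbalance, e
#' @return parameter list for [synthetic_tip_density()]
#' @export
tip_density_params <- function(q_neg = 0.2, q_pos = 0.2,
                               z_neg = 0.1, z_pos = 0.8,
                               s_neg = 0.35, s_pos = 0.5,
                               quad = 0, quad_z = 0.45, quad_a = 0.3,
                               balance_tol = 1e-9) {
  if (abs(q_neg - q_pos) > balance_tol)
    stop(sprintf("unbalanced lobe amplitudes: %.3g vs %.3g e", q_neg, q_pos))
  list(q_neg = q_neg, q_pos = q_pos, z_neg = z_neg, z_pos = z_pos,
       s_neg = s_neg, s_pos = s_pos, quad = quad, quad_z = quad_z,
       quad_a = quad_a)
}

gaussian_on_grid <- function(g, center, sigma) {
  r2 <- min_image_r2(g, center)
  (2 * pi * sigma^2)^(-1.5) * exp(-r2 / (2 * sigma^2))
}

#' Synthetic CO-tip differential charge density
#'
#' Model of the difference between the CO electron density and the
#' superposed atomic C and O densities: a neutral, axially symmetric
#' distribution whose leading multipoles along the tip axis (a dipole,
#' optionally plus a quadrupole) are set by the parameters.  The grid is
#' offset-indexed: the probe apex sits at lattice index (1,1,1) and
#' displacements wrap periodically, which is the layout the FFT
#' cross-correlations consume directly.
#'
#' @param params a [tip_density_params()] list
#' @param spec a [grid_spec()] matching the sample grids
#' @return An object of class `afm_tip_density` with fields `grid`
#'   (a `grid3d`, signed, integral 0), `axis` (`c(0,0,-1)`) and `params`.
#' @export
synthetic_tip_density <- function(params = tip_density_params(),
                                  spec = grid_spec()) {
  g <- empty_grid(spec)
  g$origin <- c(0, 0, 0)  # offset-indexed: apex at lattice origin
  v <- params$q_pos * gaussian_on_grid(g, c(0, 0, params$z_pos),
                                       params$s_pos) -
       params$q_neg * gaussian_on_grid(g, c(0, 0, params$z_neg),
                                       params$s_neg)
  if (params$quad != 0) {
    a <- params$quad_a
    v <- v + params$quad / a^2 *
      (gaussian_on_grid(g, c(0, 0, params$quad_z - a), a) -
       2 * gaussian_on_grid(g, c(0, 0, params$quad_z), a) +
       gaussian_on_grid(g, c(0, 0, params$quad_z + a), a))
  }
  g$values <- v
  net <- grid_integral(g)
  if (abs(net) > 1e-6)
    stop(sprintf("tip density not neutral after quadrature: %.3g e", net))
  structure(list(grid = g, axis = c(0, 0, -1), params = params),
            class = "afm_tip_density")
}

#' Axial dipole moment of a tip density
#' @param tip an `afm_tip_density`
#' @return dipole moment along +z, e.Angstrom
#' @export
tip_axial_dipole <- function(tip) {
  g <- tip$grid
  ax <- grid_axes(g)
  L <- diag(g$cell)
  # offset-indexed: fold coordinates into (-L/2, L/2] around the apex
  zc <- ax[[3]] - L[3] * round(ax[[3]] / L[3])
  zslab <- apply(g$values, 3, sum) * voxel_volume(g)
  sum(zslab * zc)
}

#' Synthetic CO probe electron density
#'
#' Non-negative electron density of the CO probe itself (oxygen apex at
#' the lattice origin, carbon behind it along +z), built from the same
#' atom-centered exponential profiles as the sample density and
#' offset-indexed like [synthetic_tip_density()].  This is the density
#' whose overlap with the sample density carries the short-range Pauli
#' repulsion.
#'
#' @param spec a [grid_spec()] matching the sample grids
#' @param bond_len C-O bond length, Angstrom
#' @param table element table
#' @return a `grid3d`, non-negative, offset-indexed
#' @export
synthetic_tip_electron_density <- function(spec = grid_spec(),
                                           bond_len = 1.15,
                                           table = element_table()) {
  g <- empty_grid(spec)
  g$origin <- c(0, 0, 0)
  pars <- element_params(c("O", "C"), table)
  zs <- c(0, bond_len)
  acc <- g$values
  for (i in 1:2) {
    r <- sqrt(min_image_r2(g, c(0, 0, zs[i])))
    lam <- pars$decay[i]
    acc <- acc + pars$valence[i] * exp(-r / lam) / (8 * pi * lam^3)
  }
  g$values <- acc
  g
}
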