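# Shared test helpers: tiny grids, brute-force oracles, simple fields.

# small periodic grid filled with reproducible values
random_grid <- function(shape = c(12, 12, 12), cell = c(6, 6, 6),
                        seed = 42, origin = c(0, 0, 0)) {
  set.seed(seed)
  grid3d(array(runif(prod(shape)), shape), cell = cell, origin = origin)
}

# direct-space periodic cross-correlation oracle at one shift (0-based):
# sum_m a[m] * b[m - k] * dV, by explicit index arithmetic
direct_cross_correlation_at <- function(a, b, k, dV) {
  n <- dim(a)
  i1 <- (seq_len(n[1]) - 1 - k[1]) %% n[1] + 1
  i2 <- (seq_len(n[2]) - 1 - k[2]) %% n[2] + 1
  i3 <- (seq_len(n[3]) - 1 - k[3]) %% n[3] + 1
  sum(a * b[i1, i2, i3]) * dV
}

# normalized Gaussian on a grid (periodic minimum image)
gaussian_grid <- function(g, center, sigma, q = 1) {
  g$values <- q * (2 * pi * sigma^2)^(-1.5) *
    exp(-afmsim:::min_image_r2(g, center) / (2 * sigma^2))
  g
}

# uniform-lateral-force test field E = -fx * x on a tall cell
lateral_force_field <- function(fx, cell_side = 20, z_len = 20,
                                spacing = 0.2) {
  spec <- grid_spec(cell_side = cell_side, z_len = z_len,
                    spacing = spacing, z_floor = 0)
  g <- empty_grid(spec)
  ax <- grid_axes(g)
  g$values <- outer(outer(-fx * ax[[1]], rep(1, spec$shape[2])),
                    rep(1, spec$shape[3]))
  assemble_force_field(vdw = g)
}

# one-carbon-atom attractive (vdW-only) field centered in the cell
single_atom_field <- function(cell_side = 20, z_len = 16, spacing = 0.1,
                              z_floor = -4) {
  mol <- molecule("C", matrix(c(cell_side / 2, cell_side / 2, 0), 1, 3),
                  id = 1L)
  spec <- grid_spec(cell_side = cell_side, z_len = z_len,
                    spacing = spacing, z_floor = z_floor)
  list(mol = mol, spec = spec,
       ff = assemble_force_field(vdw = vdw_energy_grid(mol, spec)))
}

NM2EV <- 16.0217663
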