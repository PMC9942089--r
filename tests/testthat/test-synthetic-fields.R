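test_that("synthetic electron density integrates to the valence count", {
  spec <- grid_spec(cell_side = 10, z_len = 10, spacing = 0.15,
                    z_floor = -5)
  one <- molecule("C", matrix(c(5, 5, 0), 1, 3))
  rho <- synthetic_electron_density(one, spec)
  expect_gte(min(rho$values), 0)
  expect_equal(grid_integral(rho), 4, tolerance = 0.01)

  fx <- fixture_molecules(1)
  mol <- center_in_cell(fx$thiophene, 10)
  rho2 <- synthetic_electron_density(mol, spec)
  nval <- sum(element_params(mol$atoms$element)$valence)
  expect_equal(grid_integral(rho2), nval, tolerance = 0.01)

  expect_error(synthetic_electron_density(one, grid_spec(spacing = 0.6)),
               "too coarse")
})

test_that("density field is symmetric under exchange of identical atoms", {
  spec <- grid_spec(cell_side = 8, z_len = 8, spacing = 0.2, z_floor = -4)
  pair <- molecule(c("N", "N"), rbind(c(3, 4, 0), c(5, 4, 0)))
  rho <- synthetic_electron_density(pair, spec)
  # mirror about the x = 4 plane maps the periodic lattice onto itself:
  # x_i = (i-1)*h  ->  (8 - x_i) mod 8
  nx <- spec$shape[1]
  idx <- ((nx - (seq_len(nx) - 1)) %% nx) + 1
  expect_equal(rho$values[idx, , ], rho$values, tolerance = 1e-10)
})

test_that("smeared core charge balances the electron count", {
  spec <- grid_spec(cell_side = 10, z_len = 10, spacing = 0.2,
                    z_floor = -5)
  h1 <- molecule("H", matrix(c(5, 5, 0), 1, 3))
  rn <- nuclear_charge_density(h1, spec, smear_sigma = 0.5)
  expect_equal(grid_integral(rn), 1, tolerance = 0.01)
  expect_error(nuclear_charge_density(h1, spec, smear_sigma = 0.3),
               "under-resolved")

  mol <- center_in_cell(fixture_molecules(1)$benzene, 10)
  net <- grid_integral(nuclear_charge_density(mol, spec)) -
    grid_integral(synthetic_electron_density(mol, spec))
  expect_equal(net, 0, tolerance = 0.02 * 30)
})

test_that("empty molecules give all-zero density grids", {
  spec <- grid_spec(cell_side = 6, z_len = 6, spacing = 0.3, z_floor = 0)
  expect_equal(max(abs(synthetic_electron_density(NULL, spec)$values)), 0)
  expect_equal(max(abs(nuclear_charge_density(NULL, spec)$values)), 0)
})

test_that("Poisson solver reproduces the isolated-Gaussian erf potential", {
  ke <- 14.399645
  L <- 20
  spec <- grid_spec(cell_side = L, z_len = L, spacing = 0.25, z_floor = 0)
  g <- gaussian_grid(empty_grid(spec), c(L / 2, L / 2, L / 2), 0.6)
  g$values <- g$values - mean(g$values)  # neutralizing background
  V <- poisson_potential(g, tol = 1e-2)
  ax <- grid_axes(V)
  iy <- which.min(abs(ax[[2]] - L / 2))
  iz <- which.min(abs(ax[[3]] - L / 2))
  # periodic-image correction: cubic-lattice point-charge self term
  # (Madelung constant -2.837297/L) plus the neutralizing-background
  # quadratic term 2 pi r^2 / (3 L^3)
  for (r in c(1, 2, 3, 4.5)) {
    ix <- which.min(abs(ax[[1]] - (L / 2 + r)))
    rr <- ax[[1]][ix] - L / 2
    vnum <- V$values[ix, iy, iz]
    viso <- ke * (2 * pnorm(rr / 0.6) - 1) / rr
    vper <- viso + ke * (-2.837297 / L + 2 * pi * rr^2 / (3 * L^3))
    expect_equal(vnum, vper, tolerance = 0.02)
  }
})

test_that("Poisson output is zero-mean and spectrally consistent", {
  g <- random_grid(shape = c(16, 16, 16), cell = c(8, 8, 8), seed = 9)
  g$values <- g$values - mean(g$values)  # neutralize
  V <- poisson_potential(g)
  expect_equal(mean(V$values), 0, tolerance = 1e-12)
  # discrete (spectral) Laplacian recovers -4 pi ke rho
  n <- g$shape; L <- diag(g$cell)
  k2 <- outer(outer(afmsim:::fft_wavevectors(n[1], L[1])^2,
                    afmsim:::fft_wavevectors(n[2], L[2])^2, "+"),
              afmsim:::fft_wavevectors(n[3], L[3])^2, "+")
  lap <- Re(fft(-k2 * fft(V$values), inverse = TRUE)) / prod(n)
  rhs <- -4 * pi * 14.399645 * g$values
  expect_equal(lap, rhs, tolerance = 1e-6)
  # zero charge -> zero potential
  z <- g; z$values[] <- 0
  expect_equal(max(abs(poisson_potential(z)$values)), 0)
  # non-neutral input refused
  bad <- g; bad$values <- bad$values + 1
  expect_error(poisson_potential(bad), "not neutral")
})

test_that("opposite Gaussian pair gives an antisymmetric potential", {
  L <- 12
  spec <- grid_spec(cell_side = L, z_len = L, spacing = 0.25, z_floor = 0)
  g <- empty_grid(spec)
  gp <- gaussian_grid(empty_grid(spec), c(L / 2 - 2, L / 2, L / 2), 0.5)
  gm <- gaussian_grid(empty_grid(spec), c(L / 2 + 2, L / 2, L / 2), 0.5)
  g$values <- gp$values - gm$values
  V <- poisson_potential(g)
  nx <- spec$shape[1]
  idx <- ((nx - (seq_len(nx) - 1)) %% nx) + 1  # mirror about midplane
  expect_equal(V$values[idx, , ], -V$values, tolerance = 1e-10)
})

test_that("synthetic tip density is neutral with the configured dipole", {
  spec <- grid_spec(cell_side = 10, z_len = 10, spacing = 0.15,
                    z_floor = 0)
  tp <- tip_density_params()
  tip <- synthetic_tip_density(tp, spec)
  expect_lt(abs(grid_integral(tip$grid)), 1e-6)
  expect_equal(tip_axial_dipole(tip), tp$q_pos * (tp$z_pos - tp$z_neg),
               tolerance = 0.02)
  # quadrupole term keeps charge and dipole balance
  tq <- tip_density_params(quad = 0.1)
  tipq <- synthetic_tip_density(tq, spec)
  expect_lt(abs(grid_integral(tipq$grid)), 1e-6)
  expect_equal(tip_axial_dipole(tipq), tip_axial_dipole(tip),
               tolerance = 0.05)
  expect_error(tip_density_params(q_neg = 0.2, q_pos = 0.3), "unbalanced")
})

test_that("tip density has the cylindrical symmetry of the probe axis", {
  spec <- grid_spec(cell_side = 8, z_len = 8, spacing = 0.2, z_floor = 0)
  tip <- synthetic_tip_density(spec = spec)
  v <- tip$grid$values
  # a 90-degree rotation about the z axis maps the lattice onto itself
  rot <- aperm(v, c(2, 1, 3))
  n <- dim(v)[1]
  idx <- ((n - (seq_len(n) - 1)) %% n) + 1
  expect_equal(rot[, idx, ], v, tolerance = 1e-9)
})
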