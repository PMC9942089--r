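test_that("vdW energy grid matches a brute-force pair sum", {
  spec <- grid_spec(cell_side = 8, z_len = 8, spacing = 0.4, z_floor = -4)
  mol <- molecule(c("C", "H", "O"),
                  rbind(c(3, 4, 0), c(5, 4, 0.3), c(4, 3, -0.2)))
  g <- vdw_energy_grid(mol, spec)
  pars <- element_params(mol$atoms$element)
  ax <- grid_axes(g)
  set.seed(2)
  for (rep in 1:12) {
    ijk <- sapply(spec$shape, function(n) sample.int(n, 1))
    pt <- c(ax[[1]][ijk[1]], ax[[2]][ijk[2]], ax[[3]][ijk[3]])
    e <- 0
    for (a in seq_len(3)) {
      d <- pt - unlist(mol$atoms[a, 2:4])
      d <- d - 8 * round(d / 8)          # minimum image
      r2 <- max(sum(d^2), pars$rmin[a]^2)
      e <- e - sqrt(pars$c6[a] * 9.6) / r2^3
    }
    expect_equal(g$values[ijk[1], ijk[2], ijk[3]], e, tolerance = 1e-12)
  }
  expect_lte(max(g$values), 0)
  # clamp: the on-atom voxel is finite and equals the boundary value
  one <- molecule("C", matrix(c(4, 4, 0), 1, 3))
  g1 <- vdw_energy_grid(one, spec)
  expect_true(all(is.finite(g1$values)))
  r0 <- element_params("C")$rmin
  expect_equal(min(g1$values), -sqrt(element_params("C")$c6 * 9.6) / r0^6,
               tolerance = 1e-12)
})

test_that("FFT cross-correlation energies match direct-space sums", {
  a <- random_grid(shape = c(6, 5, 4), cell = c(6, 5, 4), seed = 1)
  b <- random_grid(shape = c(6, 5, 4), cell = c(6, 5, 4), seed = 2)
  dV <- voxel_volume(a)
  es <- es_energy_grid(a, b)
  sr <- sr_energy_grid(a, b, sr_params(V0 = 18, alpha = 1))
  for (k in list(c(0, 0, 0), c(1, 0, 0), c(2, 3, 1), c(5, 4, 3))) {
    i <- k + 1
    expect_equal(es$values[i[1], i[2], i[3]],
                 direct_cross_correlation_at(a$values, b$values, k, dV),
                 tolerance = 1e-10)
    expect_equal(sr$values[i[1], i[2], i[3]],
                 18 * direct_cross_correlation_at(a$values, b$values, k, dV),
                 tolerance = 1e-9)
  }
})

test_that("delta-like tip density sifts the sample potential", {
  v <- random_grid(shape = c(8, 8, 8), cell = c(4, 4, 4), seed = 7)
  tipd <- v
  tipd$values[] <- 0
  tipd$values[1, 1, 1] <- 1 / voxel_volume(v)  # unit point charge at apex
  es <- es_energy_grid(v, tipd)
  expect_equal(es$values, v$values, tolerance = 1e-10)
})

test_that("Gaussian-Gaussian overlap matches the closed form", {
  L <- 16
  spec <- grid_spec(cell_side = L, z_len = L, spacing = 0.2, z_floor = 0)
  s1 <- 0.6; s2 <- 0.8
  rho_s <- gaussian_grid(empty_grid(spec), c(L / 2, L / 2, L / 2), s1)
  rho_t <- gaussian_grid(empty_grid(spec), c(0, 0, 1) %% L, s2)
  # tip grid is offset-indexed: its apex reference is lattice index
  # (1,1,1), so a lobe written at (0,0,1) rides 1 Angstrom above the
  # probe position R and lands at R + (0,0,1)
  sr <- sr_energy_grid(rho_s, rho_t, sr_params(V0 = 18, alpha = 1))
  ax <- grid_axes(sr)
  s12 <- s1^2 + s2^2
  overlap <- function(d2) (2 * pi * s12)^(-1.5) * exp(-d2 / (2 * s12))
  at_pos <- function(p) {
    i <- vapply(1:3, function(k) which.min(abs(ax[[k]] - p[k])),
                integer(1))
    sr$values[i[1], i[2], i[3]]
  }
  ctr <- c(L / 2, L / 2, L / 2)
  # probe 1 A below the sample Gaussian -> lobe centers coincide
  expect_equal(at_pos(ctr - c(0, 0, 1)), 18 * overlap(0),
               tolerance = 1e-3)
  # probe 3 A below -> lobe 2 A below the sample Gaussian
  expect_equal(at_pos(ctr - c(0, 0, 3)), 18 * overlap(4),
               tolerance = 1e-3)
  # additionally shifted 2 A laterally -> separation sqrt(8)
  expect_equal(at_pos(ctr + c(2, 0, -3)), 18 * overlap(8),
               tolerance = 1e-3)
})

test_that("short-range term scales with V0 and rejects negative density", {
  a <- random_grid(shape = c(6, 6, 6), cell = c(3, 3, 3), seed = 4)
  b <- random_grid(shape = c(6, 6, 6), cell = c(3, 3, 3), seed = 5)
  s1 <- sr_energy_grid(a, b, sr_params(V0 = 18))
  s2 <- sr_energy_grid(a, b, sr_params(V0 = 36))
  expect_equal(s2$values, 2 * s1$values, tolerance = 1e-12)
  expect_gte(min(s1$values), 0)
  bad <- a; bad$values[1, 1, 1] <- -0.5
  expect_error(sr_energy_grid(bad, b), "non-negative")
})

test_that("assembled field is the voxelwise sum with zero defaults", {
  a <- random_grid(seed = 1); b <- random_grid(seed = 2)
  c3 <- random_grid(seed = 3)
  ff <- assemble_force_field(vdw = a, es = b, sr = c3)
  expect_equal(ff$E_total$values, a$values + b$values + c3$values)
  ff2 <- assemble_force_field(vdw = a)
  expect_equal(ff2$E_total$values, a$values)
  expect_equal(max(abs(ff2$E_es$values)), 0)
  small <- random_grid(shape = c(4, 4, 4), cell = c(6, 6, 6))
  expect_error(assemble_force_field(vdw = a, es = small), "lattice")
  expect_error(assemble_force_field(), "at least one")
})

test_that("trilinear interpolation is exact on nodes and linear fields", {
  g <- random_grid(shape = c(7, 6, 5), cell = c(7, 6, 5), seed = 12)
  ff <- assemble_force_field(vdw = g)
  ax <- grid_axes(g)
  for (ijk in list(c(1, 1, 1), c(3, 4, 2), c(7, 6, 5))) {
    pos <- c(ax[[1]][ijk[1]], ax[[2]][ijk[2]], ax[[3]][ijk[3]])
    expect_equal(energy_at(ff, pos), g$values[ijk[1], ijk[2], ijk[3]],
                 tolerance = 1e-12)
  }
  # linear-in-x field: interpolation and force are exact off-node too
  lf <- lateral_force_field(fx = 0.3, cell_side = 10, z_len = 10,
                            spacing = 0.5)
  expect_equal(energy_at(lf, c(2.34, 3.1, 4.7)), -0.3 * 2.34,
               tolerance = 1e-10)
  f <- force_at(lf, c(2.34, 3.1, 4.7))
  expect_equal(as.vector(f), c(0.3, 0, 0), tolerance = 1e-9)
})

test_that("interpolated force matches the analytic vdW gradient", {
  saf <- single_atom_field(cell_side = 12, z_len = 12, spacing = 0.05,
                           z_floor = -4)
  c6 <- sqrt(element_params("C")$c6 * 9.6)
  pos <- c(6, 6, 3.2)  # straight above the atom
  f <- force_at(saf$ff, pos, h = 0.02)
  expect_equal(f[1, 3], -6 * c6 / 3.2^7, tolerance = 0.01)
  # lateral force vanishes on the symmetry axis
  expect_lt(max(abs(f[1, 1:2])), 1e-8)
})

test_that("full synthetic pipeline yields a physically signed field", {
  mol <- center_in_cell(fixture_molecules(1)$benzene, 12)
  spec <- grid_spec(cell_side = 12, z_len = 10, spacing = 0.25,
                    z_floor = -3)
  ff <- build_force_field(mol, spec)
  expect_s3_class(ff, "afm_force_field")
  expect_lte(max(ff$E_vdw$values), 0)
  expect_gte(min(ff$E_sr$values), 0)
  # ES part integrates tiny net energy (neutral tip over neutral sample)
  expect_lt(abs(mean(ff$E_es$values)), 1e-6)
  # the cell is periodic in z too, so the farthest probe positions sit
  # mid-gap (5 A from the molecular plane both ways); energy decays there
  iz_far <- which.min(abs(grid_axes(ff$E_total)[[3]] - 5))
  expect_lt(max(abs(ff$E_total$values[, , iz_far])),
            max(abs(ff$E_total$values)) * 0.05)
})
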