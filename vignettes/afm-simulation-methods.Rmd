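---
title: "Methods: CO-tip AFM image simulation in afmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CO-tip AFM image simulation in afmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmsim)
```

# Overview

`afmsim` simulates constant-height frequency-modulation AFM images of
quasi-planar organic molecules scanned with a CO-functionalized metal
tip.  The pipeline is:

1. molecule I/O and selection filtering (`read_xyz()`, `passes_filter()`),
2. volumetric sample fields — electron density, core charge,
   electrostatic potential — on a periodic orthorhombic grid
   (`synthetic_electron_density()`, `poisson_potential()`, with
   XSF/Gaussian-cube import for externally computed grids),
3. a probe-position energy field built from three physically motivated
   terms (`build_force_field()`),
4. relaxation of the flexible CO probe at every scan position
   (`relax_probe()`, `z_scan()`),
5. conversion of relaxed vertical force curves to frequency shift at
   finite oscillation amplitude (`frequency_shift_curve()`,
   `generate_stack()`), and
6. layout of rendered grayscale stacks into a browsable, indexed
   dataset (`build_dataset()`, `lookup()`, `audit_dataset()`).

All simulation steps are deterministic; the only random number use in
the package is the small coordinate jitter inside
`fixture_molecules(seed)`.

# Interaction model

The probe-position energy is a voxelwise sum of three grids on one
lattice,

$$E_\mathrm{total}(\mathbf R) \;=\; E_\mathrm{vdW}(\mathbf R)
  + E_\mathrm{ES}(\mathbf R) + E_\mathrm{SR}(\mathbf R),$$

where $\mathbf R$ is the probe apex position.

**Van der Waals.** A pairwise attractive dispersion term
$E_\mathrm{vdW} = -\sum_a \sqrt{C_{6,a}\,C_{6,\mathrm{probe}}}\,/\,r_a^6$
over all sample atoms, with $r_a$ clamped below a per-element
minimum-approach radius so the term stays finite; the repulsive wall is
carried by the short-range term instead.  Per-element $C_6$ and clamp
radii live in `element_table()`.

**Electrostatics.** The interaction of the tip's differential charge
density $\delta\rho_\mathrm{tip}$ (the charge rearrangement responsible
for the CO dipole/quadrupole) with the sample potential
$V_\mathrm{sample}$:

$$E_\mathrm{ES}(\mathbf R) = \int V_\mathrm{sample}(\mathbf r)\,
  \delta\rho_\mathrm{tip}(\mathbf r - \mathbf R)\, dV .$$

**Short-range (Pauli) repulsion.** The density-overlap model

$$E_\mathrm{SR}(\mathbf R) = V_0 \int
  \rho_\mathrm{sample}(\mathbf r)^{\alpha}\,
  \rho_\mathrm{tip}(\mathbf r - \mathbf R)^{\alpha}\, dV,$$

with defaults $V_0 = 18\ \mathrm{eV\,\mathring A^3}$ and $\alpha = 1$
(`sr_params()`).

Both integrals are periodic cross-correlations over the cell and are
evaluated exactly (to machine precision on the grid) with FFTs:
`out = Re(ifft(fft(a) * Conj(fft(b)))) / N * dV`.  Tip grids are
*offset-indexed*: the probe apex sits at lattice index $(1,1,1)$ and
lobes wrap periodically, so the correlation output is directly indexed
by apex position on the sample lattice.  The unit tests verify the FFT
path against direct double sums at machine precision.

# Synthetic field generators

The package targets desk-scale use without quantum-chemistry inputs, so
it generates stand-in fields from geometry alone (externally computed
XSF/cube grids can be substituted at any point):

- **Electron density**: a sum of isotropic single-exponential atomic
  profiles $\rho_a(r) = N_\mathrm{val}\,e^{-r/\lambda}/(8\pi\lambda^3)$,
  normalized to the valence electron count, with per-element decay
  length $\lambda = r_\mathrm{cov}/2$.
- **Core charge**: Gaussian-smeared positive point charges of
  $+N_\mathrm{val}$ per atom (smearing tied to the grid spacing, with a
  resolution guard).
- **Electrostatic potential**: the periodic Poisson equation solved
  spectrally, $\hat V(\mathbf k) = 4\pi k_e \hat\rho(\mathbf k)/|\mathbf k|^2$
  with the $\mathbf k = 0$ mode zeroed (zero-mean potential over the
  cell); a tiny residual quadrature charge is removed as a uniform
  jellium background before the solve.
- **Tip differential density**: two opposite Gaussian lobes on the
  probe axis (negative near the apex) giving a configurable axial
  dipole, plus an optional quadrupolar second-difference term; the total
  charge is exactly balanced by construction.
- **Tip electron density**: exponential C and O profiles stacked on the
  axis, O apex down.

The Poisson solver is validated against the isolated-Gaussian
$\mathrm{erf}(r/\sqrt{2}\sigma)/r$ potential.  Because the solver is
periodic with a neutralizing background, the comparison includes the
cubic-lattice image correction
$k_e\,(-2.837297/L + 2\pi r^2/3L^3)$; both the spectral-Laplacian
identity and this oracle are exercised in the test suite.

# Probe relaxation

The CO probe hangs on a lever arm $\delta = 3.02\ \mathring A$ below
the pivot (outermost metal atom) and tilts against a torsional spring,

$$E_\mathrm{spring} = \tfrac12\,\kappa\,(\delta\,\theta)^2 ,$$

with the effective lateral stiffness $\kappa$ quoted in N/m and
converted internally by $1\ \mathrm{eV/\mathring A^2} = 16.0217663\
\mathrm{N/m}$.  At each scan position the lateral displacement
$\mathbf d = (d_x, d_y)$ of the apex on the lever sphere
($z = z_0 + \delta - \sqrt{\delta^2 - |\mathbf d|^2}$) minimizes
interpolated field energy plus spring energy.

Numerical choices:

- trilinear interpolation of the energy grid (periodic in $x,y$,
  clamped in $z$), gradients by central differences
  ($h = 0.02\ \mathring A$) with the exact spring/chain-rule term;
- Barzilai–Borwein trial steps with strict-decrease backtracking
  (monotone descent), a $0.3\ \mathring A$ trust cap per step, and a
  deterministic $\theta = 0$ start;
- a small-angle cap $\theta \le 0.5$ rad; at the cap the outward radial
  gradient component is projected out both for stepping and for the
  convergence test, so boundary minima terminate cleanly;
- approach curves are computed far-to-near with warm starts, which both
  stabilizes and accelerates the relaxation and mirrors the physical
  approach of the oscillating sensor.

The relaxation is validated against closed-form oracles: zero tilt on
laterally uniform surfaces, the exact spring-balance displacement under
a constant lateral force, and recovery of the rigid-probe scan as
$\kappa \to \infty$.

# Frequency shift

The vertical force is the numerical derivative
$F_z = -\partial E/\partial z$ of the relaxed energy along the
approach (centered differences on the $0.1\ \mathring A$ ladder, with
one extra level at each end).  The frequency shift at closest-approach
height $z$ and amplitude $A$ is the standard large-amplitude integral

$$\Delta f(z) = -\frac{f_0}{\pi k A} \int_{-1}^{1}
  F_z\!\big(z + A(1+u)\big)\,\frac{u}{\sqrt{1-u^2}}\,du,$$

evaluated by 64-node Chebyshev–Gauss quadrature (the weight
$1/\sqrt{1-u^2}$ is absorbed exactly) on a natural cubic spline of the
sampled force curve.  A linear force $F = cz$ yields exactly
$-(f_0/2k)c$ for every amplitude, and the small-amplitude limit
reproduces the force-gradient formula; both are enforced in the tests.
For image stacks, `generate_stack()` computes one relaxed z-scan per
pixel spanning all heights plus the oscillation range, and evaluates
all pixels' splines in a single vectorized tridiagonal solve.

Defaults are qPlus-style sensor values ($f_0 = 30300$ Hz,
$k = 1800$ N/m); both are freely configurable.

# Operational parameters and dataset layout

The default operational grid (`parameter_grid()`) crosses

| parameter | values |
|---|---|
| amplitude $A$ | 0.40, 0.60, 0.80, 1.00, 1.20, 1.40 Å |
| stiffness $\kappa$ | 0.40, 0.60, 0.80, 1.00 N/m |
| tip–sample distance | 2.80–3.70 Å in 0.10 Å steps |

i.e. 240 combinations organized as 24 $(A, \kappa)$ subsets of 10
heights.  `build_dataset()` writes
`root/A<amp>_K<kappa>/<CID>/df_<i>.png` with `i = 0` at the farthest
distance, a machine-readable `layout.json`, JSON indexes
(formula/CID/name) and a `manifest.json` with per-image MD5 checksums;
reruns skip any CID folder whose files all match the manifest
(idempotent resume).  Images are 8-bit grayscale PNGs, normalized per
image (most negative $\Delta f$ darkest) or per stack.

Molecule selection follows four rules, applied in order: element
whitelist (C, H, N, O, S, P, F, Cl, Br, I), at least 8 atoms, lateral
fit in the 24 Å cell, and quasi-planarity ($z$ extent $\le 1.83$ Å,
inclusive).

# Worked example

```{r example, eval = FALSE}
mol <- center_in_cell(fixture_molecules(1)$halopyridinol, 24)
spec <- grid_spec(cell_side = 24, z_len = 16, spacing = 0.375,
                  z_floor = -4)
ff <- build_force_field(mol, spec)
st <- generate_stack(mol, ff, tip_model(kappa = 0.4),
                     cantilever_config(A = 0.6),
                     scan_config(pixels = 128L))
write_stack(st, "halopyridinol_A0.60_K0.40")
```

# Limitations

- The synthetic exponential densities are stand-ins, not DFT densities.
  Their tails (notably for heavy halogens, where
  $\lambda = r_\mathrm{cov}/2$ is largest) are fatter than true
  frontier densities, so the density-overlap repulsion is stronger and
  longer-ranged than in first-principles force fields.  At the default
  heights the simulated contrast is therefore repulsion-dominated, and
  the soft probe can slide to the tilt cap over bulky substituents.
  Supplying DFT-derived XSF/cube grids removes this bias without any
  code change.
- Cells are orthorhombic and periodic in all three axes; the vertical
  extent must be chosen large enough that the periodic image below the
  molecule does not intrude on the scan window.
- The tilt model is a single polar spring with a small-angle cap; probe
  azimuthal anharmonicity and metal-tip relaxation are not modeled.
- The electrostatic term uses a rigid tip charge density; mutual
  polarization of tip and sample is neglected.
- Filtering, naming and layout target quasi-planar organic molecules;
  3D structures are out of scope by design.
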