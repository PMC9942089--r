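# afmsim

Simulation of high-resolution frequency-modulation AFM images acquired
with a CO-functionalized tip, in R.

Non-contact AFM with a CO molecule adsorbed on the tip apex resolves
the internal bond structure of single organic molecules.  `afmsim`
models the three ingredients that shape such images:

- a **probe-position energy field** over the sample, split into an
  attractive van der Waals term (pairwise `-C6/r^6`), an
  **electrostatic** term (FFT cross-correlation of the sample potential
  with the tip's differential charge density), and a **short-range
  Pauli** term (density-overlap model
  `V0 * integral rho_sample^alpha * rho_tip^alpha`, defaults
  `V0 = 18 eV A^3`, `alpha = 1`);
- **relaxation of the flexible CO probe**: the apex hangs on a
  3.02 A lever below the tip pivot and tilts against a torsional
  spring (kappa = 0.4–1.0 N/m), which bends force curves and sharpens
  bond-like image features;
- **frequency-shift conversion**: relaxed vertical force curves are
  turned into `Delta f` by the standard large-amplitude
  Chebyshev–Gauss quadrature for a qPlus-style sensor
  (`f0 = 30300 Hz`, `k = 1800 N/m`, configurable).

Sample fields come either from volumetric files (XSF, Gaussian cube)
or from built-in synthetic generators (exponential atomic densities,
smeared cores, a spectral periodic Poisson solver and a Gaussian-lobe
tip density), so the whole pipeline runs from plain XYZ geometry with
no quantum-chemistry inputs.  Constant-height image stacks over an
operational grid of 6 amplitudes x 4 stiffnesses x 10 heights
(240 combinations in 24 subsets) are laid out as indexed, checksummed
PNG datasets with search and audit tools.

See the methods vignette
(`vignettes/afm-simulation-methods.Rmd`) for the model, numerical
choices and limitations.

## Worked example

Simulate a halogenated pyridinol fixture (a built-in stand-in for a
PubChem molecule) end to end:

```r
library(afmsim)

mol <- center_in_cell(fixture_molecules(1)$halopyridinol, 24)
mol
#> <afm_molecule> CID=9002  C5H2BrClINO  (12 atoms)  halogenated-pyridinol-fixture
str(passes_filter(mol))
#> List of 2
#>  $ accepted: logi TRUE
#>  $ reason  : chr "ok"

spec <- grid_spec(cell_side = 24, z_len = 16, spacing = 0.375,
                  z_floor = -4)
ff <- build_force_field(mol, spec)  # vdW + electrostatic + Pauli grids
ff
#> <afm_force_field> 64 x 64 x 43, E_total range [-0.0006188, 136.8] eV

# relaxed-probe force curve above the ring (apex heights in Angstrom)
sc <- z_scan(c(12, 12), ff, tip_model(kappa = 0.4),
             scan_config(dz = 0.1), z_range = c(2.8, 5.6))
head(subset(sc, z >= 3), 4)
#>     z energy    fz disp converged
#> 4 3.0  0.632 1.351 1.45      TRUE
#> 5 3.1  0.508 0.969 1.45      TRUE
#> 6 3.2  0.439 0.694 1.45      TRUE
#> 7 3.3  0.369 0.694 1.45      TRUE

# frequency shift at A = 0.6 Angstrom oscillation amplitude
fs <- frequency_shift_curve(sc$z, sc$fz, cantilever_config(A = 0.6))
head(fs, 3)
#>     z    df
#> 1 2.7 161.8
#> 2 2.8 159.4
#> 3 2.9 146.8

# a 10-height constant-height image stack, rendered to 8-bit grayscale
st <- generate_stack(mol, ff, tip_model(kappa = 0.4),
                     cantilever_config(A = 0.6),
                     scan_config(pixels = 128L))
st
#> <afm_image_stack> CID=9002 C5H2BrClINO  A=0.60 A  kappa=0.40 N/m  10 heights  128x128 px
basename(write_stack(st, "demo"))
#>  [1] "df_0.png" "df_1.png" "df_2.png" "df_3.png" "df_4.png" "df_5.png"
#>  [7] "df_6.png" "df_7.png" "df_8.png" "df_9.png"
```

(`df_0.png` is the farthest tip–sample distance; with the default
synthetic densities the contrast at these heights is
repulsion-dominated, see the vignette's limitations section.)

Datasets over many molecules and the full parameter grid:

```r
build_dataset(list(mol), "afm-demo")   # root/A<amp>_K<kappa>/<CID>/df_<i>.png
lookup("C5H2BrClINO", "afm-demo")      # search by CID, formula or name
audit_dataset("afm-demo")              # manifest vs on-disk fsck
```

The same operations are scriptable via the CLI:

```sh
Rscript inst/cli/afmsim.R filter   --xyz-dir molecules
Rscript inst/cli/afmsim.R simulate --xyz mol.xyz --out stack --amplitude 0.6 --kappa 0.4
Rscript inst/cli/afmsim.R build    --xyz-dir molecules --out afm-demo
Rscript inst/cli/afmsim.R lookup   --root afm-demo --query C5H2BrClINO
Rscript inst/cli/afmsim.R audit    --root afm-demo
```

(after installation the script also lives at
`system.file("cli", "afmsim.R", package = "afmsim")`; a YAML file via
`--config` can supply any long option).

## Tests

The package uses testthat (edition 3):

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "afmsim", load_package = "installed")'
```

The suite validates each numerical kernel against an independent
oracle: FFT correlations against direct double sums, the Poisson
solver against the isolated-Gaussian erf potential (with periodic
image correction), the density-overlap term against the closed-form
Gaussian convolution, probe relaxation against the exact
spring-balance displacement and the rigid-probe limit, and the
frequency-shift quadrature against the exact linear-force and
small-amplitude results.

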