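#' Orthorhombic periodic scalar field
#'
#' A `grid3d` stores one scalar value per voxel of a periodic
#' orthorhombic cell.  Voxel `(i, j, l)` (1-based) sits at
#' `origin + ((i-1)*hx, (j-1)*hy, (l-1)*hz)` with `h = cell side / n`
#' along each axis; there is no duplicated end point, the lattice is the
#' natural one for FFT work.  Units of `values` depend on use:
#' e/A^3 for densities, volts (eV per e) for potentials, eV for energy
#' grids.
#'
#' @param values numeric 3D array `(nx, ny, nz)`
#' @param cell 3x3 matrix of cell vectors (rows), Angstrom; or a length-3
#'   vector of orthorhombic side lengths
#' @param origin cell origin, Angstrom (default `c(0,0,0)`)
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(values, cell, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (is.vector(cell) && length(cell) == 3L) cell <- diag(cell)
  cell <- as.matrix(cell)
  if (any(dim(cell) != c(3L, 3L))) stop("cell must be 3x3")
  if (any(abs(cell[upper.tri(cell)]) > 1e-12) ||
      any(abs(cell[lower.tri(cell)]) > 1e-12))
    stop("only orthorhombic (diagonal) cells are supported")
  if (any(diag(cell) <= 0)) stop("cell sides must be positive")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(origin = as.numeric(origin), cell = cell,
                 shape = dim(values), values = values),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d, cell %.3g x %.3g x %.3g A, range [%.4g, %.4g]\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$cell[1, 1], x$cell[2, 2], x$cell[3, 3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Grid spacing along the three axes
#' @param g a `grid3d`
#' @return length-3 numeric vector, Angstrom per voxel
#' @export
grid_spacing <- function(g) diag(g$cell) / g$shape

#' Voxel volume of a grid
#' @param g a `grid3d`
#' @return scalar, Angstrom^3
#' @export
voxel_volume <- function(g) prod(grid_spacing(g))

#' Axis coordinate vectors of the grid lattice
#' @param g a `grid3d`
#' @return list of three numeric vectors (x, y, z voxel coordinates)
#' @export
grid_axes <- function(g) {
  h <- grid_spacing(g)
  lapply(1:3, function(k) g$origin[k] + (seq_len(g$shape[k]) - 1) * h[k])
}

#' Quadrature integral of a grid (midpoint rule over the cell)
#' @param g a `grid3d`
#' @return scalar; units of values times Angstrom^3
#' @export
grid_integral <- function(g) sum(g$values) * voxel_volume(g)

#' Grid geometry specification
#'
#' Describes the simulation lattice without values: a square
#' `cell_side x cell_side` base, `z_len` of cell height and a target
#' voxel spacing.  The molecular plane (z = 0) defaults to 6 Angstrom
#' above the cell floor, leaving the larger vacuum above for the probe.
#'
#' @param cell_side square cell side, Angstrom (default 24)
#' @param z_len cell height, Angstrom (default 20)
#' @param spacing target voxel spacing, Angstrom (default 0.15)
#' @param z_floor z of the cell floor, Angstrom (default -6)
#' @return list with `cell_side`, `z_len`, `spacing`, `origin`, `shape`
#' @export
grid_spec <- function(cell_side = 24, z_len = 20, spacing = 0.15,
                      z_floor = -6) {
  stopifnot(cell_side > 0, z_len > 0, spacing > 0)
  shape <- c(max(1L, round(cell_side / spacing)),
             max(1L, round(cell_side / spacing)),
             max(1L, round(z_len / spacing)))
  list(cell_side = cell_side, z_len = z_len, spacing = spacing,
       origin = c(0, 0, z_floor), shape = as.integer(shape))
}

#' All-zero grid for a geometry spec
#' @param spec a [grid_spec()]
#' @return a `grid3d` of zeros
#' @export
empty_grid <- function(spec) {
  grid3d(array(0, spec$shape),
         cell = c(spec$cell_side, spec$cell_side, spec$z_len),
         origin = spec$origin)
}

#' Minimum-image squared distances from one point to every voxel
#'
#' Periodic in all three axes.
#' @param g a `grid3d` (values ignored)
#' @param pt length-3 position, Angstrom
#' @return 3D array of squared distances, same shape as `g`
#' @keywords internal
min_image_r2 <- function(g, pt) {
  ax <- grid_axes(g)
  L <- diag(g$cell)
  d <- lapply(1:3, function(k) {
    dk <- ax[[k]] - pt[k]
    dk - L[k] * round(dk / L[k])
  })
  outer(outer(d[[1]]^2, d[[2]]^2, "+"), d[[3]]^2, "+")
}

two_grids_commensurate <- function(a, b, tol = 1e-8) {
  all(a$shape == b$shape) &&
    all(abs(grid_spacing(a) - grid_spacing(b)) < tol)
}

#' Write a grid as an XSF 3D datagrid
#'
#' Follows the XCrySDen convention for periodic datagrids: the stated
#' point counts include a duplicated end point along every axis, so the
#' file holds `(nx+1)(ny+1)(nz+1)` values with x running fastest.  The
#' duplication is produced on write and removed on read, so
#' `read_xsf(write_xsf(g))` reproduces `g` exactly.
#'
#' @param g a `grid3d`
#' @param path output path
#' @param name datagrid label inside the file
#' @return Invisibly, `path`.
#' @export
write_xsf <- function(g, path, name = "grid") {
  v <- g$values
  v <- v[c(seq_len(dim(v)[1]), 1L), , , drop = FALSE]
  v <- v[, c(seq_len(dim(v)[2]), 1L), , drop = FALSE]
  v <- v[, , c(seq_len(dim(v)[3]), 1L), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("BEGIN_BLOCK_DATAGRID_3D",
               " written_by_afmsim",
               sprintf(" BEGIN_DATAGRID_3D_%s", name),
               sprintf("   %d %d %d", dim(v)[1], dim(v)[2], dim(v)[3]),
               sprintf("   %.10g %.10g %.10g", g$origin[1], g$origin[2],
                       g$origin[3]),
               sprintf("   %.10g %.10g %.10g", g$cell[1, 1], g$cell[1, 2],
                       g$cell[1, 3]),
               sprintf("   %.10g %.10g %.10g", g$cell[2, 1], g$cell[2, 2],
                       g$cell[2, 3]),
               sprintf("   %.10g %.10g %.10g", g$cell[3, 1], g$cell[3, 2],
                       g$cell[3, 3])), con)
  vals <- as.vector(v)  # x fastest, column-major matches XSF ordering
  nper <- 5L
  idx <- split(vals, ceiling(seq_along(vals) / nper))
  writeLines(vapply(idx, function(r) paste(sprintf("%.10e", r),
                                           collapse = " "),
                    character(1)), con)
  writeLines(c(" END_DATAGRID_3D", "END_BLOCK_DATAGRID_3D"), con)
  invisible(path)
}

#' Read an XSF 3D datagrid
#'
#' Reads the first `BEGIN_DATAGRID_3D` block.  The duplicated periodic
#' end point along each axis is dropped, returning the natural
#' `(nx, ny, nz)` lattice.
#'
#' @param path XSF file path
#' @return a `grid3d`
#' @export
read_xsf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^\\s*BEGIN_DATAGRID_3D", lines)
  if (!length(beg)) stop("no BEGIN_DATAGRID_3D block in ", path)
  end <- grep("^\\s*END_DATAGRID_3D", lines)
  end <- end[end > beg[1]][1]
  if (is.na(end)) stop("unterminated datagrid block in ", path)
  block <- lines[(beg[1] + 1):(end - 1)]
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  shape1 <- num(block[1])
  if (length(shape1) != 3L || anyNA(shape1))
    stop("malformed datagrid dimension line in ", path)
  origin <- num(block[2])
  cell <- rbind(num(block[3]), num(block[4]), num(block[5]))
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(block[-(1:5)]),
                                                      "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape1))
    stop("datagrid in ", path, " holds ", length(vals),
         " values, expected ", prod(shape1))
  v <- array(vals, dim = shape1)
  v <- v[-shape1[1], -shape1[2], -shape1[3], drop = FALSE]
  grid3d(v, cell = cell, origin = origin)
}

BOHR_A <- 0.529177210903

#' Read a Gaussian cube file
#'
#' Positive axis counts mark Bohr units (the usual cube convention);
#' everything is converted to Angstrom.  Cube grids state `n` points per
#' axis with no duplicated end point; the cell is taken as `n` steps
#' (periodic wrap), keeping integrals invariant under unit conversion.
#'
#' @param path cube file path
#' @return a `grid3d` (values per Angstrom^3-compatible units as stored)
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- abs(as.integer(hdr[1]))
  origin <- hdr[2:4]
  ax <- lapply(4:6, function(i) num(lines[i]))
  n <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  bohr <- all(vapply(ax, function(a) a[1] > 0, logical(1)))
  sc <- if (bohr) BOHR_A else 1
  steps <- lapply(ax, function(a) a[2:4] * sc)
  origin <- origin * sc
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(n))
    stop("cube file ", path, " holds ", length(vals),
         " values, expected ", prod(n))
  # cube ordering: x slowest, z fastest
  v <- aperm(array(vals, dim = rev(n)), c(3, 2, 1))
  if (bohr) v <- v / BOHR_A^3   # density-like values per volume
  cell <- rbind(steps[[1]] * n[1], steps[[2]] * n[2], steps[[3]] * n[3])
  grid3d(v, cell = cell, origin = origin)
}
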