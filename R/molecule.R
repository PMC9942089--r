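#' Construct a molecule object
#'
#' A molecule is an ordered set of atoms (element symbol plus Cartesian
#' coordinates in Angstrom) carrying a non-negative integer identifier in
#' the style of a PubChem CID, and optionally a free-text name.
#'
#' @param elements character vector of element symbols
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom
#' @param id non-negative integer identifier (default 0)
#' @param name optional molecule name
#' @return An object of class `afm_molecule`.
#' @export
molecule <- function(elements, xyz, id = 0L, name = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix matching length(elements)")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  # symbol format only; whitelist membership is a filter decision, and
  # table parameters are resolved where they are needed
  if (!all(grepl("^[A-Z][a-z]?$", elements)))
    stop("malformed element symbol(s): ",
         paste(unique(elements[!grepl("^[A-Z][a-z]?$", elements)]),
               collapse = ", "))
  if (is.na(id) || id < 0) stop("id must be a non-negative integer")
  atoms <- data.frame(element = as.character(elements),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(id = as.integer(id), atoms = atoms, name = name),
            class = "afm_molecule")
}

#' @export
print.afm_molecule <- function(x, ...) {
  cat(sprintf("<afm_molecule> CID=%d  %s  (%d atoms)%s\n",
              x$id, chemical_formula(x), nrow(x$atoms),
              if (!is.null(x$name)) paste0("  ", x$name) else ""))
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ dialect: atom count line, comment line, then one
#' `element x y z` record per atom (Angstrom).  If the comment line
#' contains a `CID=<n>` token the identifier is taken from it, else 0.
#'
#' @param path path to an XYZ file
#' @return An `afm_molecule`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("line 1: malformed atom count '", lines[1], "'")
  comment <- lines[2]
  recs <- lines[-(1:2)]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) != n)
    stop("atom count line says ", n, " atoms but file has ",
         length(recs), " records")
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(recs[i]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop("line ", i + 2L, ": expected 'element x y z'")
    el[i] <- tok[1]
    co <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(co))
      stop("line ", i + 2L, ": non-numeric coordinate")
    xyz[i, ] <- co
  }
  if (!all(el %in% element_table()$element)) {
    bad <- unique(el[!el %in% element_table()$element])
    stop("unknown element symbol(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  id <- 0L
  m <- regmatches(comment, regexpr("CID=([0-9]+)", comment))
  if (length(m) == 1L && nzchar(m))
    id <- as.integer(sub("CID=", "", m))
  name <- trimws(sub("CID=[0-9]+", "", comment))
  molecule(el, xyz, id = id, name = if (nzchar(name)) name else NULL)
}

#' Write a molecule to an XYZ file
#'
#' The comment line always carries a `CID=<id>` token so that a
#' write/read round trip preserves the identifier without a side-car
#' file.
#'
#' @param mol an `afm_molecule`
#' @param path output path
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(mol, path) {
  stopifnot(inherits(mol, "afm_molecule"))
  a <- mol$atoms
  comment <- sprintf("CID=%d%s", mol$id,
                     if (!is.null(mol$name)) paste0(" ", mol$name) else "")
  body <- sprintf("%-2s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z)
  writeLines(c(as.character(nrow(a)), comment, body), path)
  invisible(path)
}

#' Height span of a molecule along z
#'
#' @param mol an `afm_molecule`
#' @return `max(z) - min(z)` in Angstrom; 0 for a single atom.
#' @export
z_extent <- function(mol) {
  stopifnot(inherits(mol, "afm_molecule"))
  max(mol$atoms$z) - min(mol$atoms$z)
}

#' Molecule selection criteria
#'
#' Defaults reflect the selection used for large quasi-planar AFM image
#' collections: only the ten supported organic elements, at least eight
#' atoms, an in-plane footprint fitting a 24 Angstrom square cell, and a
#' height span of at most 1.83 Angstrom (inclusive).
#'
#' @param allowed_elements element whitelist
#' @param min_atoms minimum atom count
#' @param cell_side side of the square simulation cell, Angstrom
#' @param max_z_extent maximum z span, Angstrom (inclusive bound)
#' @return An object of class `afm_filter`.
#' @export
filter_criteria <- function(allowed_elements = element_table()$element,
                            min_atoms = 8L, cell_side = 24,
                            max_z_extent = 1.83) {
  stopifnot(min_atoms >= 1L, cell_side > 0, max_z_extent > 0)
  structure(list(allowed_elements = allowed_elements,
                 min_atoms = as.integer(min_atoms),
                 cell_side = cell_side, max_z_extent = max_z_extent),
            class = "afm_filter")
}

#' Apply the molecule selection filter
#'
#' Rules, checked in order: element whitelist, minimum atom count, xy
#' bounding box must fit `cell_side` in both directions (raw atomic
#' centers, no radius padding), and z span at most `max_z_extent`
#' (inclusive).  Decisions are returned, never raised.
#'
#' @param mol an `afm_molecule`
#' @param criteria an `afm_filter`, default [filter_criteria()]
#' @return list with `accepted` (logical) and `reason` ("ok" or the first
#'   failing rule: "element", "min_atoms", "cell_fit", "z_extent")
#' @export
passes_filter <- function(mol, criteria = filter_criteria()) {
  stopifnot(inherits(mol, "afm_molecule"), inherits(criteria, "afm_filter"))
  a <- mol$atoms
  if (!all(a$element %in% criteria$allowed_elements))
    return(list(accepted = FALSE, reason = "element"))
  if (nrow(a) < criteria$min_atoms)
    return(list(accepted = FALSE, reason = "min_atoms"))
  if (diff(range(a$x)) > criteria$cell_side ||
      diff(range(a$y)) > criteria$cell_side)
    return(list(accepted = FALSE, reason = "cell_fit"))
  if (z_extent(mol) > criteria$max_z_extent)
    return(list(accepted = FALSE, reason = "z_extent"))
  list(accepted = TRUE, reason = "ok")
}

#' Center a molecule in the square simulation cell
#'
#' Rigid translation only: the xy centroid moves to the cell center and
#' the mean atomic z to `z_ref` (default 0, the reference molecular
#' plane).  Relative geometry is untouched.
#'
#' @param mol an `afm_molecule`
#' @param cell_side cell side, Angstrom
#' @param z_ref target mean z, Angstrom
#' @return The translated `afm_molecule`.
#' @export
center_in_cell <- function(mol, cell_side = 24, z_ref = 0) {
  stopifnot(inherits(mol, "afm_molecule"))
  a <- mol$atoms
  if (diff(range(a$x)) > cell_side || diff(range(a$y)) > cell_side)
    stop("molecule does not fit a ", cell_side, " Angstrom cell")
  a$x <- a$x - mean(a$x) + cell_side / 2
  a$y <- a$y - mean(a$y) + cell_side / 2
  a$z <- a$z - mean(a$z) + z_ref
  mol$atoms <- a
  mol
}

#' Chemical formula in Hill notation
#'
#' Carbon first, hydrogen second, all other elements alphabetically
#' (the PubChem convention).
#'
#' @param mol an `afm_molecule`
#' @return A single string, e.g. `"C6H6"`.
#' @export
chemical_formula <- function(mol) {
  stopifnot(inherits(mol, "afm_molecule"))
  counts <- table(mol$atoms$element)
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect("C", syms), intersect("H", syms), rest)
  paste0(vapply(ord, function(s) {
    n <- counts[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' Height-map descriptor of a molecule
#'
#' Paints each atom as a filled disk of its render radius on a
#' `pixels x pixels` grayscale canvas spanning the square cell.  Disk
#' intensity is linear in the atom's z coordinate between the molecule's
#' min and max z (0 = lowest, 1 = highest); a single-plane molecule
#' renders at mid-gray.  Atoms are painted in increasing z order, so
#' higher atoms overwrite lower ones where disks overlap.  Background is
#' black (0).
#'
#' @param mol a centered `afm_molecule`
#' @param pixels image side in pixels
#' @param cell_side cell side, Angstrom
#' @param table element table supplying render radii
#' @return `pixels x pixels` numeric matrix in `[0, 1]`, row = y, col = x.
#' @export
height_map <- function(mol, pixels = 256L, cell_side = 24,
                       table = element_table()) {
  stopifnot(inherits(mol, "afm_molecule"), pixels >= 1L)
  a <- mol$atoms
  pars <- element_params(a$element, table)
  zr <- range(a$z)
  shade <- if (diff(zr) < 1e-12) rep(0.5, nrow(a)) else
    (a$z - zr[1]) / diff(zr)
  img <- matrix(0, pixels, pixels)
  px <- (seq_len(pixels) - 0.5) * cell_side / pixels
  ord <- order(a$z)
  for (i in ord) {
    r <- pars$rdraw[i]
    ix <- which(abs(px - a$x[i]) <= r)
    iy <- which(abs(px - a$y[i]) <= r)
    if (!length(ix) || !length(iy)) next
    dx2 <- (px[ix] - a$x[i])^2
    dy2 <- (px[iy] - a$y[i])^2
    mask <- outer(dy2, dx2, "+") <= r^2
    sub <- img[iy, ix, drop = FALSE]
    sub[mask] <- shade[i]
    img[iy, ix] <- sub
  }
  img
}
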