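#' Element parameter table for the supported chemical space
#'
#' Per-element parameters used throughout the simulator, restricted to the
#' ten elements the pipeline supports: C, H, N, O, S, P and the halogens
#' F, Cl, Br, I.
#'
#' Columns:
#' \describe{
#'   \item{element}{symbol}
#'   \item{number}{atomic number}
#'   \item{valence}{valence electron count; normalization of the synthetic
#'     atomic electron density and magnitude of the smeared core charge}
#'   \item{decay}{decay length of the single-exponential atomic density
#'     profile, in Angstrom (half the covalent radius)}
#'   \item{c6}{homonuclear dispersion coefficient in eV.A^6, adapted from
#'     the UFF Lennard-Jones table (C6 = 2 eps r0^6); combined with the
#'     probe coefficient by a geometric mean}
#'   \item{rmin}{minimum-approach radius in Angstrom used to clamp the
#'     r^-6 attraction at close range (half the UFF r0)}
#'   \item{rcov}{covalent radius, Angstrom}
#'   \item{rdraw}{disk radius used when painting height maps, Angstrom}
#' }
#'
#' @return A data.frame with one row per supported element.
#' @export
element_table <- function() {
  tb <- data.frame(
    element = c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
    number  = c(6L, 1L, 7L, 8L, 16L, 15L, 9L, 17L, 35L, 53L),
    valence = c(4, 1, 5, 6, 6, 5, 7, 7, 7, 7),
    rcov    = c(0.76, 0.31, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39),
    c6      = c(29.7, 2.2, 14.4, 9.6, 102, 135, 6.3, 74.6, 118, 244),
    rmin    = c(1.926, 1.443, 1.830, 1.750, 2.018, 2.074, 1.682, 1.974,
                2.095, 2.250),
    stringsAsFactors = FALSE
  )
  tb$decay <- tb$rcov / 2
  tb$rdraw <- tb$rcov
  stopifnot(all(tb$valence > 0), all(tb$decay > 0), all(tb$c6 > 0),
            all(tb$rmin > 0))
  tb
}

#' Look up rows of the element table for a vector of symbols
#'
#' @param elements character vector of element symbols
#' @param table element table, as from [element_table()]
#' @return data.frame of matching rows, in input order
#' @keywords internal
element_params <- function(elements, table = element_table()) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  table[idx, , drop = FALSE]
}
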