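#' Cantilever / qPlus sensor configuration
#'
#' Defaults are typical qPlus sensor values (f0 = 30300 Hz,
#' k = 1800 N/m); both are freely configurable and are not tied to any
#' particular instrument.
#'
#' @param f0 resonance frequency, Hz
#' @param k cantilever spring constant, N/m
#' @param A oscillation amplitude, Angstrom
#' @return object of class `afm_cantilever`
#' @export
cantilever_config <- function(f0 = 30300, k = 1800, A = 1.0) {
  stopifnot(f0 > 0, k > 0, A > 0)
  structure(list(f0 = f0, k = k, A = A), class = "afm_cantilever")
}

chebyshev_nodes <- function(n) cos((2 * seq_len(n) - 1) * pi / (2 * n))

#' Frequency shift from a vertical force curve
#'
#' Large-amplitude frequency-shift integral of frequency-modulation
#' AFM:
#' `Delta f(z) = -(f0 / (pi k A)) * Int_{-1}^{1} F_z(z + A(1+u)) * u / sqrt(1-u^2) du`
#' with `z` the closest-approach position of the oscillation cycle.
#' The integral is evaluated by Chebyshev-Gauss quadrature (exact
#' weight `1/sqrt(1-u^2)`) on a cubic-spline interpolation of the
#' sampled force curve.  In the small-amplitude limit this reduces to
#' the force-gradient formula `-(f0 / 2k) dF_z/dz`; a purely attractive
#' curve gives negative shifts on approach.
#'
#' @param z sampled apex heights, Angstrom (ascending)
#' @param fz vertical force samples, eV/Angstrom
#' @param cant an [cantilever_config()]
#' @param z_eval closest-approach heights at which to evaluate, Angstrom
#'   (default: all `z` with full oscillation support)
#' @param n_nodes quadrature node count (default 64)
#' @return data.frame with `z` and `df` (Hz)
#' @export
frequency_shift_curve <- function(z, fz, cant = cantilever_config(),
                                  z_eval = NULL, n_nodes = 64L) {
  stopifnot(length(z) == length(fz), length(z) >= 4L, all(diff(z) > 0))
  A <- cant$A
  if (is.null(z_eval)) z_eval <- z[z + 2 * A <= max(z) + 1e-9]
  if (!length(z_eval)) stop("force curve support shorter than 2A")
  if (min(z_eval) < min(z) - 1e-9 || max(z_eval) + 2 * A > max(z) + 1e-9)
    stop("requested z range extends beyond the force-curve support")
  fsp <- stats::splinefun(z, fz, method = "natural")
  u <- chebyshev_nodes(n_nodes)
  k_ev <- cant$k / NM_TO_EV_A2  # eV/Angstrom^2
  df <- vapply(z_eval, function(zc) {
    -(cant$f0 / (n_nodes * k_ev * A)) * sum(fsp(zc + A * (1 + u)) * u)
  }, numeric(1))
  data.frame(z = z_eval, df = df)
}

# Natural cubic spline on a uniform grid, evaluated for many curves at
# once: Y is (length(z) x n_curves), t a vector of targets inside
# range(z).  Returns (length(t) x n_curves).
spline_eval_matrix <- function(z, Y, t) {
  n <- length(z)
  h <- z[2] - z[1]
  # second derivatives: natural boundary, tridiagonal (1,4,1) system
  M <- matrix(0, n, ncol(Y))
  if (n > 2) {
    A <- diag(4, n - 2)
    if (n > 3) {
      idx <- seq_len(n - 3)
      A[cbind(idx, idx + 1)] <- 1
      A[cbind(idx + 1, idx)] <- 1
    }
    B <- 6 / h^2 * (Y[1:(n - 2), , drop = FALSE] -
                    2 * Y[2:(n - 1), , drop = FALSE] +
                    Y[3:n, , drop = FALSE])
    M[2:(n - 1), ] <- solve(A, B)
  }
  i <- pmin(pmax(findInterval(t, z), 1L), n - 1L)
  s <- t - z[i]
  out <- matrix(0, length(t), ncol(Y))
  for (j in seq_along(t)) {
    ii <- i[j]; ss <- s[j]
    out[j, ] <- Y[ii, ] +
      ss * ((Y[ii + 1, ] - Y[ii, ]) / h - h / 6 * (2 * M[ii, ] + M[ii + 1, ])) +
      ss^2 * M[ii, ] / 2 + ss^3 * (M[ii + 1, ] - M[ii, ]) / (6 * h)
  }
  out
}

#' Closest-approach placement for a constant-height image
#'
#' Tip-sample distance is measured from the probe's nearest oscillation
#' turning point to the arithmetic mean of the atomic z coordinates, so
#' the oscillation consumes the force curve on
#' `[mean(z) + height, mean(z) + height + 2A]`.
#'
#' @param height tip-sample distance, Angstrom
#' @param A oscillation amplitude, Angstrom
#' @param mol the molecule being imaged
#' @return list with `z_closest` and `z_span` (`c(lo, hi)`), Angstrom
#' @export
tip_placement <- function(height, A, mol) {
  zc <- mean(mol$atoms$z) + height
  list(z_closest = zc, z_span = c(zc, zc + 2 * A))
}

#' Render a map as 8-bit grayscale
#'
#' Per-image linear normalization: the minimum maps to 0 (darkest; for
#' frequency-shift maps the most negative shift), the maximum to 255.
#' Degenerate (constant) maps render mid-gray (128).
#'
#' @param map numeric matrix (finite values)
#' @param stack_range optional `c(lo, hi)` to normalize against a whole
#'   stack instead of this image
#' @return integer matrix in `[0, 255]`
#' @export
render_grayscale <- function(map, stack_range = NULL) {
  stopifnot(all(is.finite(map)))
  r <- if (is.null(stack_range)) range(map) else stack_range
  if (diff(r) < .Machine$double.eps * max(1, abs(r[1])))
    return(matrix(128L, nrow(map), ncol(map)))
  out <- round((map - r[1]) / diff(r) * 255)
  mode(out) <- "integer"
  matrix(pmin(pmax(out, 0L), 255L), nrow(map), ncol(map))
}

#' Simulate a constant-height frequency-shift image stack
#'
#' One relaxed z-scan per pixel covering the farthest height plus the
#' full oscillation span, reused across all heights: per height, the
#' per-pixel force curves are converted to frequency shift at the
#' closest-approach position and rendered to 8-bit grayscale.
#'
#' @param mol a centered `afm_molecule` (its mean z sets the height
#'   reference)
#' @param ff an `afm_force_field` for `mol`
#' @param tip an [tip_model()] (sets kappa)
#' @param cant an [cantilever_config()] (sets A)
#' @param cfg an [scan_config()] (heights, pixels, dz, tolerances)
#' @param normalize "image" (default) or "stack" grayscale scaling
#' @return object of class `afm_image_stack`: fields `id`, `A`, `kappa`,
#'   `heights`, `maps` (list of Delta-f matrices, Hz, farthest first),
#'   `rendered` (list of integer matrices), `f0`, `k`, `pixels`
#' @export
generate_stack <- function(mol, ff, tip = tip_model(),
                           cant = cantilever_config(),
                           cfg = scan_config(),
                           normalize = c("image", "stack")) {
  normalize <- match.arg(normalize)
  z0 <- mean(mol$atoms$z)
  hts <- sort(cfg$heights, decreasing = TRUE)  # farthest first
  z_lo <- z0 + min(hts)
  z_hi <- z0 + max(hts) + 2 * cant$A
  sc <- scan_field(ff, tip, cfg, z_range = c(z_lo, z_hi))
  u <- chebyshev_nodes(64L)
  k_ev <- cant$k / NM_TO_EV_A2
  pref <- -cant$f0 / (64 * k_ev * cant$A)
  maps <- vector("list", length(hts))
  # all oscillation sample points for all heights at once
  targets <- as.vector(outer(cant$A * (1 + u), z0 + hts, "+"))
  Fmat <- spline_eval_matrix(sc$z, sc$fz, targets)  # (64*nh) x npix
  for (ih in seq_along(hts)) {
    rows <- (ih - 1) * 64 + seq_len(64)
    dfvec <- pref * colSums(Fmat[rows, , drop = FALSE] * u)
    maps[[ih]] <- matrix(dfvec, cfg$pixels, cfg$pixels, byrow = TRUE)
  }
  srange <- if (normalize == "stack") range(unlist(maps)) else NULL
  rendered <- lapply(maps, render_grayscale, stack_range = srange)
  structure(list(id = mol$id, A = cant$A, kappa = tip$kappa,
                 heights = hts, maps = maps, rendered = rendered,
                 f0 = cant$f0, k = cant$k, pixels = cfg$pixels,
                 formula = chemical_formula(mol),
                 name = mol$name),
            class = "afm_image_stack")
}

#' @export
print.afm_image_stack <- function(x, ...) {
  cat(sprintf("<afm_image_stack> CID=%d %s  A=%.2f A  kappa=%.2f N/m  %d heights  %dx%d px\n",
              x$id, x$formula, x$A, x$kappa, length(x$heights),
              x$pixels, x$pixels))
  invisible(x)
}

#' Write an image stack to a directory
#'
#' One 8-bit grayscale PNG per height, named `df_<i>.png` with `i`
#' indexed from 0 at the farthest height, plus a JSON sidecar with the
#' stack metadata.
#'
#' @param stack an `afm_image_stack`
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written PNG paths
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$heights))
  for (i in seq_along(stack$heights)) {
    paths[i] <- file.path(dir, sprintf("df_%d.png", i - 1L))
    png::writePNG(stack$rendered[[i]] / 255, paths[i])
  }
  meta <- list(cid = stack$id, formula = stack$formula,
               name = stack$name, A = stack$A, kappa = stack$kappa,
               heights = stack$heights, f0 = stack$f0, k = stack$k,
               pixels = stack$pixels,
               files = basename(paths))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
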