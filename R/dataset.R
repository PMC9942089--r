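#' Operational parameter grid
#'
#' Default grid: four tilt stiffnesses (0.40-1.00 N/m), six oscillation
#' amplitudes (0.40-1.40 Angstrom) and ten tip-sample distances
#' (2.80-3.70 Angstrom, 0.1 steps), i.e. 240 combinations in 24
#' (A, kappa) subsets of 10 heights each.
#'
#' @param amplitudes oscillation amplitudes, Angstrom, increasing
#' @param kappas tilt stiffnesses, N/m, increasing
#' @param heights tip-sample distances, Angstrom, increasing
#' @return object of class `afm_parameter_grid`
#' @export
parameter_grid <- function(amplitudes = c(0.40, 0.60, 0.80, 1.00, 1.20, 1.40),
                           kappas = c(0.40, 0.60, 0.80, 1.00),
                           heights = seq(2.80, 3.70, by = 0.10)) {
  stopifnot(length(amplitudes) >= 1, length(kappas) >= 1,
            length(heights) >= 1,
            all(diff(amplitudes) > 0), all(diff(kappas) > 0),
            all(diff(heights) > 0))
  structure(list(amplitudes = amplitudes, kappas = kappas,
                 heights = heights),
            class = "afm_parameter_grid")
}

#' Enumerate all (A, kappa, height) combinations
#'
#' Deterministic A-major ordering: amplitude varies slowest, height
#' fastest.
#'
#' @param grid an [parameter_grid()]
#' @return data.frame with columns `A`, `kappa`, `height`
#' @export
enumerate_combinations <- function(grid = parameter_grid()) {
  stopifnot(inherits(grid, "afm_parameter_grid"))
  out <- expand.grid(height = grid$heights, kappa = grid$kappas,
                     A = grid$amplitudes, KEEP.OUT.ATTRS = FALSE)
  out[, c("A", "kappa", "height")]
}

subset_label <- function(A, kappa) sprintf("A%.2f_K%.2f", A, kappa)

#' Subset directory labels, one per (A, kappa) pair
#'
#' Fixed-width zero-padded numeric labels (`A1.00_K0.40` style), whose
#' lexicographic order equals the enumeration order.
#'
#' @param grid an [parameter_grid()]
#' @return data.frame with `A`, `kappa`, `label`
#' @export
subset_directories <- function(grid = parameter_grid()) {
  out <- expand.grid(kappa = grid$kappas, A = grid$amplitudes,
                     KEEP.OUT.ATTRS = FALSE)[, c("A", "kappa")]
  out$label <- subset_label(out$A, out$kappa)
  out
}

#' Build a browsable image dataset for a set of molecules
#'
#' Lays the simulated stacks out as
#' `root/<A..K..>/<CID>/df_<i>.png` (heights indexed from 0 at the
#' farthest distance), writes a machine-readable `layout.json` spec at
#' the root, JSON index files (`formula_to_cids`, `cid_to_formula`,
#' `cid_to_name`) and a `manifest.json` with per-molecule status and
#' image checksums.  A rerun skips CID folders whose files all match
#' the manifest checksums (idempotent resume).  Per-molecule failures
#' are logged in the manifest and skipped.
#'
#' @param molecules list of `afm_molecule`
#' @param root dataset root directory
#' @param grid an [parameter_grid()]
#' @param spec field [grid_spec()]
#' @param cfg an [scan_config()] (pixels, dz, heights are taken from
#'   `grid`, not `cfg`)
#' @param f0,k cantilever parameters, Hz and N/m
#' @param apply_filter reject molecules failing [passes_filter()]
#'   (default TRUE)
#' @return invisibly, the manifest list (also written as JSON)
#' @export
build_dataset <- function(molecules, root, grid = parameter_grid(),
                          spec = grid_spec(), cfg = scan_config(),
                          f0 = 30300, k = 1800, apply_filter = TRUE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  layout <- list(
    subset_pattern = "A<amplitude>_K<kappa>",
    cid_pattern = "<CID>",
    image_pattern = "df_<i>.png",
    height_index = "0 = farthest tip-sample distance",
    heights = sort(grid$heights, decreasing = TRUE),
    amplitudes = grid$amplitudes, kappas = grid$kappas,
    pixels = cfg$pixels)
  jsonlite::write_json(layout, file.path(root, "layout.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  old <- read_json_if(file.path(root, "manifest.json"))
  subs <- subset_directories(grid)
  entries <- list()
  n_written <- 0L; n_skipped <- 0L; n_failed <- 0L
  cid_formula <- list(); cid_name <- list()
  for (mol in molecules) {
    cid <- as.character(mol$id)
    st <- list(cid = mol$id, status = "ok")
    if (apply_filter) {
      fl <- passes_filter(mol)
      if (!fl$accepted) {
        st$status <- paste0("filtered:", fl$reason)
        entries[[cid]] <- st
        n_failed <- n_failed + 1L
        next
      }
    }
    res <- tryCatch({
      cmol <- center_in_cell(mol, spec$cell_side)
      cid_formula[[cid]] <- chemical_formula(cmol)
      cid_name[[cid]] <- if (is.null(cmol$name)) "" else cmol$name
      files <- list()
      ff <- NULL
      for (ik in seq_along(grid$kappas)) {
        kap <- grid$kappas[ik]
        for (ia in seq_along(grid$amplitudes)) {
          A <- grid$amplitudes[ia]
          dir <- file.path(root, subset_label(A, kap), cid)
          expect <- file.path(dir, sprintf("df_%d.png",
                                           seq_along(grid$heights) - 1L))
          if (folder_complete(dir, expect, old, cid)) {
            n_skipped <- n_skipped + 1L
            files[[subset_label(A, kap)]] <-
              old$molecules[[cid]]$files[[subset_label(A, kap)]]
            next
          }
          if (is.null(ff)) ff <- build_force_field(cmol, spec)
          stk <- generate_stack(cmol, ff, tip_model(kappa = kap),
                                cantilever_config(f0 = f0, k = k, A = A),
                                scan_config(dz = cfg$dz,
                                            force_tol = cfg$force_tol,
                                            max_iter = cfg$max_iter,
                                            heights = grid$heights,
                                            pixels = cfg$pixels,
                                            theta_cap = cfg$theta_cap))
          paths <- write_stack(stk, dir)
          n_written <- n_written + length(paths)
          files[[subset_label(A, kap)]] <-
            as.list(tools::md5sum(paths))
        }
      }
      st$files <- files
      st
    }, error = function(e) {
      list(cid = mol$id, status = paste0("error:", conditionMessage(e)))
    })
    if (startsWith(res$status, "error")) n_failed <- n_failed + 1L
    entries[[cid]] <- res
  }
  ok <- Filter(function(e) identical(e$status, "ok"), entries)
  f2c <- split(vapply(names(cid_formula), function(cid) as.integer(cid),
                      integer(1)),
               unlist(cid_formula))
  idx_dir <- file.path(root, "index")
  dir.create(idx_dir, showWarnings = FALSE)
  jsonlite::write_json(f2c, file.path(idx_dir, "formula_to_cids.json"),
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(cid_formula, file.path(idx_dir, "cid_to_formula.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(cid_name, file.path(idx_dir, "cid_to_name.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("afmsim")),
    n_molecules = length(molecules), n_ok = length(ok),
    n_failed = n_failed, n_subsets = nrow(subs),
    n_heights = length(grid$heights),
    images_written = n_written, stacks_skipped = n_skipped,
    expected_images = length(ok) * nrow(subs) * length(grid$heights),
    molecules = entries)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (n_failed > 0L)
    warning(n_failed, " molecule(s) failed or were filtered; see manifest")
  invisible(manifest)
}

read_json_if <- function(path) {
  if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else NULL
}

folder_complete <- function(dir, expect, old_manifest, cid) {
  if (!all(file.exists(expect))) return(FALSE)
  if (is.null(old_manifest)) return(FALSE)
  rec <- old_manifest$molecules[[cid]]
  if (is.null(rec) || !identical(rec$status, "ok")) return(FALSE)
  sums <- rec$files[[basename(dirname(dir))]]
  if (is.null(sums)) return(FALSE)
  cur <- tools::md5sum(expect)
  all(vapply(expect, function(p) identical(cur[[p]], sums[[p]]),
             logical(1)))
}

#' Search a dataset by CID, formula or name
#'
#' CID queries match exactly; formula queries return every CID sharing
#' the formula; name queries match exactly, case-insensitively.  An
#' empty result is an empty data.frame; a missing index raises an
#' error.
#'
#' @param query CID (number or digit string), Hill formula, or name
#' @param root dataset root
#' @param by "auto" (default), "cid", "formula" or "name"
#' @return data.frame with `cid`, `formula`, `name` and `path` (CID
#'   folder paths relative to the subset directories)
#' @export
lookup <- function(query, root, by = c("auto", "cid", "formula", "name")) {
  by <- match.arg(by)
  idx_dir <- file.path(root, "index")
  f2c <- read_json_if(file.path(idx_dir, "formula_to_cids.json"))
  c2f <- read_json_if(file.path(idx_dir, "cid_to_formula.json"))
  c2n <- read_json_if(file.path(idx_dir, "cid_to_name.json"))
  if (is.null(f2c) || is.null(c2f) || is.null(c2n))
    stop("dataset index not found under ", idx_dir)
  query <- as.character(query)
  if (by == "auto")
    by <- if (grepl("^[0-9]+$", query)) "cid"
          else if (query %in% names(f2c)) "formula" else "name"
  cids <- switch(by,
    cid = if (query %in% names(c2f)) query else character(0),
    formula = as.character(unlist(f2c[[query]])),
    name = names(c2n)[vapply(c2n, function(n)
      identical(tolower(n), tolower(query)), logical(1))])
  if (!length(cids))
    return(data.frame(cid = integer(0), formula = character(0),
                      name = character(0), path = character(0)))
  data.frame(cid = as.integer(cids),
             formula = unlist(c2f[cids], use.names = FALSE),
             name = unlist(c2n[cids], use.names = FALSE),
             path = cids, stringsAsFactors = FALSE)
}

#' Audit a dataset tree against its manifest
#'
#' Compares the on-disk PNG count per CID folder with the manifest's
#' expectations.
#'
#' @param root dataset root
#' @return list with `consistent` (logical), `expected_images`,
#'   `found_images`, and a data.frame `problems`
#' @export
audit_dataset <- function(root) {
  man <- read_json_if(file.path(root, "manifest.json"))
  if (is.null(man)) stop("no manifest.json under ", root)
  problems <- list()
  found <- 0L
  for (rec in man$molecules) {
    if (!identical(rec$status, "ok")) next
    for (lab in names(rec$files)) {
      dir <- file.path(root, lab, as.character(rec$cid))
      pngs <- list.files(dir, pattern = "^df_[0-9]+\\.png$")
      found <- found + length(pngs)
      if (length(pngs) != man$n_heights)
        problems[[length(problems) + 1L]] <-
          data.frame(cid = rec$cid, subset = lab, n_found = length(pngs))
    }
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(cid = integer(0), subset = character(0),
               n_found = integer(0))
  list(consistent = nrow(problems) == 0L &&
         found == man$expected_images,
       expected_images = man$expected_images, found_images = found,
       problems = problems)
}
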