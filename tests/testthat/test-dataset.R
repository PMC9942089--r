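test_that("parameter enumeration covers the full operational grid", {
  grid <- parameter_grid()
  combos <- enumerate_combinations(grid)
  expect_identical(nrow(combos), 240L)
  expect_identical(nrow(unique(combos)), 240L)
  # amplitude-major: height varies fastest, amplitude slowest
  expect_equal(combos$A[1:10], rep(0.4, 10))
  expect_equal(combos$kappa[1:10], rep(0.4, 10))
  expect_equal(combos$height[1:10], seq(2.8, 3.7, by = 0.1))
  expect_equal(combos$kappa[11:20], rep(0.6, 10))
  expect_equal(combos$A[240], 1.4)
  subs <- subset_directories(grid)
  expect_identical(nrow(subs), 24L)
  expect_identical(subs$label[1], "A0.40_K0.40")
  expect_identical(subs$label[24], "A1.40_K1.00")
  expect_identical(subs$label, sort(subs$label))  # lexicographic = order
  expect_identical(anyDuplicated(subs$label), 0L)
})

test_that("fixture molecules are reproducible and span the element set", {
  fx1 <- fixture_molecules(1)
  fx2 <- fixture_molecules(1)
  expect_identical(fx1, fx2)
  fx3 <- fixture_molecules(99)
  expect_identical(names(fx3), names(fx1))
  # jitter moves coordinates a little but never filter decisions
  for (nm in names(fx1)) {
    expect_lt(max(abs(as.matrix(fx1[[nm]]$atoms[2:4]) -
                      as.matrix(fx3[[nm]]$atoms[2:4]))), 0.05)
    expect_identical(passes_filter(fx3[[nm]])$reason,
                     passes_filter(fx1[[nm]])$reason)
  }
  pos <- fx1[!startsWith(names(fx1), "fail_")]
  neg <- fx1[startsWith(names(fx1), "fail_")]
  expect_gte(length(pos), 6L)
  for (m in pos) expect_true(passes_filter(m)$accepted)
  expect_identical(passes_filter(neg$fail_element)$reason, "element")
  expect_identical(passes_filter(neg$fail_min_atoms)$reason, "min_atoms")
  expect_identical(passes_filter(neg$fail_cell_fit)$reason, "cell_fit")
  expect_identical(passes_filter(neg$fail_z_extent)$reason, "z_extent")
  elems <- sort(unique(unlist(lapply(pos, function(m) m$atoms$element))))
  expect_setequal(elems, element_table()$element)
  # CIDs are unique across the set
  ids <- vapply(fx1, function(m) m$id, integer(1))
  expect_identical(anyDuplicated(ids), 0L)
})

# shared tiny dataset build used by the remaining blocks
tiny_build <- local({
  done <- NULL
  function() {
    if (!is.null(done)) return(done)
    fx <- fixture_molecules(1)
    iso <- fx$benzene
    iso$id <- 9999L
    iso$name <- "benzene-copy"
    mols <- list(fx$benzene, fx$thiophene, iso, fx$fail_min_atoms)
    grid <- parameter_grid(amplitudes = c(0.5, 0.9),
                           kappas = c(0.4, 0.8),
                           heights = c(3.0, 3.3))
    spec <- grid_spec(cell_side = 12, z_len = 10, spacing = 0.3,
                      z_floor = -3)
    cfg <- scan_config(dz = 0.1, pixels = 8L)
    root <- file.path(tempdir(), "afm-tiny-dataset")
    unlink(root, recursive = TRUE)
    man <- suppressWarnings(
      build_dataset(mols, root, grid, spec, cfg))
    done <<- list(root = root, man = man, mols = mols, grid = grid,
                  spec = spec, cfg = cfg)
    done
  }
})

test_that("dataset build lays out subsets, stacks and indexes", {
  tb <- tiny_build()
  man <- tb$man
  expect_identical(man$n_ok, 3L)
  expect_identical(man$n_failed, 1L)
  expect_identical(man$expected_images, 3L * 4L * 2L)
  expect_identical(man$images_written, 24L)
  expect_identical(man$molecules[["9102"]]$status, "filtered:min_atoms")
  # on-disk layout: root/A<amp>_K<kappa>/<CID>/df_<i>.png
  labs <- subset_directories(tb$grid)$label
  expect_setequal(
    list.dirs(tb$root, recursive = FALSE, full.names = FALSE),
    c(labs, "index"))
  for (lab in labs) {
    expect_setequal(list.files(file.path(tb$root, lab, "9001")),
                    c("df_0.png", "df_1.png", "stack.json"))
  }
  expect_false(dir.exists(file.path(tb$root, labs[1], "9102")))
  # farthest distance gets index 0
  meta <- jsonlite::read_json(
    file.path(tb$root, "A0.50_K0.40", "9001", "stack.json"),
    simplifyVector = TRUE)
  expect_equal(meta$heights, c(3.3, 3.0))
  expect_equal(meta$kappa, 0.4)
  layout <- jsonlite::read_json(file.path(tb$root, "layout.json"),
                                simplifyVector = TRUE)
  expect_identical(layout$image_pattern, "df_<i>.png")
  expect_equal(layout$pixels, 8)
  aud <- audit_dataset(tb$root)
  expect_true(aud$consistent)
  expect_identical(aud$found_images, 24L)
  expect_identical(nrow(aud$problems), 0L)
})

test_that("rebuilding an intact dataset rewrites nothing", {
  tb <- tiny_build()
  pngs <- list.files(tb$root, pattern = "\\.png$", recursive = TRUE,
                     full.names = TRUE)
  before <- file.mtime(pngs)
  Sys.sleep(1.1)   # mtime granularity
  man2 <- suppressWarnings(
    build_dataset(tb$mols, tb$root, tb$grid, tb$spec, tb$cfg))
  expect_identical(man2$images_written, 0L)
  expect_identical(man2$stacks_skipped, 12L)  # 3 molecules x 4 subsets
  expect_identical(file.mtime(pngs), before)
  expect_true(audit_dataset(tb$root)$consistent)
  # a deleted image invalidates only its own stack on the next pass
  victim <- file.path(tb$root, "A0.90_K0.80", "9003", "df_1.png")
  unlink(victim)
  expect_false(audit_dataset(tb$root)$consistent)
  man3 <- suppressWarnings(
    build_dataset(tb$mols, tb$root, tb$grid, tb$spec, tb$cfg))
  expect_identical(man3$images_written, 2L)
  expect_identical(man3$stacks_skipped, 11L)
  expect_true(file.exists(victim))
  expect_true(audit_dataset(tb$root)$consistent)
})

test_that("lookup resolves CIDs, shared formulas and names", {
  tb <- tiny_build()
  by_cid <- lookup(9003, tb$root)
  expect_identical(by_cid$formula, "C4H4S")
  expect_identical(by_cid$path, "9003")
  # two distinct CIDs share the benzene formula
  by_f <- lookup("C6H6", tb$root)
  expect_setequal(by_f$cid, c(9001L, 9999L))
  # formula round trip: every indexed CID maps back to itself
  for (i in seq_len(nrow(by_f)))
    expect_true(by_f$cid[i] %in% lookup(by_f$formula[i], tb$root)$cid)
  by_n <- lookup("BENZENE-COPY", tb$root, by = "name")
  expect_identical(by_n$cid, 9999L)
  expect_identical(nrow(lookup("C60", tb$root)), 0L)
  expect_identical(nrow(lookup(123456, tb$root)), 0L)
  expect_error(lookup("C6H6", file.path(tempdir(), "nowhere")),
               "index not found")
})
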