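ring_xy <- function(n, r, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(ang), r * sin(ang))
}

#' Deterministic synthetic molecule set
#'
#' Builds a small, fully synthetic stand-in for a downloaded compound
#' collection: six quasi-planar molecules that jointly cover all ten
#' supported elements (8-30 atoms each, fitting the 24 Angstrom cell,
#' z span at most 1.83 Angstrom), including a halogen-substituted
#' heteroaromatic ring, plus four molecules each deliberately violating
#' one selection rule (element whitelist, minimum atom count, cell fit,
#' z span) for negative testing.  IDs at 9100 and above mark the
#' designed failures.
#'
#' The seed controls only a small (+-0.01 Angstrom) in-plane jitter:
#' the same seed reproduces coordinates bit-exactly, different seeds
#' give distinct conformers on the same skeletons, and no jitter can
#' move a molecule across a filter boundary.
#'
#' @param seed integer seed
#' @return named list of `afm_molecule`
#' @export
fixture_molecules <- function(seed = 1L) {
  mk <- function(el, xy, z, id, name) {
    molecule(el, cbind(xy, z), id = id, name = name)
  }
  hex <- ring_xy(6, 1.39)
  hexH <- ring_xy(6, 2.48)

  benzene <- mk(rep(c("C", "H"), each = 6), rbind(hex, hexH),
                rep(0, 12), 9001L, "benzene-fixture")

  # halogen-substituted pyridinol ring: N + 5 C, with Br, I, Cl, OH and
  # one ring H; composition C5H2BrClINO
  ringel <- c("N", "C", "C", "C", "C", "C")
  ring <- ring_xy(6, 1.37)
  sub_r <- c(NA, 3.2, 2.45, 3.4, 3.05, 2.73)
  subel <- c(NA, "Br", "H", "I", "Cl", "O")
  ang <- 2 * pi * (0:5) / 6
  subs <- cbind(sub_r * cos(ang), sub_r * sin(ang))
  oh <- c(2.73 * cos(ang[6]) + 0.95 * cos(ang[6] + 0.6),
          2.73 * sin(ang[6]) + 0.95 * sin(ang[6] + 0.6))
  halopyr <- mk(c(ringel, subel[-1], "H"),
                rbind(ring, subs[-1, ], oh), rep(0, 12),
                9002L, "halogenated-pyridinol-fixture")

  pent <- ring_xy(5, 1.2, phase = pi / 2)
  pentH <- ring_xy(5, 2.25, phase = pi / 2)[2:5, ]
  thiophene <- mk(c("S", rep("C", 4), rep("H", 4)),
                  rbind(pent, pentH), rep(0, 9),
                  9003L, "thiophene-fixture")

  # benzene ring with a PF2 substituent; F atoms sit out of plane
  pf2 <- mk(c(rep("C", 6), rep("H", 5), "P", "F", "F"),
            rbind(hex, hexH[2:6, ], c(2.95, 0), c(3.9, 0.8),
                  c(3.9, -0.8)),
            c(rep(0, 11), 0, 0.6, -0.6),
            9004L, "difluorophosphino-benzene-fixture")

  # planar biphenyl: two rings joined at x = +-0.74
  hexL <- sweep(ring_xy(6, 1.39), 2, c(-2.13, 0), "+")
  hexR <- sweep(ring_xy(6, 1.39, phase = pi), 2, c(2.13, 0), "+")
  hL <- sweep(ring_xy(6, 2.48), 2, c(-2.13, 0), "+")[c(2:6), ]
  hR <- sweep(ring_xy(6, 2.48, phase = pi), 2, c(2.13, 0), "+")[c(2:6), ]
  biphenyl <- mk(c(rep("C", 12), rep("H", 10)),
                 rbind(hexL, hexR, hL, hR), rep(0, 22),
                 9005L, "biphenyl-fixture")

  # toluene with an sp3 methyl group: two H out of plane (+-0.89 A)
  toluene <- mk(c(rep("C", 6), rep("H", 5), "C", "H", "H", "H"),
                rbind(hex, hexH[2:6, ], c(2.9, 0), c(3.95, 0),
                      c(3.3, 0.5), c(3.3, -0.5)),
                c(rep(0, 12), 0, 0.89, -0.89),
                9006L, "toluene-fixture")

  # designed filter failures
  fail_elem <- mk(c(rep("C", 6), rep("H", 5), "Fe"),
                  rbind(hex, hexH[2:6, ], c(2.9, 0)), rep(0, 12),
                  9101L, "fails-element-fixture")
  fail_small <- mk(c("C", "C", "O", "H", "H", "H", "H"),
                   cbind(c(0, 1.5, 2.9, -0.9, -0.9, 1.5, 3.4),
                         c(0, 0, 0.5, 0.7, -0.7, 1.0, -0.2)),
                   rep(0, 7), 9102L, "fails-min-atoms-fixture")
  chain <- cbind(seq(0, by = 1.3, length.out = 20), rep(0, 20))
  fail_wide <- mk(c("H", rep("C", 20), "H"),
                  rbind(c(-1.1, 0), chain, c(25.8, 0)), rep(0, 22),
                  9103L, "fails-cell-fit-fixture")
  fail_tall <- mk(rep(c("C", "H"), each = 6), rbind(hex, hexH),
                  c(rep(0, 11), 2.0), 9104L, "fails-z-extent-fixture")

  out <- list(benzene = benzene, halopyridinol = halopyr,
              thiophene = thiophene, pf2_benzene = pf2,
              biphenyl = biphenyl, toluene = toluene,
              fail_element = fail_elem, fail_min_atoms = fail_small,
              fail_cell_fit = fail_wide, fail_z_extent = fail_tall)
  set.seed(seed)
  lapply(out, function(m) {
    n <- nrow(m$atoms)
    m$atoms$x <- m$atoms$x + stats::runif(n, -0.01, 0.01)
    m$atoms$y <- m$atoms$y + stats::runif(n, -0.01, 0.01)
    m
  })
}
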