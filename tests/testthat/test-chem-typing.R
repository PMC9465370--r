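# ideal-geometry glycine backbone (heavy atoms)
glycine_atoms <- function() {
  pf_atoms(1:4, c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
           x = c(0, 1.45, 2.0, 1.45), y = c(0, 0, 1.3, 2.4),
           z = 0, resid = "GLY")
}

test_that("template bonds reproduce amino-acid connectivity", {
  bonds <- perceive_bonds(glycine_atoms(), "template")
  expect_equal(unname(bonds), rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
})

test_that("template mode links sequence-adjacent residues by peptide bonds", {
  g1 <- glycine_atoms()
  g2 <- glycine_atoms()
  g2$resno <- 2L
  g2$serial <- 5:8
  # place residue 2 so its N sits 1.33 A from residue 1's C
  g2$x <- g2$x + 2.0 + 1.33 * 0.6
  g2$y <- g2$y + 1.3 + 1.33 * 0.8
  at <- rbind(g1, g2)
  bonds <- perceive_bonds(at, "template")
  expect_true(any(bonds[, 1] == 3 & bonds[, 2] == 5))  # C(1)-N(2)
  expect_equal(nrow(bonds), 7)
})

test_that("unknown residues fall back to distance mode with a warning", {
  at <- pf_atoms(1:2, c("X1", "X2"), "C", x = c(0, 1.5), y = 0, z = 0,
                 resid = "FRG")
  expect_warning(b <- perceive_bonds(at, "template"), "distance mode")
  expect_equal(nrow(b), 1)
})

test_that("distance-mode bonds match a brute-force pairwise check", {
  for (seed in 1:5) {
    at <- withr::with_seed(seed, {
      n <- 60
      pf_atoms(seq_len(n), "X", sample(c("C", "N", "O", "S"), n, TRUE),
               runif(n, 0, 12), runif(n, 0, 12), runif(n, 0, 12))
    })
    got <- perceive_bonds(at, "distance")
    radii <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05)
    xyz <- as.matrix(at[, c("x", "y", "z")])
    want <- list()
    for (i in 1:(nrow(at) - 1)) for (j in (i + 1):nrow(at)) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <=
          radii[at$element[i]] + radii[at$element[j]] + 0.45)
        want[[length(want) + 1]] <- c(i, j)
    }
    want <- do.call(rbind, want)
    expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ,
                                          drop = FALSE]))
  }
  far <- pf_atoms(1:2, "C", "C", x = c(0, 10), y = 0, z = 0)
  expect_equal(nrow(perceive_bonds(far, "distance")), 0)
})

test_that("fragment enumeration matches brute-force 3-path counting", {
  # linear chain A-B-C-D
  chain <- enumerate_fragments(
    pf_atoms(1:4, c("A", "B", "C", "D"), "C", x = 1:4, y = 0, z = 0),
    rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(chain), 2)
  # star: B bonded to A, C, D
  star <- enumerate_fragments(
    pf_atoms(1:4, c("A", "B", "C", "D"), "C", x = c(0, 1, 2, 1), y = c(0, 0, 0, 1), z = 0),
    rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_equal(nrow(star), 3)
  # two isolated atoms
  expect_equal(nrow(enumerate_fragments(
    pf_atoms(1:2, "A", "C", x = c(0, 5), y = 0, z = 0),
    matrix(integer(0), ncol = 2))), 0)

  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(10:60, 1))
    bonds <- random_bond_graph(n, seed = seed)
    at <- pf_atoms(seq_len(n), paste0("A", seq_len(n)), "C",
                   x = seq_len(n), y = 0, z = 0, resid = "RND")
    fr <- enumerate_fragments(at, bonds)
    got <- sort(paste(pmin(fr$i1, fr$i3), fr$i2, pmax(fr$i1, fr$i3)))
    expect_equal(got, oracle_three_paths(bonds))
    expect_equal(anyDuplicated(got), 0)
    # canonical orientation: anchor-end label never exceeds the far end's
    lab <- paste(at$resid, at$name, sep = ":")
    expect_true(all(lab[fr$i1] < lab[fr$i3] |
                    (lab[fr$i1] == lab[fr$i3] & fr$i1 < fr$i3)))
  }
})

test_that("SYBYL typing follows the rule table", {
  # benzene: planar hexagon, 1.39 A bonds
  ang <- 2 * pi * (0:5) / 6
  benz <- pf_atoms(1:6, paste0("C", 1:6), "C", x = 1.39 * cos(ang),
                   y = 1.39 * sin(ang), z = 0, resid = "BNZ", het = TRUE)
  bb <- perceive_bonds(benz, "distance")
  expect_equal(assign_sybyl_types(benz, bb), rep("C.ar", 6))

  # hydroxyl-like C-O (1.43 A) vs carbonyl C=O (1.23 A)
  ol <- pf_atoms(1:2, c("C1", "O1"), c("C", "O"), x = c(0, 1.43), y = 0,
                 z = 0, het = TRUE)
  expect_equal(assign_sybyl_types(ol, rbind(c(1, 2))), c("C.3", "O.3"))
  on <- pf_atoms(1:2, c("C1", "O1"), c("C", "O"), x = c(0, 1.23), y = 0,
                 z = 0, het = TRUE)
  expect_equal(assign_sybyl_types(on, rbind(c(1, 2))), c("C.2", "O.2"))

  # carboxylate: both terminal oxygens type O.co2
  coo <- pf_atoms(1:4, c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
                  x = c(-1.5, 0, 0.65, 0.65), y = c(0, 0, 1.1, -1.1),
                  z = 0, het = TRUE)
  expect_equal(assign_sybyl_types(coo, rbind(c(1, 2), c(2, 3), c(2, 4))),
               c("C.3", "C.2", "O.co2", "O.co2"))

  # amide: N bonded to a carbonyl carbon
  amd <- pf_atoms(1:4, c("CA", "C", "O", "N"), c("C", "C", "O", "N"),
                  x = c(-1.5, 0, 0.6, 0.6), y = c(0, 0, 1.1, -1.15),
                  z = 0, het = TRUE)
  expect_equal(assign_sybyl_types(amd, rbind(c(1, 2), c(2, 3), c(2, 4))),
               c("C.3", "C.2", "O.2", "N.am"))

  # isolated atoms default to the sp3 type; unknown elements sink to Du
  iso <- pf_atoms(1:3, c("L1", "L2", "L3"), c("C", "N", "FE"),
                  x = c(0, 10, 20), y = 0, z = 0, het = TRUE)
  expect_equal(assign_sybyl_types(iso, NULL), c("C.3", "N.3", "Du"))
})

test_that("SYBYL typing is permutation-equivariant", {
  ang <- 2 * pi * (0:5) / 6
  at <- rbind(
    pf_atoms(1:6, paste0("C", 1:6), "C", x = 1.39 * cos(ang),
             y = 1.39 * sin(ang), z = 0, het = TRUE),
    pf_atoms(7:8, c("C7", "O1"), c("C", "O"), x = c(10, 11.23), y = 0,
             z = 0, het = TRUE))
  bonds <- perceive_bonds(at, "distance")
  base <- assign_sybyl_types(at, bonds)
  perm <- withr::with_seed(3, sample(nrow(at)))
  inv <- order(perm)
  pbonds <- cbind(inv[bonds[, 1]], inv[bonds[, 2]])
  expect_equal(assign_sybyl_types(at[perm, ], pbonds), base[perm])
})
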