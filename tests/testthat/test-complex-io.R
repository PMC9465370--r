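test_that("parse_pdb_complex partitions ATOM vs selected HETATM records", {
  txt <- c(pdb_record("ATOM", 1, "N", "GLY", resno = 1),
           pdb_record("ATOM", 2, "CA", "GLY", resno = 1, x = 1.45),
           pdb_record("HETATM", 3, "C1", "LIG", resno = 90, x = 5))
  cx <- parse_pdb_complex(txt, "LIG")
  expect_equal(nrow(cx$protein), 2)
  expect_equal(nrow(cx$ligand), 1)
  expect_equal(cx$ligand$resid, "LIG")

  expect_error(parse_pdb_complex(txt, "XYZ"), "ligand not found")
})

test_that("waters and buffer ions are never selected as ligand", {
  txt <- c(pdb_record("ATOM", 1, "CA", "GLY"),
           pdb_record("HETATM", 2, "O", "HOH", resno = 50, x = 3, elem = "O"),
           pdb_record("HETATM", 3, "CL", "CL", resno = 51, x = 6,
                      elem = "Cl"))
  expect_error(parse_pdb_complex(txt, "any"), "ligand not found")
  # ions become eligible when exclusion is turned off
  cx <- parse_pdb_complex(txt, "any", exclude_ions = FALSE)
  expect_equal(cx$ligand$resid, "CL")
})

test_that("malformed fixed-width records fail with a line number", {
  txt <- c(pdb_record("ATOM", 1, "CA", "GLY"), "ATOM     2  CB BAD")
  expect_error(parse_pdb_complex(txt, "any"), "line 2")
  txt2 <- c(pdb_record("ATOM", 1, "CA", "GLY"),
            sub("0\\.000", "x.or0", pdb_record("HETATM", 2, "C1", "LIG",
                                               resno = 9)))
  expect_error(parse_pdb_complex(txt2, "LIG"), "line 2")
})

test_that("alternate locations resolve to highest occupancy, ties alphabetical", {
  txt <- c(pdb_record("ATOM", 1, "CA", "GLY", x = 1.0, occ = 0.4, alt = "A"),
           pdb_record("ATOM", 2, "CA", "GLY", x = 2.0, occ = 0.6, alt = "B"),
           pdb_record("HETATM", 3, "C1", "LIG", resno = 9, x = 5.0,
                      occ = 0.5, alt = "B"),
           pdb_record("HETATM", 4, "C1", "LIG", resno = 9, x = 6.0,
                      occ = 0.5, alt = "A"))
  cx <- parse_pdb_complex(txt, "LIG")
  expect_equal(nrow(cx$protein), 1)
  expect_equal(cx$protein$x, 2.0)     # occupancy 0.6 beats 0.4
  expect_equal(cx$ligand$x, 6.0)      # equal occupancy: altloc A wins
})

test_that("write -> parse round trip preserves structure to PDB precision", {
  cx <- make_toy_complex(data.frame(fragment = c(1, 1, 2),
                                    distance = c(3.0, 4.5, 2.5),
                                    element = c("C", "N", "O")), seed = 11)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, tf)
  cx2 <- parse_pdb_complex(tf, "LIG")
  expect_equal(nrow(cx2$protein), nrow(cx$protein))
  expect_equal(nrow(cx2$ligand), nrow(cx$ligand))
  expect_identical(cx2$protein$name, cx$protein$name)
  expect_identical(cx2$ligand$resid, cx$ligand$resid)
  for (h in c("protein", "ligand"))
    expect_lt(max(abs(as.matrix(cx2[[h]][, c("x", "y", "z")]) -
                      as.matrix(cx[[h]][, c("x", "y", "z")]))), 1e-3)
  # CONECT-carried ligand bonds survive the round trip
  expect_equal(cx2$ligand_bonds, cx$ligand_bonds)
})

test_that("write_pdb follows atom-name column conventions and range checks", {
  prot <- pf_atoms(1:2, c("CA", "HD11"), c("C", "H"), c(0, 1), 0, 0,
                   resid = "LEU")
  cx <- pf_complex(prot, pf_atoms(3, "C1", "C", 5, 0, 0, resid = "LIG",
                                  het = TRUE))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, tf)
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  expect_equal(substr(lines[1], 13, 16), " CA ")   # short name indented
  expect_equal(substr(lines[2], 13, 16), "HD11")   # 4-char name flush left
  cx$ligand$x <- 12345.0
  expect_error(write_pdb(cx, tf), "field")
})

test_that("strip_hydrogens removes H/D, drops their bonds, and is idempotent", {
  at <- pf_atoms(1:5, c("N", "H", "CA", "HA", "C"),
                 c("N", "H", "C", "H", "C"),
                 x = 0:4, y = 0, z = 0, resid = "GLY")
  cx <- pf_complex(at, pf_atoms(6, "C1", "C", 9, 0, 0, het = TRUE),
                   protein_bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5)))
  st <- strip_hydrogens(cx)
  expect_equal(nrow(st$protein), 3)
  expect_identical(st$protein$name, c("N", "CA", "C"))
  expect_equal(nrow(st$protein_bonds), 2)  # N-CA and CA-C survive, remapped
  expect_equal(unname(st$protein_bonds), rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(strip_hydrogens(st), st)

  # brute-force element scan agrees on a random fixture
  n <- 40
  elems <- withr::with_seed(5, sample(c("C", "H", "O", "D"), n, TRUE))
  cx2 <- pf_complex(pf_atoms(seq_len(n), "X", elems, seq_len(n), 0, 0),
                    pf_atoms(n + 1, "C1", "C", 99, 0, 0, het = TRUE))
  expect_equal(nrow(strip_hydrogens(cx2)$protein),
               sum(!(elems %in% c("H", "D"))))
})

test_that("pocket box follows the midpoint/extent formula with a floored edge", {
  at <- pf_atoms(1:2, "C", "C", x = c(0, 4), y = c(0, 2), z = c(0, 0))
  bx <- compute_pocket_box(at, margin = 4)
  expect_equal(unname(bx$center), c(2, 1, 0))
  expect_equal(unname(bx$edges), c(12, 10, 10))

  one <- compute_pocket_box(pf_atoms(1, "C", "C", 1, 1, 1), margin = 0)
  expect_equal(unname(one$center), c(1, 1, 1))
  expect_equal(unname(one$edges), c(10, 10, 10))

  expect_error(compute_pocket_box(pf_atoms(1, "H1", "H", 0, 0, 0)),
               "heavy atom")
})

test_that("pocket box contains every atom and is translation equivariant", {
  at <- withr::with_seed(7, pf_atoms(1:50, "C", "C", rnorm(50, 0, 6),
                                     rnorm(50, 0, 6), rnorm(50, 0, 6)))
  bx <- compute_pocket_box(at, margin = 2)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lo <- bx$center - bx$edges / 2
  hi <- bx$center + bx$edges / 2
  expect_true(all(t(xyz) >= lo - 1e-12 & t(xyz) <= hi + 1e-12))
  # per-axis extent exceeds edges minus twice the margin only marginally
  expect_true(all(apply(xyz, 2, function(v) diff(range(v))) <=
                  bx$edges - 2 * 2 + 1e-12 + 10))

  sh <- at
  sh$x <- sh$x + 3.2; sh$y <- sh$y - 1.1; sh$z <- sh$z + 0.7
  bx2 <- compute_pocket_box(sh, margin = 2)
  expect_equal(unname(bx2$center - bx$center), c(3.2, -1.1, 0.7))
  expect_equal(bx2$edges, bx$edges)
})
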