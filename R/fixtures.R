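# Deterministic synthetic-structure generators. They emulate the shape of
# the training corpus (contacts clustered per group in fragment-local
# coordinates) with a minimal pseudo-residue vocabulary, exercising the real
# parsing / typing / extraction code paths without any downloads.

# local geometry of the pseudo-residue FRG (X1-X2-X3, tetrahedral angle)
.pf_frg_local <- rbind(c(0, 0, 0),
                       c(1.5, 0, 0),
                       c(1.5 + 1.5 * cos(pi * 70.5 / 180),
                         1.5 * sin(pi * 70.5 / 180), 0))

.pf_random_rotation <- function() {
  repeat {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-9) return(q)
  }
}

# SYBYL type of an isolated (degree-0) heavy atom under the shipped table
.pf_isolated_sybyl <- function(element) {
  switch(toupper(element),
         C = "C.3", N = "N.3", O = "O.3", S = "S.3", P = "P.3",
         F = "F", CL = "Cl", BR = "Br", I = "I", "Du")
}

.pf_grid_position <- function(i, spacing = 20) {
  c((i - 1) %% 8, ((i - 1) %/% 8) %% 8, (i - 1) %/% 64) * spacing
}

# Assemble one complex from fragment placements: placement k gets one FRG
# fragment instance (random rigid orientation) and one ligand atom at the
# given fragment-local position.
.pf_build_complex <- function(locals, elements, source_id) {
  m <- nrow(locals)
  pxyz <- matrix(0, 3 * m, 3)
  lxyz <- matrix(0, m, 3)
  for (k in seq_len(m)) {
    g <- .pf_grid_position(k)
    R <- .pf_random_rotation()
    pxyz[(3 * k - 2):(3 * k), ] <- t(g + R %*% t(.pf_frg_local))
    lxyz[k, ] <- g + as.numeric(R %*% locals[k, ])
  }
  allxyz <- rbind(pxyz, lxyz)
  dmin <- min(stats::dist(allxyz))
  if (dmin < 0.5)
    stop(sprintf("infeasible geometry: atoms overlap (min separation %.2f A)",
                 dmin))
  prot <- pf_atoms(serial = seq_len(3 * m),
                   name = rep(c("X1", "X2", "X3"), m),
                   element = "C",
                   x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3],
                   chain = "A", resno = rep(seq_len(m), each = 3),
                   resid = "FRG", het = FALSE)
  lig <- pf_atoms(serial = 3 * m + seq_len(m),
                  name = paste0("L", seq_len(m)),
                  element = elements,
                  x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
                  chain = "L", resno = 900L, resid = "LIG", het = TRUE)
  pf_complex(prot, lig,
             protein_bonds = perceive_bonds(prot, "distance"),
             ligand_bonds = perceive_bonds(lig, "distance"),
             source_id = source_id)
}

#' Generate a deterministic toy protein-ligand complex
#'
#' Fragments are realised as bonded carbon triples (pseudo-residue FRG) on a
#' wide grid; each requested ligand atom is placed at an exact distance from
#' its fragment's anchor in a seeded random direction. By construction,
#' [extract_interaction_pairs] finds exactly one pair per ligand atom whose
#' distance is within the cutoff, at exactly the requested distance.
#'
#' @param ligand_spec data frame with columns `fragment` (1-based fragment
#'   index), `distance` (Angstrom from the anchor) and `element`.
#' @param n_fragments number of fragments (default: largest index used).
#' @param seed integer seed; output is byte-identical for equal seeds.
#' @param source_id identifier for the complex.
#' @return a [pf_complex] with distance-perceived bonds.
#' @export
make_toy_complex <- function(ligand_spec = data.frame(fragment = 1,
                                                      distance = 4.0,
                                                      element = "C"),
                             n_fragments = max(ligand_spec$fragment),
                             seed = 1, source_id = "toy") {
  stopifnot(all(ligand_spec$distance >= 0),
            all(ligand_spec$fragment >= 1),
            n_fragments >= max(ligand_spec$fragment))
  .pf_with_seed(seed, {
    pxyz <- matrix(0, 3 * n_fragments, 3)
    frames <- vector("list", n_fragments)
    for (f in seq_len(n_fragments)) {
      g <- .pf_grid_position(f)
      R <- .pf_random_rotation()
      pxyz[(3 * f - 2):(3 * f), ] <- t(g + R %*% t(.pf_frg_local))
      frames[[f]] <- list(origin = g, R = R)
    }
    nl <- nrow(ligand_spec)
    lxyz <- matrix(0, nl, 3)
    for (i in seq_len(nl)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      fr <- frames[[ligand_spec$fragment[i]]]
      lxyz[i, ] <- fr$origin + ligand_spec$distance[i] * as.numeric(fr$R %*% u)
    }
    allxyz <- rbind(pxyz, lxyz)
    if (nrow(allxyz) > 1 && min(stats::dist(allxyz)) < 0.5)
      stop("infeasible geometry: atoms overlap (< 0.5 A)")
    prot <- pf_atoms(serial = seq_len(3 * n_fragments),
                     name = rep(c("X1", "X2", "X3"), n_fragments),
                     element = "C", x = pxyz[, 1], y = pxyz[, 2],
                     z = pxyz[, 3], chain = "A",
                     resno = rep(seq_len(n_fragments), each = 3),
                     resid = "FRG", het = FALSE)
    lig <- pf_atoms(serial = 3 * n_fragments + seq_len(nl),
                    name = paste0("L", seq_len(nl)),
                    element = ligand_spec$element,
                    x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
                    chain = "L", resno = 900L, resid = "LIG", het = TRUE)
    pf_complex(prot, lig,
               protein_bonds = perceive_bonds(prot, "distance"),
               ligand_bonds = perceive_bonds(lig, "distance"),
               source_id = source_id)
  })
}

#' Generate a corpus with planted interaction patterns
#'
#' Each planted pattern is a Gaussian cloud of fragment-local ligand
#' positions around a stated mean (points are resampled into the annulus
#' 0.6-4.9 Angstrom from the anchor and away from the fragment atoms, so
#' every planted point yields exactly one extracted pair). Optional decoy
#' contacts are uniform over that annulus. Contacts are distributed over as
#' many complexes as needed, a bounded number of fragment instances per
#' complex.
#'
#' @param patterns list of pattern specs: each a list with `element`
#'   (ligand atom element), `mean` (local 3-vector, Angstrom), `sd`
#'   (isotropic standard deviation) and `n_points`.
#' @param n_decoys number of uniform decoy contacts (element C).
#' @param seed integer seed.
#' @param per_complex fragment instances per generated complex.
#' @return list with `complexes` (list of [pf_complex]) and `truth` (data
#'   frame: `complex`, `pattern` — index or "decoy" — `group_key`, `lx`,
#'   `ly`, `lz`).
#' @export
make_planted_pattern_corpus <- function(patterns, n_decoys = 0, seed = 1,
                                        per_complex = 8) {
  stopifnot(length(patterns) >= 1,
            all(vapply(patterns, function(p) p$n_points >= 1, logical(1))))
  .pf_with_seed(seed, {
    draw_point <- function(mean, sd) {
      repeat {
        p <- mean + stats::rnorm(3, 0, sd)
        r <- sqrt(sum(p^2))
        if (r < 0.6 || r > 4.9) next
        if (min(sqrt(rowSums(sweep(.pf_frg_local, 2, p)^2))) < 0.8) next
        return(p)
      }
    }
    draw_decoy <- function() {
      repeat {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- stats::runif(1, 1.2, 4.8) * u
        if (min(sqrt(rowSums(sweep(.pf_frg_local, 2, p)^2))) >= 0.8)
          return(p)
      }
    }
    rows <- list()
    for (pi in seq_along(patterns)) {
      sp <- patterns[[pi]]
      for (j in seq_len(sp$n_points))
        rows[[length(rows) + 1]] <-
          list(pattern = as.character(pi), element = sp$element,
               point = draw_point(sp$mean, sp$sd))
    }
    for (j in seq_len(n_decoys))
      rows[[length(rows) + 1]] <-
        list(pattern = "decoy", element = "C", point = draw_decoy())
    # round-robin shuffle so complexes mix patterns
    rows <- rows[order(seq_along(rows) %% per_complex,
                       seq_along(rows))]
    chunks <- split(seq_along(rows),
                    ceiling(seq_along(rows) / per_complex))
    complexes <- vector("list", length(chunks))
    truth <- list()
    for (ci in seq_along(chunks)) {
      idx <- chunks[[ci]]
      locals <- do.call(rbind, lapply(rows[idx], `[[`, "point"))
      elements <- vapply(rows[idx], `[[`, character(1), "element")
      complexes[[ci]] <- .pf_build_complex(locals, elements,
                                           sprintf("planted-%03d", ci))
      truth[[ci]] <- data.frame(
        complex = ci,
        pattern = vapply(rows[idx], `[[`, character(1), "pattern"),
        group_key = paste0(vapply(elements, .pf_isolated_sybyl,
                                  character(1)),
                           "|FRG:X1:X2:X3"),
        lx = locals[, 1], ly = locals[, 2], lz = locals[, 3],
        stringsAsFactors = FALSE)
    }
    list(complexes = complexes, truth = do.call(rbind, truth))
  })
}

#' Generate docked poses at exact ligand RMSD targets
#'
#' Each pose displaces every ligand atom of the reference by the target
#' distance along an independent seeded random direction, so the in-place
#' [ligand_rmsd] to the reference equals the target exactly.
#'
#' @param reference a [pf_complex].
#' @param rmsd_targets numeric vector of non-negative RMSD targets,
#'   Angstrom.
#' @param seed integer seed.
#' @return list, one element per target: `pose` ([pf_complex]), `rmsd`
#'   (achieved = target), `pose_id`.
#' @export
make_pose_set <- function(reference, rmsd_targets, seed = 1) {
  stopifnot(all(rmsd_targets >= 0))
  .pf_with_seed(seed, {
    lapply(seq_along(rmsd_targets), function(i) {
      t <- rmsd_targets[i]
      pose <- reference
      nl <- nrow(pose$ligand)
      U <- matrix(stats::rnorm(3 * nl), nl, 3)
      U <- U / sqrt(rowSums(U^2))
      pose$ligand$x <- pose$ligand$x + t * U[, 1]
      pose$ligand$y <- pose$ligand$y + t * U[, 2]
      pose$ligand$z <- pose$ligand$z + t * U[, 3]
      pose$source_id <- sprintf("%s_pose%02d", reference$source_id, i)
      list(pose = pose, rmsd = t, pose_id = pose$source_id)
    })
  })
}

#' Generate two-feature classification tables
#'
#' `separable`: disjoint (pattern_num, pattern_ratio) clouds for the two
#' classes. `null`: labels independent of the features. `monotone`: label
#' is exactly (pattern_ratio > 0.5).
#'
#' @param kind `"separable"`, `"null"` or `"monotone"`.
#' @param n number of rows (>= 4).
#' @param seed integer seed.
#' @return list with `features` (data frame `pattern_num`,
#'   `pattern_ratio`) and `labels` (logical).
#' @export
make_feature_table <- function(kind = c("separable", "null", "monotone"),
                               n = 200, seed = 1) {
  kind <- match.arg(kind)
  if (n < 4) stop("n must be >= 4")
  .pf_with_seed(seed, {
    if (kind == "separable") {
      npos <- floor(n / 2)
      labels <- c(rep(TRUE, npos), rep(FALSE, n - npos))
      num <- c(round(stats::runif(npos, 600, 900)),
               round(stats::runif(n - npos, 20, 250)))
      ratio <- c(stats::runif(npos, 0.85, 0.98),
                 stats::runif(n - npos, 0.05, 0.40))
    } else if (kind == "null") {
      labels <- stats::runif(n) < 0.5
      num <- round(stats::runif(n, 0, 1000))
      ratio <- stats::runif(n)
    } else {
      ratio <- stats::runif(n)
      num <- round(stats::runif(n, 0, 1000))
      labels <- ratio > 0.5
    }
    ord <- sample.int(n)
    list(features = data.frame(pattern_num = num[ord],
                               pattern_ratio = ratio[ord]),
         labels = labels[ord])
  })
}
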