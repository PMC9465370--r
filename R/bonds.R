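# Single-bond covalent radii, Angstrom (Cordero et al. consensus values).
.pf_cov_radii <- c(H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71,
                   O = 0.66, F = 0.57, SI = 1.11, P = 1.07, S = 1.05,
                   CL = 1.02, SE = 1.20, BR = 1.20, I = 1.39)
.pf_cov_default <- 0.77
.pf_bond_tol <- 0.45

# Heavy-atom connectivity of the 20 standard amino acids (atom-name pairs).
# The backbone N-CA / CA-C / C-O triple plus C-OXT is implied for all.
.pf_aa_sidechain <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLY = list(),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE2", "CZ2"), c("CZ2", "CH2"),
             c("CH2", "CZ3"), c("CZ3", "CE3")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
)
.pf_backbone <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))

# Uniform-grid candidate neighbour pairs: rows of A within `cutoff` of rows
# of B (both n x 3 matrices). Returns a 2-column index matrix (i in A, j in
# B) containing at least every pair at distance <= cutoff.
.pf_grid_candidates <- function(A, B, cutoff) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(matrix(integer(0), ncol = 2))
  cell <- max(cutoff, 1e-6)
  keyB <- floor(B / cell)
  hashB <- paste(keyB[, 1], keyB[, 2], keyB[, 3])
  bins <- split(seq_len(nrow(B)), hashB)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", nrow(A))
  keyA <- floor(A / cell)
  for (i in seq_len(nrow(A))) {
    neigh <- sweep(offs, 2, keyA[i, ], "+")
    hs <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    js <- unlist(bins[hs], use.names = FALSE)
    if (length(js)) out[[i]] <- cbind(i, js)
  }
  got <- do.call(rbind, out)
  if (is.null(got)) matrix(integer(0), ncol = 2) else got
}

#' Perceive covalent bonds between heavy atoms
#'
#' Template mode uses the shipped amino-acid connectivity table (plus
#' peptide C-N links between sequence-adjacent residues of the same chain);
#' residues absent from the table fall back to distance mode with a warning.
#' Distance mode bonds every atom pair closer than the sum of covalent radii
#' plus a 0.45 Angstrom tolerance, using a uniform spatial grid.
#'
#' @param atoms atom table (heavy atoms; see [pf_atoms]).
#' @param mode `"template"` or `"distance"`.
#' @return two-column integer matrix of bonded row indices (i < j).
#' @export
perceive_bonds <- function(atoms, mode = c("template", "distance")) {
  mode <- match.arg(mode)
  n <- nrow(atoms)
  if (n < 2) return(.pf_bond_matrix(NULL))
  if (mode == "distance") return(.pf_distance_bonds(atoms, seq_len(n)))

  known <- atoms$resid %in% names(.pf_aa_sidechain)
  bonds <- list()
  reskey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  for (rk in unique(reskey[known])) {
    idx <- which(reskey == rk & known)
    tmpl <- c(.pf_backbone, .pf_aa_sidechain[[atoms$resid[idx[1]]]])
    for (pr in tmpl) {
      i <- idx[match(pr[1], atoms$name[idx])]
      j <- idx[match(pr[2], atoms$name[idx])]
      if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  # peptide links: C(i) - N(i+1), adjacent residue numbers, same chain
  for (ch in unique(atoms$chain[known])) {
    ridx <- which(known & atoms$chain == ch)
    resnos <- sort(unique(atoms$resno[ridx]))
    for (k in seq_along(resnos)[-1]) {
      if (resnos[k] - resnos[k - 1] != 1) next
      ci <- ridx[atoms$resno[ridx] == resnos[k - 1] & atoms$name[ridx] == "C"]
      ni <- ridx[atoms$resno[ridx] == resnos[k] & atoms$name[ridx] == "N"]
      if (length(ci) == 1 && length(ni) == 1) {
        d <- sqrt(sum((unlist(atoms[ci, c("x", "y", "z")]) -
                       unlist(atoms[ni, c("x", "y", "z")]))^2))
        if (d <= 2.0) bonds[[length(bonds) + 1]] <- c(ci, ni)
      }
    }
  }
  res <- if (length(bonds)) do.call(rbind, bonds) else NULL
  if (any(!known)) {
    warning(sprintf("residues not in template table (%s); using distance mode for them",
                    paste(unique(atoms$resid[!known]), collapse = ", ")))
    res <- rbind(res, .pf_distance_bonds(atoms, which(!known)))
  }
  .pf_bond_matrix(res)
}

# distance-mode bonds among atoms[subset, ]
.pf_distance_bonds <- function(atoms, subset) {
  xyz <- as.matrix(atoms[subset, c("x", "y", "z")])
  rad <- .pf_cov_radii[atoms$element[subset]]
  rad[is.na(rad)] <- .pf_cov_default
  maxcut <- 2 * max(rad) + .pf_bond_tol
  cand <- .pf_grid_candidates(xyz, xyz, maxcut)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) == 0) return(.pf_bond_matrix(NULL))
  d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                     xyz[cand[, 2], , drop = FALSE])^2))
  ok <- d <= rad[cand[, 1]] + rad[cand[, 2]] + .pf_bond_tol
  .pf_bond_matrix(cbind(subset[cand[ok, 1]], subset[cand[ok, 2]]))
}
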