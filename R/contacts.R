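#' Local orthonormal frame of a protein fragment
#'
#' Origin at the anchor (first) atom; x along anchor -> atom2; y in the
#' fragment plane with positive component toward atom3; z = x cross y
#' (right-handed). For a collinear triple the y axis falls back,
#' deterministically, to the smallest-index global axis not parallel to x.
#'
#' @param p1,p2,p3 numeric 3-vectors: anchor, second and third atom
#'   positions.
#' @return list with `origin` (3-vector), `R` (3x3 matrix whose columns are
#'   the x, y, z axes) and `degenerate` (logical, collinear fallback used).
#' @export
fragment_local_frame <- function(p1, p2, p3) {
  v1 <- p2 - p1
  n1 <- sqrt(sum(v1^2))
  if (n1 < 1e-9) stop("fragment atoms 1 and 2 coincide")
  xhat <- v1 / n1
  v2 <- p3 - p1
  yraw <- v2 - sum(v2 * xhat) * xhat
  degenerate <- FALSE
  if (sqrt(sum(yraw^2)) < 1e-6) {
    degenerate <- TRUE
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- 1
      yraw <- e - sum(e * xhat) * xhat
      if (sqrt(sum(yraw^2)) >= 1e-6) break
    }
  }
  yhat <- yraw / sqrt(sum(yraw^2))
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  list(origin = p1, R = cbind(xhat, yhat, zhat, deparse.level = 0),
       degenerate = degenerate)
}

#' Extract ligand-atom / protein-fragment interaction pairs
#'
#' One pair is emitted for every (ligand heavy atom, fragment) combination
#' whose anchor distance is within the cutoff (inclusive). Each pair carries
#' the ligand atom's coordinates expressed in the fragment's local frame and
#' a group key combining the ligand atom's SYBYL type with the fragment type.
#' A ligand atom contacting k fragments yields k pairs.
#'
#' @param structure a [pf_complex] (heavy atoms).
#' @param types optional SYBYL types for the ligand atoms; computed via
#'   [assign_sybyl_types] (with distance-perceived ligand bonds if the
#'   complex carries none) when NULL.
#' @param fragments optional fragment table; computed via [perceive_bonds]
#'   (template mode) + [enumerate_fragments] when NULL.
#' @param cutoff contact cutoff in Angstrom (default 5, inclusive).
#' @param method `"grid"` (cell-list accelerated, default) or `"brute"`
#'   (exhaustive O(n*m) scan); both return identical results.
#' @return data frame, ordered by (ligand atom, fragment): `ligand_atom`,
#'   `fragment` (row indices), `sybyl`, `frag_type`, `group_key`,
#'   `distance`, `lx`, `ly`, `lz`.
#' @export
extract_interaction_pairs <- function(structure, types = NULL,
                                      fragments = NULL, cutoff = 5.0,
                                      method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0)
  lig <- structure$ligand
  if (is.null(types)) {
    lb <- structure$ligand_bonds
    if (nrow(lb) == 0) lb <- perceive_bonds(lig, "distance")
    types <- assign_sybyl_types(lig, lb)
  }
  if (is.null(fragments)) {
    pb <- structure$protein_bonds
    if (nrow(pb) == 0)
      pb <- suppressWarnings(perceive_bonds(structure$protein, "template"))
    fragments <- enumerate_fragments(structure$protein, pb)
  }
  empty <- data.frame(ligand_atom = integer(0), fragment = integer(0),
                      sybyl = character(0), frag_type = character(0),
                      group_key = character(0), distance = numeric(0),
                      lx = numeric(0), ly = numeric(0), lz = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(lig) == 0 || nrow(fragments) == 0) return(empty)

  L <- as.matrix(lig[, c("x", "y", "z")])
  P <- as.matrix(structure$protein[, c("x", "y", "z")])
  anchors <- P[fragments$i1, , drop = FALSE]

  if (method == "brute") {
    cand <- as.matrix(expand.grid(i = seq_len(nrow(L)),
                                  j = seq_len(nrow(fragments))))
  } else {
    cand <- .pf_grid_candidates(L, anchors, cutoff)
  }
  if (nrow(cand) == 0) return(empty)
  d <- sqrt(rowSums((L[cand[, 1], , drop = FALSE] -
                     anchors[cand[, 2], , drop = FALSE])^2))
  keep <- d <= cutoff
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(cand) == 0) return(empty)
  ord <- order(cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  d <- d[ord]

  loc <- matrix(0, nrow(cand), 3)
  frames <- vector("list", nrow(fragments))
  for (r in seq_len(nrow(cand))) {
    j <- cand[r, 2]
    if (is.null(frames[[j]]))
      frames[[j]] <- fragment_local_frame(P[fragments$i1[j], ],
                                          P[fragments$i2[j], ],
                                          P[fragments$i3[j], ])
    fr <- frames[[j]]
    loc[r, ] <- as.numeric(crossprod(fr$R, L[cand[r, 1], ] - fr$origin))
  }
  data.frame(ligand_atom = cand[, 1], fragment = cand[, 2],
             sybyl = types[cand[, 1]],
             frag_type = fragments$type_key[cand[, 2]],
             group_key = paste(types[cand[, 1]],
                               fragments$type_key[cand[, 2]], sep = "|"),
             distance = d, lx = loc[, 1], ly = loc[, 2], lz = loc[, 3],
             stringsAsFactors = FALSE)
}

#' Group interaction pairs by (SYBYL type, fragment type)
#'
#' @param pairs data frame from [extract_interaction_pairs].
#' @return named list of data frames, one per group key (sorted); the group
#'   sizes sum to `nrow(pairs)`.
#' @export
group_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(structure(list(), names = character(0)))
  out <- split(pairs, pairs$group_key)
  out[order(names(out))]
}
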