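# Version string for the fragment canonical-orientation convention;
# recorded in pattern-library metadata (mixing conventions would silently
# corrupt pattern counts).
.pf_fragment_convention <- "pf-frag-lexmin-1.0"

#' Enumerate three-atom protein fragments
#'
#' A fragment is a simple path of three covalently linked heavy atoms in the
#' bond graph. Each undirected path is emitted exactly once, oriented so
#' that the (residue name, atom name) label sequence is lexicographically
#' smallest end-first (ties broken by atom index); the first atom of the
#' oriented triple is the fragment anchor used for contact distances.
#' Fragments may span residues via peptide bonds.
#'
#' @param atoms protein atom table (heavy atoms).
#' @param bonds bond index matrix from [perceive_bonds].
#' @return data frame with columns `i1,i2,i3` (row indices into `atoms`,
#'   `i1` = anchor) and `type_key` ("anchor-resid:name1:name2:name3"),
#'   sorted by (i1, i2, i3).
#' @export
enumerate_fragments <- function(atoms, bonds) {
  n <- nrow(atoms)
  bonds <- .pf_bond_matrix(bonds)
  empty <- data.frame(i1 = integer(0), i2 = integer(0), i3 = integer(0),
                      type_key = character(0), stringsAsFactors = FALSE)
  if (n < 3 || nrow(bonds) < 2) return(empty)
  adj <- .pf_adjacency(n, bonds)
  lab <- paste(atoms$resid, atoms$name, sep = ":")
  rows <- list()
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    for (p in seq_along(nb)[-length(nb)]) for (q in seq((p + 1), length(nb))) {
      a <- nb[p]; c <- nb[q]
      # canonical orientation: smaller end label (then index) first
      if (lab[a] < lab[c] || (lab[a] == lab[c] && a < c)) {
        rows[[length(rows) + 1]] <- c(a, b, c)
      } else {
        rows[[length(rows) + 1]] <- c(c, b, a)
      }
    }
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(i1 = m[, 1], i2 = m[, 2], i3 = m[, 3],
                    type_key = paste(atoms$resid[m[, 1]], atoms$name[m[, 1]],
                                     atoms$name[m[, 2]], atoms$name[m[, 3]],
                                     sep = ":"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$i1, out$i2, out$i3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
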