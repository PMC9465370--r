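# Version string for the typing rule table; recorded in pattern-library
# metadata so libraries built under different rules can never be mixed.
.pf_sybyl_version <- "pf-sybyl-1.0"

# Bond-length thresholds (Angstrom) used to infer higher bond order between
# heavy-atom pairs when no explicit orders are available. Keys are sorted
# element pairs.
.pf_order_thresholds <- list(
  "C|C" = c(triple = 1.25, double = 1.38),
  "C|N" = c(triple = 1.20, double = 1.31),
  "C|O" = c(double = 1.30),
  "C|S" = c(double = 1.71),
  "N|N" = c(triple = 1.15, double = 1.28),
  "N|O" = c(double = 1.28),
  "O|S" = c(double = 1.50),
  "O|P" = c(double = 1.55)
)

.pf_elem_pair <- function(e1, e2) paste(pmin(e1, e2), pmax(e1, e2), sep = "|")

# Infer 1/2/3 bond orders from interatomic distances.
.pf_infer_orders <- function(atoms, bonds) {
  if (nrow(bonds) == 0) return(integer(0))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                     xyz[bonds[, 2], , drop = FALSE])^2))
  key <- .pf_elem_pair(atoms$element[bonds[, 1]], atoms$element[bonds[, 2]])
  ord <- rep(1L, nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    th <- .pf_order_thresholds[[key[k]]]
    if (is.null(th)) next
    if (!is.na(th["triple"]) && d[k] <= th["triple"]) ord[k] <- 3L
    else if (d[k] <= th["double"]) ord[k] <- 2L
  }
  ord
}

# All simple cycles of size 3..7 in the bond graph, as a list of vertex sets.
.pf_find_rings <- function(n, bonds, max_size = 7) {
  adj <- .pf_adjacency(n, bonds)
  rings <- list()
  seen <- character(0)
  path <- integer(max_size)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    for (w in adj[[v]]) {
      if (w == start && depth >= 3) {
        key <- paste(sort(path[seq_len(depth)]), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- sort(path[seq_len(depth)])
        }
      } else if (depth < max_size && w > start &&
                 !(w %in% path[seq_len(depth)])) {
        dfs(start, w, depth + 1)
      }
    }
  }
  for (s in seq_len(n)) if (length(adj[[s]])) dfs(s, s, 1L)
  # keep smallest rings: drop any ring that is a superset union of smaller ones
  rings[order(lengths(rings))]
}

.pf_adjacency <- function(n, bonds) {
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# RMS deviation of points from their best-fit plane.
.pf_planarity <- function(xyz) {
  c0 <- colMeans(xyz)
  m <- sweep(xyz, 2, c0)
  sv <- svd(m)
  sqrt(mean((m %*% sv$v[, 3])^2))
}

#' Detect aromatic rings
#'
#' A ring is flagged aromatic when it has 5-7 members, every member is C, N,
#' O or S with at most 3 heavy neighbours (sp2-consistent), and the ring is
#' planar within 0.1 Angstrom RMS of its best-fit plane.
#'
#' @param atoms atom table.
#' @param bonds bond index matrix.
#' @return logical vector: is each atom a member of an aromatic ring?
#' @export
detect_aromatic <- function(atoms, bonds) {
  n <- nrow(atoms)
  arom <- rep(FALSE, n)
  if (n < 5 || nrow(bonds) == 0) return(arom)
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (ring in .pf_find_rings(n, bonds)) {
    if (length(ring) < 5 || length(ring) > 7) next
    if (!all(atoms$element[ring] %in% c("C", "N", "O", "S"))) next
    if (any(deg[ring] > 3)) next
    if (.pf_planarity(xyz[ring, , drop = FALSE]) > 0.1) next
    arom[ring] <- TRUE
  }
  arom
}

#' Assign SYBYL atom types to heavy atoms
#'
#' A deterministic, self-contained rule table keyed on element, heavy-atom
#' degree, aromatic-ring membership and neighbour pattern, with bond orders
#' inferred from interatomic distances. The vocabulary emitted is: C.1 C.2
#' C.3 C.ar, N.1 N.2 N.3 N.4 N.ar N.am, O.2 O.3 O.co2, S.2 S.3 S.O S.O2,
#' P.3, F Cl Br I, and Du for anything unclassifiable. Inputs must be
#' hydrogen-free; isolated (degree-0) C/N/O default to the sp3 type.
#'
#' @param atoms atom table (ligand heavy atoms).
#' @param bonds bond index matrix (e.g. from [perceive_bonds]).
#' @param aromatic optional logical vector overriding [detect_aromatic].
#' @return character vector of SYBYL type codes, one per atom.
#' @export
assign_sybyl_types <- function(atoms, bonds, aromatic = NULL) {
  n <- nrow(atoms)
  if (n == 0) return(character(0))
  bonds <- .pf_bond_matrix(bonds)
  if (is.null(aromatic)) aromatic <- detect_aromatic(atoms, bonds)
  adj <- .pf_adjacency(n, bonds)
  deg <- lengths(adj)
  orders <- .pf_infer_orders(atoms, bonds)
  elem <- atoms$element

  # max inferred order on any bond incident to atom i
  max_order <- rep(0L, n)
  # order of the bond between i and j (0 if none)
  bond_order <- function(i, j) {
    k <- which((bonds[, 1] == i & bonds[, 2] == j) |
               (bonds[, 1] == j & bonds[, 2] == i))
    if (length(k)) orders[k[1]] else 0L
  }
  for (k in seq_len(nrow(bonds))) {
    max_order[bonds[k, 1]] <- max(max_order[bonds[k, 1]], orders[k])
    max_order[bonds[k, 2]] <- max(max_order[bonds[k, 2]], orders[k])
  }

  # is atom i a carbonyl-like carbon (C with O/S neighbour at double-bond
  # distance)?
  carbonyl_c <- vapply(seq_len(n), function(i) {
    elem[i] == "C" && any(vapply(adj[[i]], function(j)
      elem[j] %in% c("O", "S") && bond_order(i, j) >= 2L, logical(1)))
  }, logical(1))

  type_one <- function(i) {
    e <- elem[i]
    nb <- adj[[i]]
    switch(e,
      "F" = "F", "CL" = "Cl", "BR" = "Br", "I" = "I",
      "P" = "P.3",
      "S" = {
        n_o2 <- sum(vapply(nb, function(j)
          elem[j] == "O" && bond_order(i, j) >= 2L, logical(1)))
        if (n_o2 >= 2) "S.O2"
        else if (n_o2 == 1) "S.O"
        else if (max_order[i] >= 2L) "S.2"
        else "S.3"
      },
      "O" = {
        if (deg[i] >= 2) "O.3"
        else if (deg[i] == 1) {
          j <- nb[1]
          # carboxylate-like: terminal O on a C carrying two terminal oxygens
          if (elem[j] == "C") {
            term_o <- sum(vapply(adj[[j]], function(k)
              elem[k] == "O" && deg[k] == 1, logical(1)))
            if (term_o >= 2) return("O.co2")
          }
          if (bond_order(i, j) >= 2L) "O.2" else "O.3"
        } else "O.3"
      },
      "N" = {
        if (aromatic[i]) "N.ar"
        else if (any(carbonyl_c[nb])) "N.am"
        else if (deg[i] >= 4) "N.4"
        else if (max_order[i] >= 3L) "N.1"
        else if (max_order[i] == 2L) "N.2"
        else "N.3"
      },
      "C" = {
        if (aromatic[i]) "C.ar"
        else if (max_order[i] >= 3L) "C.1"
        else if (max_order[i] == 2L) "C.2"
        else "C.3"
      },
      "Du")
  }
  vapply(seq_len(n), type_one, character(1))
}
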