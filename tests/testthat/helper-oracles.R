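# Independent oracles used across the suite. These deliberately use the
# most naive formulation available (double loops, exhaustive scans) and
# share no code with the package implementation paths they check.

# exhaustive O(n*m) contact scan: which (ligand, fragment-anchor) pairs lie
# within cutoff (inclusive)?
oracle_contact_pairs <- function(L, anchors, cutoff) {
  hits <- list()
  for (i in seq_len(nrow(L))) {
    for (j in seq_len(nrow(anchors))) {
      d <- sqrt(sum((L[i, ] - anchors[j, ])^2))
      if (d <= cutoff) hits[[length(hits) + 1]] <- c(i, j, d)
    }
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 3))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# exhaustive 3-path enumeration from pairs of bonds sharing one atom
oracle_three_paths <- function(bonds) {
  if (nrow(bonds) < 2) return(character(0))
  paths <- character(0)
  for (a in seq_len(nrow(bonds) - 1)) {
    for (b in (a + 1):nrow(bonds)) {
      shared <- intersect(bonds[a, ], bonds[b, ])
      if (length(shared) != 1) next
      ends <- sort(c(setdiff(bonds[a, ], shared), setdiff(bonds[b, ], shared)))
      paths <- c(paths, paste(ends[1], shared, ends[2]))
    }
  }
  sort(unique(paths))
}

# Mann-Whitney AUC with half credit for ties
oracle_mw_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  u <- 0
  for (p in pos) for (q in neg)
    u <- u + if (p > q) 1 else if (p == q) 0.5 else 0
  u / (length(pos) * length(neg))
}

# exhaustive sens/spec at one threshold (rule: score >= t is positive)
oracle_sens_spec <- function(scores, labels, t) {
  pred <- scores >= t
  c(sens = sum(pred & labels) / sum(labels),
    spec = sum(!pred & !labels) / sum(!labels))
}

# random connected-ish bond graph over n atoms
random_bond_graph <- function(n, extra = n %/% 3, seed = 1) {
  withr::with_seed(seed, {
    bonds <- if (n >= 2) cbind(2:n, sapply(2:n, function(i)
      sample.int(i - 1, 1))) else matrix(integer(0), ncol = 2)
    if (extra > 0 && n >= 3) {
      more <- t(replicate(extra, sort(sample.int(n, 2))))
      bonds <- rbind(bonds, more)
    }
    bonds <- unique(t(apply(bonds, 1, sort)))
    bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  })
}

# random extraction fixture: ligand atoms, protein atoms, a fragment table
# over random bonded-index triples, and arbitrary type labels
random_contact_fixture <- function(n_lig, n_frag, seed, box = 25) {
  withr::with_seed(seed, {
    n_prot <- n_frag * 3
    prot <- pf_atoms(serial = seq_len(n_prot), name = "CX", element = "C",
                     x = runif(n_prot, 0, box), y = runif(n_prot, 0, box),
                     z = runif(n_prot, 0, box),
                     resno = rep(seq_len(n_frag), each = 3), resid = "RND")
    lig <- pf_atoms(serial = n_prot + seq_len(n_lig), name = "L",
                    element = sample(c("C", "N", "O"), n_lig, TRUE),
                    x = runif(n_lig, 0, box), y = runif(n_lig, 0, box),
                    z = runif(n_lig, 0, box), resid = "LIG", het = TRUE)
    idx <- matrix(seq_len(n_prot), ncol = 3, byrow = TRUE)
    fragments <- data.frame(i1 = idx[, 1], i2 = idx[, 2], i3 = idx[, 3],
                            type_key = paste0("RND:T", seq_len(n_frag) %% 7))
    types <- sample(c("C.3", "C.ar", "N.3", "O.3"), n_lig, TRUE)
    list(structure = pf_complex(prot, lig), fragments = fragments,
         types = types)
  })
}

random_rotation_matrix <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# apply a rigid motion to every atom of a complex
transform_complex <- function(cx, R = diag(3), t = c(0, 0, 0)) {
  for (half in c("protein", "ligand")) {
    xyz <- as.matrix(cx[[half]][, c("x", "y", "z")]) %*% t(R)
    cx[[half]]$x <- xyz[, 1] + t[1]
    cx[[half]]$y <- xyz[, 2] + t[2]
    cx[[half]]$z <- xyz[, 3] + t[3]
  }
  cx
}

# minimal fixed-width PDB record builder for parser edge-case tests
pdb_record <- function(type = "ATOM", serial = 1, name = "CA",
                       resid = "GLY", chain = "A", resno = 1,
                       x = 0, y = 0, z = 0, occ = 1, elem = "C",
                       alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resid, chain, resno, x, y, z, occ, 0,
          elem)
}
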