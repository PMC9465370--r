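# Residue names never eligible as ligand: waters.
.pf_waters <- c("HOH", "WAT", "DOD", "H2O")

# Common buffer components / monoatomic ions excluded from ligand selection
# by default (configurable in parse_pdb_complex).
.pf_ions <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
              "CO", "CD", "HG", "IOD", "BR", "CS", "LI", "SO4", "PO4",
              "GOL", "EDO", "PEG", "ACT", "DMS", "FMT", "NO3", "EPE",
              "TRS", "MES", "BME")

#' Construct an atom table
#'
#' Atoms are stored as a data frame, one row per atom, in file order. This is
#' the common currency of the package: both halves of a [pf_complex] are atom
#' tables.
#'
#' @param serial integer record ids (unique within a structure).
#' @param name atom names (PDB column 13-16 convention, stored trimmed).
#' @param element element symbols (e.g. "C", "N", "CL").
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param chain chain identifiers.
#' @param resno residue numbers.
#' @param insert insertion codes ("" when absent).
#' @param resid residue names.
#' @param het logical, HETATM record or not.
#' @param altloc alternate-location indicator ("" when absent).
#' @return data frame with one row per atom.
#' @export
pf_atoms <- function(serial, name, element, x, y, z, chain = "A",
                     resno = 1L, insert = "", resid = "UNK",
                     het = FALSE, altloc = "") {
  df <- data.frame(serial = as.integer(serial), name = as.character(name),
                   element = toupper(as.character(element)),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   chain = as.character(chain), resno = as.integer(resno),
                   insert = as.character(insert), resid = as.character(resid),
                   het = as.logical(het), altloc = as.character(altloc),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(df$element))) stop("atom elements must be non-empty")
  df
}

#' Construct a protein-ligand complex
#'
#' A `pf_complex` holds the heavy-atom protein and ligand halves of one
#' structure plus covalent bonds (index pairs into the respective atom
#' tables) and a free-text source identifier.
#'
#' @param protein,ligand atom tables (see [pf_atoms]).
#' @param protein_bonds,ligand_bonds two-column integer matrices of bonded
#'   atom indices (rows of `protein` / `ligand`); may have zero rows.
#' @param source_id free-text identifier (e.g. a 4-character PDB code).
#' @return object of class `pf_complex`.
#' @export
pf_complex <- function(protein, ligand, protein_bonds = NULL,
                       ligand_bonds = NULL, source_id = "unknown") {
  protein_bonds <- .pf_bond_matrix(protein_bonds)
  ligand_bonds <- .pf_bond_matrix(ligand_bonds)
  if (nrow(protein_bonds) && max(protein_bonds) > nrow(protein))
    stop("protein bond index out of range")
  if (nrow(ligand_bonds) && max(ligand_bonds) > nrow(ligand))
    stop("ligand bond index out of range")
  structure(list(protein = protein, ligand = ligand,
                 protein_bonds = protein_bonds, ligand_bonds = ligand_bonds,
                 source_id = source_id),
            class = "pf_complex")
}

.pf_bond_matrix <- function(b) {
  if (is.null(b) || (is.matrix(b) && nrow(b) == 0) || length(b) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  b <- matrix(as.integer(b), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (any(b < 1)) stop("bond indices must be >= 1")
  # store undirected bonds canonically: i < j, unique, sorted
  swap <- b[, 1] > b[, 2]
  b[swap, ] <- b[swap, c(2, 1)]
  b <- unique(b[b[, 1] != b[, 2], , drop = FALSE])
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

#' @export
print.pf_complex <- function(x, ...) {
  cat(sprintf("<pf_complex %s: %d protein atoms (%d bonds), %d ligand atoms (%d bonds)>\n",
              x$source_id, nrow(x$protein), nrow(x$protein_bonds),
              nrow(x$ligand), nrow(x$ligand_bonds)))
  invisible(x)
}

#' Parse a PDB-format complex
#'
#' Reads fixed-width ATOM/HETATM (and CONECT) records, resolves alternate
#' locations (highest occupancy wins; ties broken alphabetically by altloc),
#' keeps only the first MODEL of multi-model files, and partitions atoms into
#' protein (ATOM records) and ligand (selected HETATM records). Waters are
#' never selectable as ligand; common buffer ions are excluded by default.
#'
#' @param text a file path, or a character vector of PDB lines.
#' @param ligand_selector which HETATM residue(s) form the ligand: a residue
#'   name (e.g. `"LIG"`), `"chain:X"` to take all eligible HETATMs on chain
#'   X, or `"any"` for every eligible HETATM residue.
#' @param exclude_ions drop common buffer/ion residues from ligand
#'   eligibility (default TRUE).
#' @param source_id identifier stored on the result; defaults to the file
#'   base name or "inline".
#' @return a [pf_complex]. Ligand bonds are populated from CONECT records
#'   when present; protein bonds are left for [perceive_bonds].
#' @export
parse_pdb_complex <- function(text, ligand_selector = "any",
                              exclude_ions = TRUE, source_id = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent)$", "", basename(text))
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "inline"
  }
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]

  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_rec)) stop("no ATOM or HETATM records found")
  # validate fixed-width records up front so errors carry line numbers
  for (i in which(is_rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    crd <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(crd))))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom

  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  blank <- !nzchar(elem)
  if (any(blank)) elem[blank] <- .pf_guess_element(at$elety[blank])
  alt <- ifelse(is.na(at$alt), "", at$alt)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  occ <- ifelse(is.na(at$o), 1, at$o)
  chain <- ifelse(is.na(at$chain), " ", at$chain)

  atoms <- pf_atoms(serial = at$eleno, name = trimws(at$elety),
                    element = elem, x = at$x, y = at$y, z = at$z,
                    chain = chain, resno = at$resno, insert = ins,
                    resid = trimws(at$resid), het = at$type == "HETATM",
                    altloc = alt)

  # altloc resolution: per atom site keep highest occupancy, tie -> lowest
  # altloc character
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$name, sep = "|")
  ord <- order(key, -occ, atoms$altloc)
  keep <- sort(ord[!duplicated(key[ord])])
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL

  prot <- atoms[!atoms$het, , drop = FALSE]
  het <- atoms[atoms$het, , drop = FALSE]
  eligible <- !(het$resid %in% .pf_waters)
  if (exclude_ions) eligible <- eligible & !(het$resid %in% .pf_ions)

  sel <- if (identical(ligand_selector, "any")) {
    eligible
  } else if (grepl("^chain:", ligand_selector)) {
    eligible & het$chain == sub("^chain:", "", ligand_selector)
  } else {
    eligible & het$resid == ligand_selector
  }
  if (!any(sel))
    stop(sprintf("ligand not found: no eligible HETATM residue matches '%s'",
                 ligand_selector))
  lig <- het[sel, , drop = FALSE]
  rownames(prot) <- rownames(lig) <- NULL

  lig_bonds <- .pf_conect_bonds(lines, lig$serial)
  pf_complex(prot, lig, ligand_bonds = lig_bonds, source_id = source_id)
}

.pf_guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE", "MN", "CU", "NI",
           "CO", "CD", "SI")
  vapply(nm, function(s) {
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two) substr(s, 1, 2)
    else substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.pf_conect_bonds <- function(lines, serials) {
  con <- lines[grepl("^CONECT", lines)]
  if (!length(con)) return(NULL)
  out <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                 "\\s+")[[1]]))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2) next
    a <- match(flds[1], serials)
    bs <- match(flds[-1], serials)
    ok <- !is.na(a) & !is.na(bs)
    if (any(ok)) out[[length(out) + 1]] <- cbind(a, bs[ok])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Remove hydrogen and deuterium atoms
#'
#' Drops every atom with element H or D from both halves of the complex,
#' removes bonds incident to dropped atoms, and preserves the relative order
#' of the remaining atoms. Idempotent.
#'
#' @param structure a [pf_complex].
#' @return a [pf_complex] with heavy atoms only.
#' @export
strip_hydrogens <- function(structure) {
  strip_one <- function(atoms, bonds) {
    keep <- !(atoms$element %in% c("H", "D"))
    map <- integer(length(keep))
    map[keep] <- seq_len(sum(keep))
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
    if (nrow(bonds)) {
      ok <- keep[bonds[, 1]] & keep[bonds[, 2]]
      bonds <- cbind(map[bonds[ok, 1]], map[bonds[ok, 2]])
    }
    list(atoms = atoms, bonds = bonds)
  }
  p <- strip_one(structure$protein, structure$protein_bonds)
  l <- strip_one(structure$ligand, structure$ligand_bonds)
  pf_complex(p$atoms, l$atoms, p$bonds, l$bonds, structure$source_id)
}

#' Compute a docking pocket box from ligand coordinates
#'
#' The box centre is the per-axis midpoint of the ligand heavy-atom extent;
#' each edge is the extent plus twice the margin, floored at `min_edge`.
#'
#' @param ligand_atoms atom table (see [pf_atoms]); hydrogens are ignored.
#' @param margin padding added on every side, Angstrom (default 4).
#' @param min_edge minimum edge length, Angstrom (default 10).
#' @return list with `center` and `edges`, each a named 3-vector (x, y, z).
#' @export
compute_pocket_box <- function(ligand_atoms, margin = 4.0, min_edge = 10.0) {
  heavy <- ligand_atoms[!(ligand_atoms$element %in% c("H", "D")), ,
                        drop = FALSE]
  if (nrow(heavy) == 0) stop("no ligand heavy atoms to derive a box from")
  if (margin < 0) stop("margin must be >= 0")
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  center <- (lo + hi) / 2
  edges <- pmax(hi - lo + 2 * margin, min_edge)
  names(center) <- names(edges) <- c("x", "y", "z")
  list(center = center, edges = edges)
}

#' Write a complex as PDB
#'
#' Protein atoms are emitted as ATOM records and ligand atoms as HETATM,
#' followed by CONECT records for ligand bonds. Output parses back through
#' [parse_pdb_complex] with coordinates preserved to PDB precision (1e-3
#' Angstrom).
#'
#' @param structure a [pf_complex].
#' @param file output path.
#' @export
write_pdb <- function(structure, file) {
  p <- structure$protein
  l <- structure$ligand
  all <- rbind(p, l)
  if (nrow(all) == 0) stop("empty structure")
  xyz <- as.matrix(all[, c("x", "y", "z")])
  if (any(xyz >= 10000 | xyz <= -1000))
    stop("coordinates exceed PDB fixed-width field range")
  serial <- seq_len(nrow(all))
  bio3d::write.pdb(file = file,
                   type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
                   xyz = as.vector(t(xyz)),
                   resno = all$resno, resid = all$resid, eleno = serial,
                   elety = all$name, chain = all$chain,
                   insert = ifelse(nzchar(all$insert), all$insert, NA),
                   o = rep(1.0, nrow(all)), b = rep(0.0, nrow(all)),
                   elesy = all$element)
  if (nrow(structure$ligand_bonds)) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[lines != "END"]
    lb <- structure$ligand_bonds + nrow(p)
    con <- sprintf("CONECT%5d%5d", lb[, 1], lb[, 2])
    writeLines(c(lines, con, "END"), file)
  }
  invisible(file)
}
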