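#' Parse a PDB structure into an atom table
#'
#' Thin wrapper over [bio3d::read.pdb()] returning a plain atom table.
#' HETATM records (including the \[4Fe4S\] cluster residues SF4/FS4) are
#' retained, alternate locations are resolved to the highest-occupancy
#' conformer, hydrogens are dropped, and only the first model of a
#' multi-model file is used.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @return Data frame with columns `name`, `element`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`, `occupancy`, `het`.
#' @export
parse_structure <- function(x) {
  path <- x
  if (length(x) > 1 || !file.exists(x)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(x, path)
    on.exit(unlink(path))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!nrow(at)) stop("no ATOM/HETATM records found")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("malformed coordinate fields")
  # resolve altLoc: keep highest occupancy per (chain, resno, insert, name)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[which.max(at$o[idx])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- toupper(substr(gsub("[0-9']", "", at$elety[miss]), 1, 1))
  at <- at[toupper(elem) != "H", , drop = FALSE]
  elem <- elem[toupper(elem) != "H"]
  out <- data.frame(name = at$elety, element = toupper(trimws(elem)),
                    resid = at$resid, resno = at$resno, chain = at$chain,
                    x = at$x, y = at$y, z = at$z, occupancy = at$o,
                    het = at$type == "HETATM",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

cluster_atoms <- function(atoms) {
  atoms[atoms$resid %in% c("SF4", "FS4"), , drop = FALSE]
}

pair_dist <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Extract \[4Fe4S\] cluster geometry
#'
#' Finds the four cluster Fe atoms and their bonding partners under a
#' distance cutoff, classifying each Fe-S bond as `core` (inorganic
#' sulfide of the SF4/FS4 residue) or `thiolate` (cysteine S-gamma). In
#' a well-formed cubane every Fe makes >= 3 core bonds and exactly one
#' thiolate bond; deviations raise a "malformed cubane" warning but the
#' geometry is still returned.
#'
#' @param atoms Atom table from [parse_structure()].
#' @param bond_cutoff Maximum Fe-S bond length, Angstrom (default 2.6).
#' @return A `cluster_geometry` list: `fe`, `s_core`, `s_cys` atom
#'   tables, `bonds` (data frame with `length` and `class`), and
#'   per-class `summary` (n, mean, sd).
#' @export
extract_cluster <- function(atoms, bond_cutoff = 2.6) {
  cl <- cluster_atoms(atoms)
  fe <- cl[cl$element == "FE", , drop = FALSE]
  s_core <- cl[cl$element == "S", , drop = FALSE]
  s_cys <- atoms[atoms$resid == "CYS" & atoms$name == "SG", , drop = FALSE]
  if (nrow(fe) != 4)
    stop(sprintf("expected 4 cluster Fe atoms, found %d", nrow(fe)))
  bonds <- list()
  add_bonds <- function(partners, class) {
    for (i in seq_len(nrow(fe))) for (j in seq_len(nrow(partners))) {
      d <- pair_dist(fe[i, ], partners[j, ])
      if (d <= bond_cutoff)
        bonds[[length(bonds) + 1L]] <<- data.frame(
          fe = fe$name[i], partner = partners$name[j],
          partner_resno = partners$resno[j], length = d, class = class)
    }
  }
  add_bonds(s_core, "core")
  add_bonds(s_cys, "thiolate")
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(fe = character(), partner = character(),
               partner_resno = integer(), length = numeric(),
               class = character())
  core_per_fe <- table(factor(bonds$fe[bonds$class == "core"],
                              levels = fe$name))
  thio_per_fe <- table(factor(bonds$fe[bonds$class == "thiolate"],
                              levels = fe$name))
  if (any(core_per_fe < 3) || any(thio_per_fe != 1))
    warning("malformed cubane: expected >= 3 core and exactly 1 thiolate ",
            "bond per Fe under the cutoff")
  summ <- do.call(rbind, lapply(c("core", "thiolate", "all"), function(cl2) {
    len <- if (cl2 == "all") bonds$length else
      bonds$length[bonds$class == cl2]
    data.frame(class = cl2, n = length(len),
               mean = if (length(len)) mean(len) else NA_real_,
               sd = if (length(len) > 1) stats::sd(len) else NA_real_)
  }))
  structure(list(fe = fe, s_core = s_core, s_cys = s_cys,
                 bonds = bonds, summary = summ,
                 bond_cutoff = bond_cutoff),
            class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat("<cluster_geometry>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

nucleic_resids <- c("DA", "DC", "DG", "DT")

#' Protein-DNA atomic distances
#'
#' Donor atoms are the \[4Fe4S\] cluster Fe/S atoms plus the backbone
#' amide N of protein residues; acceptors are the DNA backbone/phosphate
#' atoms (P, OP1, OP2, O3', O5') of DA/DC/DG/DT residues. All
#' donor-acceptor distances are computed and the `n_shortest` retained,
#' sorted ascending.
#'
#' @param atoms Atom table from [parse_structure()].
#' @param n_shortest Number of shortest distances to keep (default 50).
#' @return A `distance_set` list: `pairs` (data frame of donor,
#'   acceptor, distance), and `selection_rule` recording the rules used.
#' @export
protein_dna_distances <- function(atoms, n_shortest = 50) {
  dna <- atoms[atoms$resid %in% nucleic_resids, , drop = FALSE]
  if (!nrow(dna)) stop("no nucleic chain (DA/DC/DG/DT residues) found")
  prot <- atoms[!atoms$resid %in% nucleic_resids &
                  !atoms$resid %in% c("SF4", "FS4", "HOH"), , drop = FALSE]
  if (!nrow(prot)) stop("no protein chain found")
  donors <- rbind(cluster_atoms(atoms),
                  prot[prot$name == "N", , drop = FALSE])
  acceptors <- dna[dna$name %in% c("P", "OP1", "OP2", "O3'", "O5'"), ,
                   drop = FALSE]
  if (!nrow(donors) || !nrow(acceptors))
    stop("no donor or acceptor atoms under the selection rule")
  dd <- as.matrix(donors[, c("x", "y", "z")])
  aa <- as.matrix(acceptors[, c("x", "y", "z")])
  dmat <- sqrt(outer(rowSums(dd^2), rowSums(aa^2), "+") - 2 * dd %*% t(aa))
  npair <- length(dmat)
  if (n_shortest > npair)
    stop(sprintf("n_shortest = %d exceeds the %d available pairs",
                 n_shortest, npair))
  ord <- order(dmat)[seq_len(n_shortest)]
  ij <- arrayInd(ord, dim(dmat))
  pairs <- data.frame(
    donor = paste(donors$resid[ij[, 1]], donors$resno[ij[, 1]],
                  donors$name[ij[, 1]]),
    acceptor = paste(acceptors$resid[ij[, 2]], acceptors$resno[ij[, 2]],
                     acceptors$name[ij[, 2]]),
    distance = dmat[ord])
  structure(list(
    pairs = pairs,
    selection_rule = paste("donors: cluster Fe/S + protein backbone N;",
                           "acceptors: DNA P/OP1/OP2/O3'/O5';",
                           sprintf("%d shortest retained", n_shortest))),
    class = "distance_set")
}

#' Histogram of a distance set
#'
#' @param distance_set A `distance_set` from [protein_dna_distances()],
#'   or a numeric vector of distances.
#' @param bin_width Bin width, Angstrom (> 0).
#' @return List with `table` (data frame `lo`, `hi`, `count`) and
#'   `summary` (min, max, mean, n).
#' @export
distance_histogram <- function(distance_set, bin_width = 1) {
  d <- if (inherits(distance_set, "distance_set"))
    distance_set$pairs$distance else as.numeric(distance_set)
  if (!length(d)) stop("empty distance set")
  if (bin_width <= 0) stop("bin_width must be > 0")
  lo0 <- floor(min(d) / bin_width) * bin_width
  breaks <- seq(lo0, max(d) + bin_width, by = bin_width)
  cnt <- as.integer(table(cut(d, breaks, right = FALSE,
                              include.lowest = TRUE)))
  list(table = data.frame(lo = breaks[-length(breaks)],
                          hi = breaks[-1], count = cnt),
       summary = list(min = min(d), max = max(d), mean = mean(d),
                      n = length(d)))
}

# --- synthetic structure fixtures ----------------------------------------

pdb_line <- function(rec, serial, name, resid, chain, resno, xyz,
                     occ = 1.00, elem) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, "", resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0.00, elem)
}

#' Synthetic idealized \[4Fe4S\] cubane in PDB format
#'
#' Builds an idealized cubane: Fe and inorganic S alternate on the
#' corners of a cube with edge `bond_length` (so all 12 core Fe-S bonds
#' have exactly that length), and each Fe carries one cysteine S-gamma
#' at `bond_length` along the outward body diagonal. This is a synthetic
#' reference geometry, not crystallographic data.
#'
#' @param bond_length Fe-S bond length, Angstrom (default 2.30).
#' @param displace_fe Optional length-3 vector added to the first Fe's
#'   coordinates, for perturbation tests.
#' @return Character vector of PDB lines.
#' @export
synthetic_cubane_pdb <- function(bond_length = 2.30, displace_fe = NULL) {
  a <- bond_length
  fe <- rbind(c(0, 0, 0), c(a, a, 0), c(a, 0, a), c(0, a, a))
  s  <- rbind(c(a, 0, 0), c(0, a, 0), c(0, 0, a), c(a, a, a))
  if (!is.null(displace_fe)) fe[1, ] <- fe[1, ] + displace_fe
  ctr <- c(a, a, a) / 2
  lines <- c("HEADER    SYNTHETIC IDEALIZED [4FE4S] CUBANE")
  serial <- 0L
  # cysteine S-gamma along each Fe's outward diagonal
  for (i in 1:4) {
    serial <- serial + 1L
    dirv <- fe[i, ] - ctr; dirv <- dirv / sqrt(sum(dirv^2))
    sg <- fe[i, ] + bond_length * dirv
    lines <- c(lines, pdb_line("ATOM", serial, "SG", "CYS", "A", i, sg,
                               elem = "S"))
  }
  for (i in 1:4) {
    serial <- serial + 1L
    lines <- c(lines, pdb_line("HETATM", serial, sprintf("FE%d", i), "SF4",
                               "A", 100, fe[i, ], elem = "FE"))
  }
  for (i in 1:4) {
    serial <- serial + 1L
    lines <- c(lines, pdb_line("HETATM", serial, sprintf("S%d", i), "SF4",
                               "A", 100, s[i, ], elem = "S"))
  }
  c(lines, "END")
}

#' Synthetic toy protein-DNA complex in PDB format
#'
#' A minimal two-chain fixture: a protein chain A of glycine backbone N
#' atoms plus an idealized \[4Fe4S\] cluster, and a DNA chain B of
#' phosphate-group atoms, built so that the closest donor-acceptor
#' contact is `closest` Angstrom (an Fe to a phosphorus placed along
#' the x axis). Synthetic geometry for testing the distance extraction,
#' not a crystal structure.
#'
#' @param closest Closest Fe-P contact distance, Angstrom.
#' @param n_res Number of protein residues (backbone N donors).
#' @param n_nuc Number of DNA residues (each contributes P, OP1, OP2,
#'   O3', O5').
#' @return Character vector of PDB lines.
#' @export
synthetic_complex_pdb <- function(closest = 7.5, n_res = 5, n_nuc = 2) {
  lines <- c("HEADER    SYNTHETIC PROTEIN-DNA TOY COMPLEX")
  serial <- 0L
  add <- function(rec, name, resid, chain, resno, xyz, elem, occ = 1) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_line(rec, serial, name, resid, chain, resno,
                                xyz, occ, elem))
  }
  for (i in seq_len(n_res))
    add("ATOM", "N", "GLY", "A", i, c(-10 - 3.8 * i, 5 * (i %% 2), 0), "N")
  a <- 2.3
  fe <- rbind(c(0, 0, 0), c(a, a, 0), c(a, 0, a), c(0, a, a))
  s <- rbind(c(a, 0, 0), c(0, a, 0), c(0, 0, a), c(a, a, a))
  for (i in 1:4) add("HETATM", sprintf("FE%d", i), "SF4", "A", 200,
                     fe[i, ], "FE")
  for (i in 1:4) add("HETATM", sprintf("S%d", i), "SF4", "A", 200,
                     s[i, ], "S")
  # closest hand-placed contact: cluster S at (a, 0, 0) to the first P
  for (j in seq_len(n_nuc)) {
    base <- c(a + closest + 6.5 * (j - 1), 0, 0)
    add("ATOM", "P", "DA", "B", j, base, "P")
    add("ATOM", "OP1", "DA", "B", j, base + c(0.8, 1.2, 0), "O")
    add("ATOM", "OP2", "DA", "B", j, base + c(0.8, -1.2, 0), "O")
    add("ATOM", "O5'", "DA", "B", j, base + c(1.4, 0, 1.1), "O")
    add("ATOM", "O3'", "DA", "B", j, base + c(1.2, 0, 1.3), "O")
  }
  c(lines, "END")
}
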