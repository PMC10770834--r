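#' Build a molecular structure from an atom table
#'
#' @param atoms Data frame with columns `serial` (unique integers), `name`,
#'   `element`, `residue_name` (3-letter code), `residue_number`, `chain`,
#'   `x`, `y`, `z` (Angstrom) and `is_ligand` (logical; HETATM-derived).
#' @return Object of class `pdb_structure` (a data frame of atoms).
#' @export
pdb_structure <- function(atoms) {
  need <- c("serial", "name", "element", "residue_name", "residue_number",
            "chain", "x", "y", "z", "is_ligand")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (!nrow(atoms)) stop("structure has no atoms")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("coordinates must be finite")
  if (any(!nzchar(atoms$element))) stop("element symbols must be non-empty")
  atoms <- as.data.frame(atoms)[, need]
  rownames(atoms) <- NULL
  class(atoms) <- c("pdb_structure", "data.frame")
  atoms
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d atoms (%d ligand), %d residues\n",
              nrow(x), sum(x$is_ligand),
              nrow(unique(x[, c("chain", "residue_number", "is_ligand")]))))
  invisible(x)
}

#' Coordinates of a structure as an N x 3 matrix
#' @param structure A `pdb_structure`.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

infer_element <- function(name) {
  # strip leading digits/spaces; two-letter elements are rare in protein
  # work, so the first alphabetic character is used
  s <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", name)))
  ifelse(nzchar(s), substr(s, 1L, 1L), "")
}

parse_pdb_lines <- function(lines, linenos) {
  num <- function(x, what, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: malformed %s field",
                   ln[which(is.na(v))[1L]], what))
    v
  }
  rec <- substr(lines, 1, 6)
  serial <- num(trimws(substr(lines, 7, 11)), "serial", linenos)
  name <- trimws(substr(lines, 13, 16))
  resn <- trimws(substr(lines, 18, 20))
  chain <- trimws(substr(lines, 22, 22))
  resno <- num(trimws(substr(lines, 23, 26)), "residue number", linenos)
  x <- num(trimws(substr(lines, 31, 38)), "x coordinate", linenos)
  y <- num(trimws(substr(lines, 39, 46)), "y coordinate", linenos)
  z <- num(trimws(substr(lines, 47, 54)), "z coordinate", linenos)
  elem <- trimws(substr(lines, 77, 78))
  elem <- ifelse(nzchar(elem), toupper(elem), infer_element(name))
  pdb_structure(data.frame(
    serial = serial, name = name, element = elem, residue_name = resn,
    residue_number = resno, chain = ifelse(nzchar(chain), chain, "A"),
    x = x, y = y, z = z,
    is_ligand = trimws(rec) == "HETATM" & resn != "HOH",
    stringsAsFactors = FALSE))
}

#' Read a PDB file
#'
#' Honors ATOM, HETATM, MODEL and ENDMDL records. HETATM atoms are flagged
#' as ligand except waters (residue name HOH), which are dropped entirely.
#'
#' @param path Path to a PDB file.
#' @param multi If `TRUE`, always return a list of structures (one per
#'   MODEL); by default a file without MODEL records returns a single
#'   `pdb_structure`.
#' @return A `pdb_structure`, or a list of them for multi-model files.
#' @export
read_pdb <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  rec <- substr(raw, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- startsWith(raw, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(is_model)
  keep <- which(is_atom & !grepl("HOH", substr(raw, 18, 20)))
  if (!length(keep)) stop("no non-water atoms in ", path)
  groups <- split(keep, model_id[keep])
  structures <- lapply(groups, function(idx) parse_pdb_lines(raw[idx], idx))
  names(structures) <- NULL
  if (length(structures) == 1L && !multi) structures[[1L]] else structures
}

#' Write one or more structures as a PDB file
#'
#' Multi-structure input is written as MODEL/ENDMDL blocks, readable back
#' with [read_pdb()] (and by standard trajectory tools).
#'
#' @param structure A `pdb_structure` or a list of them (shared topology).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  models <- if (inherits(structure, "pdb_structure")) list(structure) else structure
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    s <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     ifelse(s$is_ligand, "HETATM", "ATOM"),
                     s$serial, substr(s$name, 1, 4), s$residue_name,
                     s$chain, s$residue_number, s$x, s$y, s$z, 1, 0, s$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

split_protein_ligand <- function(structure) {
  prot <- structure[!structure$is_ligand & structure$residue_name != "HOH", , drop = FALSE]
  lig <- structure[structure$is_ligand, , drop = FALSE]
  if (!nrow(lig)) stop("no ligand in structure")
  if (!nrow(prot)) stop("no protein atoms in structure")
  list(protein = prot, ligand = lig)
}

pair_distances <- function(a, b) {
  # |a_i - b_j| for small atom sets; n x m matrix
  ax <- as.matrix(a[, c("x", "y", "z")]); bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  sqrt(pmax(d2, 0))
}

attached_hydrogens <- function(structure, atom_row, max_bond = 1.3) {
  h <- structure[structure$element == "H" &
                 structure$chain == atom_row$chain &
                 structure$residue_number == atom_row$residue_number &
                 structure$is_ligand == atom_row$is_ligand, , drop = FALSE]
  if (!nrow(h)) return(h)
  d <- sqrt((h$x - atom_row$x)^2 + (h$y - atom_row$y)^2 + (h$z - atom_row$z)^2)
  h[d <= max_bond, , drop = FALSE]
}

hda_angle <- function(h, d, a) {
  # angle at the donor between the D-H bond and the D-A axis, degrees
  v1 <- c(h$x - d$x, h$y - d$y, h$z - d$z)
  v2 <- c(a$x - d$x, a$y - d$y, a$z - d$z)
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect protein-ligand hydrogen bonds
#'
#' Geometric criterion: heavy-atom donor-acceptor distance at most
#' `d_cutoff` between protein N/O/S and ligand N/O (either direction). When
#' a candidate pair carries explicit hydrogens on at least one partner, that
#' partner must act as the donor with a hydrogen-donor-acceptor angle at
#' most `angle_cutoff`; with no explicit hydrogens the criterion is
#' distance-only. These are the usual MD-analysis defaults (3.5 Angstrom,
#' 30 degrees).
#'
#' @param structure A `pdb_structure` containing protein and ligand atoms.
#' @param d_cutoff Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff, degrees.
#' @return Data frame: `donor_serial`, `acceptor_serial`, `distance`,
#'   `angle` (NA without explicit hydrogens), `protein_chain`,
#'   `protein_residue_number`, `protein_residue_name`.
#' @export
find_hbonds <- function(structure, d_cutoff = 3.5, angle_cutoff = 30) {
  pl <- split_protein_ligand(structure)
  pcand <- pl$protein[pl$protein$element %in% c("N", "O", "S"), , drop = FALSE]
  lcand <- pl$ligand[pl$ligand$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(donor_serial = integer(), acceptor_serial = integer(),
                      distance = numeric(), angle = numeric(),
                      protein_chain = character(),
                      protein_residue_number = integer(),
                      protein_residue_name = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pcand) || !nrow(lcand)) return(empty)
  d <- pair_distances(pcand, lcand)
  hits <- which(d <= d_cutoff, arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    p <- pcand[hits[k, 1L], ]; l <- lcand[hits[k, 2L], ]
    hp <- attached_hydrogens(structure, p)
    hl <- attached_hydrogens(structure, l)
    donor <- NULL; acceptor <- NULL; ang <- NA_real_
    if (!nrow(hp) && !nrow(hl)) {
      donor <- p; acceptor <- l              # distance-only, roles nominal
    } else {
      if (nrow(hp)) {
        angs <- vapply(seq_len(nrow(hp)), function(i) hda_angle(hp[i, ], p, l), 0)
        if (min(angs) <= angle_cutoff) { donor <- p; acceptor <- l; ang <- min(angs) }
      }
      if (is.null(donor) && nrow(hl)) {
        angs <- vapply(seq_len(nrow(hl)), function(i) hda_angle(hl[i, ], l, p), 0)
        if (min(angs) <= angle_cutoff) { donor <- l; acceptor <- p; ang <- min(angs) }
      }
    }
    if (is.null(donor)) next
    rows[[length(rows) + 1L]] <- data.frame(
      donor_serial = donor$serial, acceptor_serial = acceptor$serial,
      distance = d[hits[k, 1L], hits[k, 2L]], angle = ang,
      protein_chain = p$chain, protein_residue_number = p$residue_number,
      protein_residue_name = p$residue_name, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_residue_number, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect protein-ligand hydrophobic contacts
#'
#' Carbon-carbon proximity criterion: every (protein C, ligand C) pair at
#' distance at most `d_cutoff` counts as one contact.
#'
#' @param structure A `pdb_structure` containing protein and ligand atoms.
#' @param d_cutoff Carbon-carbon distance cutoff, Angstrom (default 4.0).
#' @return Data frame: `protein_serial`, `ligand_serial`, `distance`,
#'   `protein_chain`, `protein_residue_number`, `protein_residue_name`.
#' @export
find_hydrophobic_contacts <- function(structure, d_cutoff = 4.0) {
  pl <- split_protein_ligand(structure)
  pc <- pl$protein[pl$protein$element == "C", , drop = FALSE]
  lc <- pl$ligand[pl$ligand$element == "C", , drop = FALSE]
  empty <- data.frame(protein_serial = integer(), ligand_serial = integer(),
                      distance = numeric(), protein_chain = character(),
                      protein_residue_number = integer(),
                      protein_residue_name = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pc) || !nrow(lc)) return(empty)
  d <- pair_distances(pc, lc)
  hits <- which(d <= d_cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  out <- data.frame(
    protein_serial = pc$serial[hits[, 1L]],
    ligand_serial = lc$serial[hits[, 2L]],
    distance = d[hits],
    protein_chain = pc$chain[hits[, 1L]],
    protein_residue_number = pc$residue_number[hits[, 1L]],
    protein_residue_name = pc$residue_name[hits[, 1L]],
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_residue_number, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue protein-ligand interaction profile
#'
#' Runs both contact finders and tallies hydrogen bonds and hydrophobic
#' contacts per protein residue.
#'
#' @param structure A `pdb_structure` with protein and ligand atoms.
#' @param hb_cutoff Hydrogen-bond distance cutoff, Angstrom.
#' @param hb_angle_cutoff Hydrogen-bond angle cutoff, degrees.
#' @param hydrophobic_cutoff Hydrophobic C-C cutoff, Angstrom.
#' @return Object of class `contact_profile`: `hydrogen_bonds`,
#'   `hydrophobic_contacts` (the finder outputs) and `per_residue_counts`
#'   (data frame `chain`, `residue_number`, `residue_name`, `n_hbond`,
#'   `n_hydrophobic`, ordered by residue number).
#' @export
interaction_summary <- function(structure, hb_cutoff = 3.5,
                                hb_angle_cutoff = 30, hydrophobic_cutoff = 4.0) {
  hb <- find_hbonds(structure, hb_cutoff, hb_angle_cutoff)
  hc <- find_hydrophobic_contacts(structure, hydrophobic_cutoff)
  key <- function(df) paste(df$protein_chain, df$protein_residue_number)
  all_keys <- unique(c(key(hb), key(hc)))
  per <- if (length(all_keys)) {
    info <- rbind(hb[, c("protein_chain", "protein_residue_number", "protein_residue_name")],
                  hc[, c("protein_chain", "protein_residue_number", "protein_residue_name")])
    info <- info[!duplicated(paste(info$protein_chain, info$protein_residue_number)), , drop = FALSE]
    data.frame(chain = info$protein_chain,
               residue_number = info$protein_residue_number,
               residue_name = info$protein_residue_name,
               n_hbond = as.integer(table(factor(key(hb), levels = key(info)))),
               n_hydrophobic = as.integer(table(factor(key(hc), levels = key(info)))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(), residue_number = integer(),
               residue_name = character(), n_hbond = integer(),
               n_hydrophobic = integer(), stringsAsFactors = FALSE)
  }
  per <- per[order(per$residue_number), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(hydrogen_bonds = hb, hydrophobic_contacts = hc,
                 per_residue_counts = per), class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: %d hydrogen bonds, %d hydrophobic contacts\n",
              nrow(x$hydrogen_bonds), nrow(x$hydrophobic_contacts)))
  if (nrow(x$per_residue_counts)) print(x$per_residue_counts)
  invisible(x)
}
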