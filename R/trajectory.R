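#' Default van der Waals radii (Angstrom) and probe radius for SASA
#'
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, water).
#' @param radii Named numeric vector element -> radius, Angstrom; overrides
#'   merge into the defaults (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
#'   P 1.80).
#' @return Object of class `atom_radii`: list with `radii` and
#'   `probe_radius`.
#' @export
atom_radii <- function(probe_radius = 1.4, radii = NULL) {
  base <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  if (!is.null(radii)) base[names(radii)] <- radii
  if (any(base <= 0) || probe_radius < 0) stop("radii must be positive")
  structure(list(radii = base, probe_radius = probe_radius), class = "atom_radii")
}

#' Atomic masses for common elements (u)
#' @param elements Character vector of element symbols.
#' @return Numeric vector of masses; errors on an unknown element.
#' @export
element_masses <- function(elements) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305, NA. = 22.990)
  m <- tab[toupper(elements)]
  if (anyNA(m))
    stop("no mass for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Assemble a trajectory
#'
#' @param topology A `pdb_structure` giving atom identities.
#' @param frames List of N x 3 coordinate matrices (Angstrom), N matching
#'   the topology atom count.
#' @param frame_times Optional numeric vector of frame times (ps).
#' @return Object of class `md_trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times = NULL) {
  if (!inherits(topology, "pdb_structure")) stop("topology must be a pdb_structure")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L || nrow(f) != nrow(topology))
      stop("every frame must be an N x 3 matrix matching the topology atom count")
    if (any(!is.finite(f))) stop("frame coordinates must be finite")
    dimnames(f) <- NULL
    f
  })
  if (!length(frames)) stop("trajectory needs at least one frame")
  if (!is.null(frame_times) && length(frame_times) != length(frames))
    stop("frame_times length must match the number of frames")
  structure(list(topology = topology, frames = frames, frame_times = frame_times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology)))
  invisible(x)
}

#' Read a trajectory from multi-model PDB or XYZ text
#'
#' Format chosen from the file extension (`.pdb` or `.xyz`). XYZ files must
#' repeat the same atom count/ordering per frame; atom identities for XYZ
#' are taken as single elements with sequential residue numbers.
#'
#' @param path File path.
#' @param topology Optional `pdb_structure` supplying identities for XYZ
#'   input (element order must match).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    models <- read_pdb(path, multi = TRUE)
    frames <- lapply(models, coords)
    return(trajectory(models[[1L]], frames))
  }
  if (ext == "xyz") return(read_xyz(path, topology))
  stop("unsupported trajectory format: .", ext)
}

read_xyz <- function(path, topology = NULL) {
  raw <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); elems <- NULL
  while (i <= length(raw)) {
    if (!nzchar(trimws(raw[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(raw[i])))
    if (is.na(n)) stop(sprintf("parse error at line %d: expected atom count", i))
    block <- raw[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4L))
      stop(sprintf("parse error near line %d: malformed XYZ atom line", i + 2L))
    e <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop(sprintf("parse error near line %d: non-numeric coordinate", i + 2L))
    if (is.null(elems)) elems <- e
    else if (!identical(e, elems)) stop("inconsistent atom ordering across XYZ frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in ", path)
  if (is.null(topology)) {
    topology <- pdb_structure(data.frame(
      serial = seq_along(elems), name = elems, element = toupper(elems),
      residue_name = "UNK", residue_number = seq_along(elems), chain = "A",
      x = frames[[1L]][, 1L], y = frames[[1L]][, 2L], z = frames[[1L]][, 3L],
      is_ligand = FALSE, stringsAsFactors = FALSE))
  }
  trajectory(topology, frames)
}

#' Write a trajectory as XYZ text
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- traj$topology$element
  for (m in seq_along(traj$frames)) {
    writeLines(c(as.character(length(el)), sprintf("frame %d", m)), con)
    f <- traj$frames[[m]]
    writeLines(sprintf("%s %.6f %.6f %.6f", el, f[, 1L], f[, 2L], f[, 3L]), con)
  }
  invisible(path)
}

#' Select atom indices from a topology
#'
#' @param topology A `pdb_structure`.
#' @param selection `"ca"` (alpha carbons), `"backbone"` (N, CA, C, O of
#'   non-ligand residues), `"protein"` (all non-ligand atoms), `"ligand"`,
#'   `"heavy"` (non-hydrogen), `"all"`, or a numeric index vector (returned
#'   as-is).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(topology, selection = "all") {
  if (is.numeric(selection)) return(as.integer(selection))
  idx <- switch(selection,
    ca = which(!topology$is_ligand & topology$name == "CA"),
    backbone = which(!topology$is_ligand & topology$name %in% c("N", "CA", "C", "O")),
    protein = which(!topology$is_ligand),
    ligand = which(topology$is_ligand),
    heavy = which(topology$element != "H"),
    all = seq_len(nrow(topology)),
    stop("unknown selection: ", selection))
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  idx
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' selected atoms of a mobile coordinate set and a reference, via singular
#' value decomposition of the cross-covariance matrix with determinant sign
#' correction.
#'
#' @param reference N x 3 reference coordinates (Angstrom).
#' @param mobile N x 3 mobile coordinates.
#' @param selection Atom indices used for the fit (default all rows).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% rotation + translation`), and `rmsd` (Angstrom,
#'   over the selection after transforming).
#' @export
kabsch_superpose <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  r <- reference[selection, , drop = FALSE]
  m <- mobile[selection, , drop = FALSE]
  if (nrow(r) < 2L) stop("degenerate superposition: need at least 2 selected atoms")
  rc <- colMeans(r); mc <- colMeans(m)
  rcen <- sweep(r, 2L, rc); mcen <- sweep(m, 2L, mc)
  sv_shape <- svd(rcen)$d
  if (nrow(r) < 3L || sv_shape[2L] < 1e-8 * max(sv_shape[1L], 1)) {
    # collinear or two-point selections: rotation about the axis is
    # unconstrained; fall back to identity alignment of centered sets
    rot <- diag(3)
  } else {
    h <- t(mcen) %*% rcen
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  trans <- rc - mc %*% rot
  fitted <- mcen %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - rcen)^2)))
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param x N x 3 matrix.
#' @param transform Result of [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(x, transform) {
  sweep(as.matrix(x) %*% transform$rotation, 2L, -transform$translation)
}

superpose_frames <- function(frames, reference, selection) {
  lapply(frames, function(f) {
    tr <- kabsch_superpose(reference, f, selection)
    apply_transform(f, tr)
  })
}

#' Per-frame RMSD of a trajectory
#'
#' Each frame is Kabsch-superposed onto the reference over the selection;
#' the RMSD over that selection is reported in nm.
#'
#' @param traj An `md_trajectory`.
#' @param reference Frame index (default 1) or an N x 3 matrix.
#' @param selection Selection string or indices (see [select_atoms()]);
#'   default `"backbone"` when backbone atoms exist, else all atoms.
#' @return Numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  sel <- default_fit_selection(traj$topology, selection)
  ref <- if (is.matrix(reference)) reference else {
    if (reference < 1L || reference > length(traj$frames))
      stop("bad reference frame index: ", reference)
    traj$frames[[reference]]
  }
  vapply(traj$frames, function(f) kabsch_superpose(ref, f, sel)$rmsd, 0) / 10
}

default_fit_selection <- function(topology, selection) {
  if (!is.null(selection)) return(select_atoms(topology, selection))
  bb <- which(!topology$is_ligand & topology$name %in% c("N", "CA", "C", "O"))
  if (length(bb) >= 3L) bb else seq_len(nrow(topology))
}

#' Root-mean-square fluctuation per selected atom
#'
#' Frames are superposed to the time-averaged structure in two passes
#' (average after fitting to the first frame, then re-fit to that average —
#' the standard MD-analysis convention), after which
#' \eqn{RMSF_i = \sqrt{\langle |x_i(t) - \langle x_i \rangle|^2 \rangle_t}}.
#'
#' @param traj An `md_trajectory` with at least 2 frames.
#' @param selection Atoms reported (default `"ca"` when alpha carbons
#'   exist, else all); the superposition uses the same selection.
#' @return Data frame: `atom`, `chain`, `residue_number`, `rmsf` (nm).
#' @export
rmsf <- function(traj, selection = NULL) {
  if (length(traj$frames) < 2L) stop("RMSF needs at least 2 frames")
  top <- traj$topology
  sel <- if (is.null(selection)) {
    ca <- which(!top$is_ligand & top$name == "CA")
    if (length(ca) >= 1L) ca else seq_len(nrow(top))
  } else select_atoms(top, selection)
  fit_sel <- if (length(sel) >= 3L) sel else seq_len(nrow(top))
  pass1 <- superpose_frames(traj$frames, traj$frames[[1L]], fit_sel)
  avg <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- superpose_frames(traj$frames, avg, fit_sel)
  avg2 <- Reduce(`+`, pass2) / length(pass2)
  dev2 <- Reduce(`+`, lapply(pass2, function(f) rowSums((f - avg2)^2))) / length(pass2)
  data.frame(atom = sel, chain = top$chain[sel],
             residue_number = top$residue_number[sel],
             rmsf = sqrt(dev2[sel]) / 10)
}

#' Radius of gyration of one frame
#'
#' Mass-weighted RMS distance of atoms from the center of mass:
#' \eqn{R_g = \sqrt{\sum_i m_i |x_i - x_{com}|^2 / \sum_i m_i}}.
#'
#' @param frame N x 3 coordinate matrix (Angstrom).
#' @param masses Atomic masses (u), all > 0.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, masses) {
  frame <- as.matrix(frame)
  if (length(masses) != nrow(frame)) stop("one mass per atom required")
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(frame * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(frame, 2L, com)^2)) / sum(masses)) / 10
}

sphere_points <- function(n) {
  # deterministic golden-spiral point set on the unit sphere
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

cell_list_neighbors <- function(xyz, reach) {
  # indices of atom pairs closer than `reach` via a uniform grid
  n <- nrow(xyz)
  cell <- max(reach, 1e-6)
  key <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cell)
  id <- key[, 1L] + 4096 * key[, 2L] + 4096^2 * key[, 3L]
  buckets <- split(seq_len(n), id)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (b in names(buckets)) assign(b, buckets[[b]], envir = lookup)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ids <- (key[i, 1L] + offsets[, 1L]) + 4096 * (key[i, 2L] + offsets[, 2L]) +
      4096^2 * (key[i, 3L] + offsets[, 3L])
    cand <- unlist(lapply(as.character(ids), function(k)
      if (exists(k, envir = lookup, inherits = FALSE)) get(k, envir = lookup) else NULL),
      use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2L, xyz[i, ])^2)
      cand <- cand[d2 < reach^2]
    }
    nb[[i]] <- cand
  }
  nb
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places a deterministic golden-spiral set of `n_sphere_points` test
#' points on each atom's probe-inflated sphere of radius \eqn{r_i + probe};
#' a point is accessible when it lies outside every neighbouring atom's
#' inflated sphere. The atom's area is the accessible fraction times
#' \eqn{4\pi (r_i + probe)^2}. Neighbour search uses cell lists.
#'
#' @param frame N x 3 coordinate matrix (Angstrom).
#' @param elements Character vector of element symbols, one per atom.
#' @param radii An [atom_radii()] object.
#' @param n_sphere_points Test points per atom (default 960).
#' @return List with `total` and `per_atom` SASA in nm^2.
#' @export
sasa <- function(frame, elements, radii = atom_radii(), n_sphere_points = 960) {
  frame <- as.matrix(frame)
  el <- toupper(elements)
  missing <- setdiff(unique(el), names(radii$radii))
  if (length(missing))
    stop("no van der Waals radius for element(s): ", paste(missing, collapse = ", "))
  r <- unname(radii$radii[el]) + radii$probe_radius
  pts <- sphere_points(n_sphere_points)
  nb <- cell_list_neighbors(frame, 2 * max(r))
  per_atom <- numeric(nrow(frame))
  for (i in seq_len(nrow(frame))) {
    p <- sweep(pts * r[i], 2L, frame[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb[[i]]) {
      if (!any(acc)) break
      d2 <- rowSums(sweep(p[acc, , drop = FALSE], 2L, frame[j, ])^2)
      acc[acc] <- d2 > r[j]^2
    }
    per_atom[i] <- mean(acc) * 4 * pi * r[i]^2
  }
  list(total = sum(per_atom) / 100, per_atom = per_atom / 100)
}

#' Per-frame intermolecular hydrogen-bond counts
#'
#' Applies the [find_hbonds()] geometric criteria (default 3.5 Angstrom /
#' 30 degrees) between two disjoint atom groups in every frame.
#'
#' @param traj An `md_trajectory`.
#' @param group_a,group_b Selection strings or index vectors (see
#'   [select_atoms()]); must be disjoint and non-empty. Group B plays the
#'   ligand role.
#' @param d_cutoff,angle_cutoff Criterion parameters.
#' @return Integer vector of counts, one per frame.
#' @export
count_hbonds_series <- function(traj, group_a = "protein", group_b = "ligand",
                                d_cutoff = 3.5, angle_cutoff = 30) {
  top <- traj$topology
  a <- select_atoms(top, group_a)
  b <- select_atoms(top, group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  res_key <- paste(top$chain, top$residue_number)
  b_res <- unique(res_key[b]); a_res <- unique(res_key[a])
  keep <- sort(unique(c(a, b, which(top$element == "H" & res_key %in% c(a_res, b_res)))))
  vapply(traj$frames, function(f) {
    atoms <- top
    atoms$x <- f[, 1L]; atoms$y <- f[, 2L]; atoms$z <- f[, 3L]
    atoms$is_ligand <- res_key %in% b_res
    sub <- pdb_structure(as.data.frame(atoms)[keep, , drop = FALSE])
    nrow(find_hbonds(sub, d_cutoff, angle_cutoff))
  }, 0L)
}

#' Essential-dynamics covariance analysis
#'
#' Superposes frames to the time-averaged structure over the selection,
#' builds the 3N x 3N covariance matrix of the selected coordinates (nm^2)
#' and returns its trace, sorted eigenvalues and the per-frame projections
#' on the two leading eigenvectors.
#'
#' @param traj An `md_trajectory` with at least 2 frames.
#' @param selection Selection string or indices; default `"ca"` when alpha
#'   carbons exist, else all atoms. Needs at least 2 atoms.
#' @return List with `trace` (nm^2), `eigenvalues` (nm^2, decreasing),
#'   `projections` (frames x 2, nm).
#' @export
covariance_analysis <- function(traj, selection = NULL) {
  if (length(traj$frames) < 2L) stop("covariance analysis needs at least 2 frames")
  top <- traj$topology
  sel <- if (is.null(selection)) {
    ca <- which(!top$is_ligand & top$name == "CA")
    if (length(ca) >= 2L) ca else seq_len(nrow(top))
  } else select_atoms(top, selection)
  if (length(sel) < 2L) stop("selection must cover at least 2 atoms")
  fit_sel <- if (length(sel) >= 3L) sel else seq_len(nrow(top))
  pass1 <- superpose_frames(traj$frames, traj$frames[[1L]], fit_sel)
  avg <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- superpose_frames(traj$frames, avg, fit_sel)
  x <- t(vapply(pass2, function(f) as.numeric(t(f[sel, , drop = FALSE])),
                numeric(3L * length(sel)))) / 10   # frames x 3N, nm
  cv <- stats::cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  centered <- sweep(x, 2L, colMeans(x))
  list(trace = sum(diag(cv)),
       eigenvalues = eig$values,
       projections = centered %*% eig$vectors[, 1:2, drop = FALSE])
}

#' Time-averaged trajectory summary
#'
#' Computes the standard stability/flexibility observables and averages
#' them over frames (RMSF over selected atoms): mean RMSD to the first
#' frame, mean RMSF, mean radius of gyration, mean Shrake-Rupley SASA,
#' covariance-matrix trace, and (when a ligand is present) per-frame
#' intermolecular hydrogen-bond counts.
#'
#' @param traj An `md_trajectory`.
#' @param radii An [atom_radii()] object for SASA.
#' @param n_sphere_points SASA test points per atom.
#' @param rmsd_selection,rmsf_selection Overrides for the default
#'   selections (backbone / alpha carbon).
#' @param sasa_stride Compute SASA every `sasa_stride`-th frame (>= 1).
#' @return Object of class `trajectory_summary` with fields `mean_rmsd`,
#'   `mean_rmsf`, `mean_rg` (nm), `mean_sasa`, `covariance_trace` (nm^2),
#'   `hbond_counts` (or NULL), `per_residue_rmsf`, and per-frame series
#'   `rmsd_series`, `rg_series`, `sasa_series`.
#' @export
summarize_trajectory <- function(traj, radii = atom_radii(),
                                 n_sphere_points = 960,
                                 rmsd_selection = NULL, rmsf_selection = NULL,
                                 sasa_stride = 1L) {
  top <- traj$topology
  prot <- which(!top$is_ligand)
  if (!length(prot)) prot <- seq_len(nrow(top))
  rmsd_s <- rmsd_series(traj, 1L, rmsd_selection)
  fl <- if (length(traj$frames) >= 2L) rmsf(traj, rmsf_selection) else NULL
  masses <- element_masses(top$element[prot])
  rg_s <- vapply(traj$frames, function(f)
    radius_of_gyration(f[prot, , drop = FALSE], masses), 0)
  sasa_idx <- seq(1L, length(traj$frames), by = max(1L, sasa_stride))
  sasa_s <- vapply(traj$frames[sasa_idx], function(f)
    sasa(f[prot, , drop = FALSE], top$element[prot], radii, n_sphere_points)$total, 0)
  cov_tr <- if (length(traj$frames) >= 2L) covariance_analysis(traj)$trace else 0
  hb <- if (any(top$is_ligand) && any(!top$is_ligand))
    count_hbonds_series(traj, "protein", "ligand") else NULL
  per_res <- if (!is.null(fl))
    stats::aggregate(rmsf ~ chain + residue_number, fl, mean) else NULL
  structure(list(
    mean_rmsd = mean(rmsd_s),
    mean_rmsf = if (is.null(fl)) 0 else mean(fl$rmsf),
    mean_rg = mean(rg_s),
    mean_sasa = mean(sasa_s),
    covariance_trace = cov_tr,
    hbond_counts = hb,
    per_residue_rmsf = per_res,
    rmsd_series = rmsd_s, rg_series = rg_s, sasa_series = sasa_s,
    sasa_frames = sasa_idx), class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf(paste0("trajectory_summary: RMSD %.4f nm, RMSF %.4f nm, ",
                     "Rg %.4f nm, SASA %.3f nm^2, cov trace %.4f nm^2\n"),
              x$mean_rmsd, x$mean_rmsf, x$mean_rg, x$mean_sasa,
              x$covariance_trace))
  if (!is.null(x$hbond_counts))
    cat("  mean intermolecular H-bonds/frame:", mean(x$hbond_counts), "\n")
  invisible(x)
}
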