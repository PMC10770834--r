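#' Design for a synthetic fluorescence titration
#'
#' Defaults emulate the lysozyme-digitoxin study design: ligand
#' concentrations 0-50 uM in 5 uM steps at 25/35/45 C, a tryptophan-like
#' emission band centred at 340 nm, and enhancement thermodynamics
#' (delta H = 5600 J/mol, delta S = 104.8 J/(mol K)) that place Kb near
#' 3.1e4 M^-1 at 25 C. Noise is multiplicative Gaussian (fluorescence noise
#' scales with signal), CV 1% by default; the default enhancement amplitude
#' (saturation change 1.2x the ligand-free intensity) is calibrated so that
#' double-reciprocal fits of the generated data reproduce the fit quality
#' reported for the real titrations (R^2 near 0.995).
#'
#' @param delta_h Binding enthalpy, J/mol.
#' @param delta_s Binding entropy, J/(mol K).
#' @param temperatures Temperatures, K.
#' @param concentrations Ligand concentrations, mol/L; must include 0.
#' @param delta_f_max Saturation fluorescence change, a.u.
#' @param baseline_f0 Ligand-free peak intensity, a.u.
#' @param band_center Emission band centre, nm.
#' @param band_width Gaussian band standard deviation, nm.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer RNG seed.
#' @return Object of class `titration_design`.
#' @export
titration_design <- function(delta_h = 5600, delta_s = 104.8,
                             temperatures = c(298.15, 308.15, 318.15),
                             concentrations = seq(0, 50e-6, by = 5e-6),
                             delta_f_max = 1200, baseline_f0 = 1000,
                             band_center = 340, band_width = 25,
                             noise_cv = 0.01, seed = 1L) {
  if (!any(concentrations == 0)) stop("concentrations must include 0 (the reference)")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (band_width <= 0 || band_center <= 0) stop("band parameters must be positive")
  if (delta_f_max <= 0 || baseline_f0 <= 0) stop("intensity parameters must be positive")
  structure(list(delta_h = delta_h, delta_s = delta_s,
                 temperatures = temperatures,
                 concentrations = sort(unique(concentrations)),
                 delta_f_max = delta_f_max, baseline_f0 = baseline_f0,
                 band_center = band_center, band_width = band_width,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "titration_design")
}

#' Binding constant implied by Van 't Hoff parameters
#' @param delta_h Enthalpy, J/mol.
#' @param delta_s Entropy, J/(mol K).
#' @param temperature Temperature, K.
#' @return Kb in M^-1: `exp(-delta_h/(R T) + delta_s/R)`.
#' @export
kb_from_thermo <- function(delta_h, delta_s, temperature) {
  exp(-delta_h / (GAS_CONSTANT * temperature) + delta_s / GAS_CONSTANT)
}

#' Generate synthetic titration series with known ground truth
#'
#' Per temperature, the 1:1 free-ligand binding model gives
#' \eqn{\Delta F(c) = \Delta F_{max} K_b c / (1 + K_b c)} with
#' \eqn{K_b(T)} from the design's enthalpy/entropy; each spectrum is the
#' peak intensity \eqn{F_0 + \Delta F(c)} times a Gaussian band over a
#' 300-500 nm grid, with multiplicative Gaussian noise. Fully reproducible
#' from the design seed. An optional mass-balance variant depletes free
#' ligand against a stated protein concentration (for sensitivity studies
#' only; the free-ligand model matches the analysis assumptions).
#'
#' @param design A [titration_design()].
#' @param mass_balance If `TRUE`, compute bound fraction from the 1:1
#'   mass-balance quadratic with `protein_concentration`.
#' @param protein_concentration Total protein, mol/L (mass-balance only).
#' @return List with `series` (one [titration_series()] per temperature,
#'   named by K) and `kb_true` (named numeric, the ground-truth Kb(T)).
#' @export
generate_titration <- function(design, mass_balance = FALSE,
                               protein_concentration = 2e-6) {
  stopifnot(inherits(design, "titration_design"))
  grid <- 300:500
  band <- exp(-(grid - design$band_center)^2 / (2 * design$band_width^2))
  withr::with_seed(design$seed, {
    out <- list(); kb_true <- numeric(0)
    for (temp in design$temperatures) {
      kb <- kb_from_thermo(design$delta_h, design$delta_s, temp)
      spectra <- lapply(design$concentrations, function(conc) {
        free <- if (mass_balance) {
          # free ligand from [PL] = smaller root of the 1:1 quadratic
          pt <- protein_concentration
          b <- pt + conc + 1 / kb
          conc - (b - sqrt(b^2 - 4 * pt * conc)) / 2
        } else conc
        df <- design$delta_f_max * kb * free / (1 + kb * free)
        peak <- design$baseline_f0 + df
        intens <- peak * band
        if (design$noise_cv > 0)
          intens <- pmax(intens * (1 + stats::rnorm(length(intens), 0, design$noise_cv)), 0)
        emission_spectrum(grid, intens, 295, temp, conc)
      })
      key <- format(temp, trim = TRUE)
      out[[key]] <- titration_series(spectra)
      kb_true[key] <- kb
    }
    list(series = out, kb_true = kb_true)
  })
}

#' Design for a synthetic fluctuation trajectory
#'
#' @param base_structure A `pdb_structure`; its coordinates are the mean
#'   positions.
#' @param per_residue_amplitude Named numeric vector mapping residue number
#'   to the per-axis Gaussian displacement standard deviation (Angstrom);
#'   residues not named get 0.
#' @param rigid_jitter Length-2 numeric: maximum rigid-body rotation
#'   (degrees) and translation (Angstrom) applied to every frame.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer RNG seed.
#' @return Object of class `fluctuation_design`.
#' @export
fluctuation_design <- function(base_structure, per_residue_amplitude = numeric(0),
                               rigid_jitter = c(0, 0), n_frames = 100L, seed = 1L) {
  stopifnot(inherits(base_structure, "pdb_structure"))
  if (any(per_residue_amplitude < 0)) stop("amplitudes must be non-negative")
  if (n_frames < 2L) stop("n_frames must be at least 2")
  structure(list(base_structure = base_structure,
                 per_residue_amplitude = per_residue_amplitude,
                 rigid_jitter = rigid_jitter, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)), class = "fluctuation_design")
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_deg) * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

#' Generate a synthetic trajectory with planted fluctuations
#'
#' Each frame displaces every atom by an independent Gaussian with its
#' residue's per-axis amplitude, then applies a random rigid-body jitter to
#' the whole frame. The planted per-axis amplitude `a` implies an expected
#' recovered RMSF of `sqrt(3) * a / 10` nm (isotropic three-axis variance),
#' which serves as the closed-form oracle for estimator tests.
#'
#' @param design A [fluctuation_design()].
#' @return List with `trajectory` (an `md_trajectory`) and
#'   `amplitude_true` (per-residue per-axis sd, Angstrom, for every residue
#'   in the topology).
#' @export
generate_trajectory <- function(design) {
  stopifnot(inherits(design, "fluctuation_design"))
  top <- design$base_structure
  base <- coords(top)
  amp_map <- design$per_residue_amplitude
  amp <- amp_map[as.character(top$residue_number)]
  amp[is.na(amp)] <- 0
  amp <- unname(amp)
  withr::with_seed(design$seed, {
    frames <- lapply(seq_len(design$n_frames), function(i) {
      f <- base + matrix(stats::rnorm(length(base), 0, 1), ncol = 3) * amp
      if (any(design$rigid_jitter > 0)) {
        rot <- random_rotation(design$rigid_jitter[1L])
        cen <- colMeans(f)
        f <- sweep(sweep(f, 2L, cen) %*% rot, 2L, -cen) +
          matrix(stats::runif(3, -design$rigid_jitter[2L], design$rigid_jitter[2L]),
                 nrow(f), 3, byrow = TRUE)
      }
      f
    })
    res <- unique(top$residue_number)
    truth <- amp_map[as.character(res)]
    truth[is.na(truth)] <- 0
    names(truth) <- res
    list(trajectory = trajectory(top, frames), amplitude_true = truth)
  })
}

#' Generate a protein-ligand complex with planted contacts
#'
#' Builds a deliberately minimal synthetic scaffold: single-interaction-atom
#' pseudo-residues spaced 10 Angstrom apart along the x axis (GLY-type
#' nitrogen donors/acceptors for hydrogen bonds, ALA-type carbons for
#' hydrophobic contacts) plus three distant anchor atoms, with one ligand
#' atom planted above each interaction residue: O at 2.8-3.2 Angstrom for
#' hydrogen bonds, C at 3.5-3.9 Angstrom for hydrophobic contacts. Every
#' other protein-ligand distance exceeds 4.5 Angstrom, so the ground-truth
#' contact counts are exact. A distant dummy ligand carbon keeps the ligand
#' set non-empty for zero-contact designs.
#'
#' @param n_hbonds Number of planted hydrogen bonds (>= 0).
#' @param n_hydrophobic Number of planted hydrophobic contacts (>= 0).
#' @param seed Integer RNG seed (plant distances are drawn within their
#'   windows).
#' @return List with `structure` (a `pdb_structure`) and `truth` (data
#'   frame `residue_number`, `n_hbond`, `n_hydrophobic`).
#' @export
generate_complex <- function(n_hbonds, n_hydrophobic, seed = 1L) {
  if (n_hbonds < 0 || n_hydrophobic < 0) stop("contact counts must be non-negative")
  n_int <- n_hbonds + n_hydrophobic
  withr::with_seed(as.integer(seed), {
    xs <- 10 * seq_len(max(n_int, 1L))
    rows <- list(); serial <- 0L
    add <- function(name, element, resn, resno, x, y, z, lig) {
      serial <<- serial + 1L
      rows[[serial]] <<- data.frame(serial = serial, name = name, element = element,
                                    residue_name = resn, residue_number = resno,
                                    chain = "A", x = x, y = y, z = z,
                                    is_ligand = lig, stringsAsFactors = FALSE)
    }
    resno <- 0L
    lig_atoms <- list()
    if (n_hbonds > 0) for (i in seq_len(n_hbonds)) {
      resno <- resno + 1L
      add("N", "N", "GLY", resno, xs[resno], 0, 0, FALSE)
      lig_atoms[[length(lig_atoms) + 1L]] <-
        list(name = "O1", element = "O", x = xs[resno],
             z = stats::runif(1, 2.8, 3.2), resno = resno, kind = "hb")
    }
    if (n_hydrophobic > 0) for (i in seq_len(n_hydrophobic)) {
      resno <- resno + 1L
      add("CB", "C", "ALA", resno, xs[resno], 0, 0, FALSE)
      lig_atoms[[length(lig_atoms) + 1L]] <-
        list(name = "C1", element = "C", x = xs[resno],
             z = stats::runif(1, 3.5, 3.9), resno = resno, kind = "hp")
    }
    # distant anchors so rigid-body operations are well conditioned
    anchor_x <- max(xs) + 20
    add("CA", "C", "GLY", resno + 1L, anchor_x, 50, 0, FALSE)
    add("CA", "C", "GLY", resno + 2L, anchor_x + 10, 50, 5, FALSE)
    add("CA", "C", "GLY", resno + 3L, anchor_x + 5, 55, -5, FALSE)
    for (k in seq_along(lig_atoms)) {
      la <- lig_atoms[[k]]
      add(la$name, la$element, "LIG", 900L, la$x, 0, la$z, TRUE)
    }
    add("CD", "C", "LIG", 900L, 0, -50, 0, TRUE)   # dummy keeps ligand non-empty
    st <- pdb_structure(do.call(rbind, rows))
    truth <- data.frame(
      residue_number = seq_len(n_int),
      n_hbond = rep(c(1L, 0L), c(n_hbonds, n_hydrophobic)),
      n_hydrophobic = rep(c(0L, 1L), c(n_hbonds, n_hydrophobic)))
    truth <- truth[truth$n_hbond + truth$n_hydrophobic > 0, , drop = FALSE]
    list(structure = st, truth = truth)
  })
}

#' A small helical toy protein for tests and examples
#'
#' Alpha-carbon-only helix with `n_res` residues on an ideal helix
#' (rise 1.5 Angstrom, ~100 degrees per residue, radius 2.3 Angstrom) —
#' compact enough that atomic spheres overlap, as in a folded protein.
#'
#' @param n_res Number of residues.
#' @return A `pdb_structure` of CA atoms.
#' @export
toy_helix <- function(n_res = 20L) {
  i <- seq_len(n_res)
  ang <- (i - 1) * 100 * pi / 180
  pdb_structure(data.frame(
    serial = i, name = "CA", element = "C", residue_name = "ALA",
    residue_number = i, chain = "A",
    x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i,
    is_ligand = FALSE, stringsAsFactors = FALSE))
}
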