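# Fixtures and independent oracles used across the suite.

# Flat-band spectrum whose intensity at every wavelength equals `value`.
flat_spectrum <- function(value, conc, temp = 298.15, grid = 300:500) {
  emission_spectrum(grid, rep(value, length(grid)), 295, temp, conc)
}

# Titration series with peak intensities f0 + dFmax*Kb*c/(1+Kb*c).
hyperbolic_series <- function(kb, dfmax = 200, f0 = 500,
                              concs = c(0, 5e-6, 1e-5, 2e-5, 4e-5),
                              temp = 298.15) {
  titration_series(lapply(concs, function(conc) {
    df <- dfmax * kb * conc / (1 + kb * conc)
    flat_spectrum(f0 + df, conc, temp)
  }))
}

# Minimal atom-table builder.
atoms_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$serial <- seq_len(nrow(df))
  pdb_structure(df)
}

atom <- function(name, element, resn, resno, x, y, z, lig = FALSE, chain = "A") {
  list(serial = 1L, name = name, element = element, residue_name = resn,
       residue_number = resno, chain = chain, x = x, y = y, z = z, is_ligand = lig)
}

# Random rigid transform applied to a coordinate matrix.
rigid_move <- function(xyz, angle_deg, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  r <- diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
  sweep(as.matrix(xyz) %*% r, 2L, -shift)
}

rigid_move_structure <- function(st, angle_deg, axis, shift) {
  xyz <- rigid_move(coords(st), angle_deg, axis, shift)
  st$x <- xyz[, 1L]; st$y <- xyz[, 2L]; st$z <- xyz[, 3L]
  st
}

# Brute-force rotation-grid RMSD oracle (independent of the Kabsch path):
# golden-spiral axis grid x 2-degree angle grid over centered coordinates.
brute_force_rmsd <- function(reference, mobile, n_axes = 400, angle_step = 2) {
  r <- sweep(as.matrix(reference), 2L, colMeans(reference))
  m <- sweep(as.matrix(mobile), 2L, colMeans(mobile))
  i <- seq_len(n_axes) - 0.5
  z <- 1 - 2 * i / n_axes
  phi <- pi * (3 - sqrt(5)) * (seq_len(n_axes) - 1)
  rho <- sqrt(pmax(1 - z^2, 0))
  axes <- cbind(rho * cos(phi), rho * sin(phi), z)
  angles <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  s <- sin(angles); cc <- 1 - cos(angles)
  best <- Inf
  d0 <- m - r
  for (j in seq_len(n_axes)) {
    ax <- axes[j, ]
    k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    a1 <- m %*% k          # sin term
    a2 <- m %*% (k %*% k)  # (1-cos) term
    for (t in seq_along(angles)) {
      diff <- d0 + s[t] * a1 + cc[t] * a2
      v <- mean(rowSums(diff^2))
      if (v < best) best <- v
    }
  }
  sqrt(best)
}

# Exposed area of two equal overlapping spheres (spherical-cap closed form):
# per sphere 2*pi*R*(R + d/2), in Angstrom^2.
two_sphere_area <- function(R, d) 4 * pi * R * (R + d / 2)
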