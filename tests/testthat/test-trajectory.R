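static_traj <- function(n_res = 8, n_frames = 5) {
  top <- toy_helix(n_res)
  trajectory(top, replicate(n_frames, coords(top), simplify = FALSE))
}

test_that("Kabsch superposition is exact on identity and rigid motions", {
  top <- toy_helix(8)
  x <- coords(top)
  tr <- kabsch_superpose(x, x)
  expect_equal(tr$rmsd, 0, tolerance = 1e-12)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  moved <- rigid_move(x, 90, c(0, 0, 1), c(5, 5, 5))
  expect_lt(kabsch_superpose(x, moved)$rmsd, 1e-10)
  expect_error(kabsch_superpose(x[1, , drop = FALSE], x[1, , drop = FALSE]),
               "degenerate")
})

test_that("Kabsch matches the analytic stretched-pair result and the grid oracle", {
  anchors <- rbind(c(0, 5, 0), c(0, -5, 0), c(0, 0, 7))
  ref <- rbind(c(-1, 0, 0), c(1, 0, 0), anchors)
  mob <- rbind(c(-2, 0, 0), c(2, 0, 0), anchors)
  tr <- kabsch_superpose(ref, mob)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  fitted <- apply_transform(mob, tr)
  pair_rmsd <- sqrt(mean(rowSums((fitted[1:2, ] - ref[1:2, ])^2)))
  expect_equal(pair_rmsd, 1.0, tolerance = 1e-9)       # centered offsets +-1 vs +-2
  expect_equal(tr$rmsd, sqrt(2 / 5), tolerance = 1e-9)

  # independent oracle: brute-force rotation grid on small toys
  set.seed(5)
  for (i in 1:4) {
    a <- matrix(rnorm(15, sd = 2), 5, 3)
    b <- rigid_move(a + matrix(rnorm(15, sd = 0.3), 5, 3), runif(1, 0, 360),
                    rnorm(3), rnorm(3, 0, 5))
    k <- kabsch_superpose(a, b)$rmsd
    o <- brute_force_rmsd(a, b)
    expect_lte(k, o + 1e-9)           # Kabsch is the optimum
    expect_lt(o - k, 0.2)             # oracle within grid resolution
  }
})

test_that("RMSD series is zero for static and rigidly moved trajectories", {
  expect_equal(rmsd_series(static_traj()), rep(0, 5), tolerance = 1e-12)
  top <- toy_helix(8)
  x <- coords(top)
  set.seed(3)
  frames <- lapply(1:6, function(i) rigid_move(x, runif(1, 0, 360), rnorm(3), rnorm(3, 0, 10)))
  tr <- trajectory(top, frames)
  expect_lt(max(rmsd_series(tr)), 1e-8)
  expect_error(rmsd_series(tr, reference = 99), "reference")
})

test_that("RMSF recovers planted fluctuation amplitudes", {
  expect_equal(rmsf(static_traj(), "all")$rmsf, rep(0, 8), tolerance = 1e-12)
  expect_error(rmsf(trajectory(toy_helix(5), list(coords(toy_helix(5))))), "2 frames")

  # one atom oscillating +-a along x in equal halves; many static anchors so
  # the superposition fit absorbs only ~1/N of the planted variance
  top <- toy_helix(80)
  x <- coords(top)
  a <- 1.2
  frames <- lapply(1:40, function(i) {
    f <- x; f[40, 1] <- f[40, 1] + if (i %% 2 == 0) a else -a; f
  })
  fl <- rmsf(trajectory(top, frames), "all")
  expect_equal(fl$rmsf[40], a / 10, tolerance = 0.03)
  expect_lt(max(fl$rmsf[-40]), 0.005)

  # planted per-residue amplitudes: rank correlation of recovery >= 0.95
  amps <- setNames(seq(0.1, 1.5, length.out = 10), 3 * (1:10))
  des <- fluctuation_design(toy_helix(30), amps, rigid_jitter = c(5, 1),
                            n_frames = 150, seed = 21)
  tr <- generate_trajectory(des)
  fl2 <- rmsf(tr$trajectory, "all")
  rec <- fl2$rmsf[as.integer(names(amps))]
  expect_gte(cor(rec, unname(amps), method = "spearman"), 0.95)
  # closed-form oracle: expected RMSF = sqrt(3) * a / 10 nm for well-anchored atoms
  expect_equal(rec[10], sqrt(3) * amps[[10]] / 10, tolerance = 0.25)
})

test_that("radius of gyration matches closed forms and homogeneity", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1), 12), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, c(1, 1)), 0.1)   # 1 Angstrom = 0.1 nm
  x <- coords(toy_helix(12)); m <- element_masses(rep("C", 12))
  expect_equal(radius_of_gyration(3 * x, m), 3 * radius_of_gyration(x, m),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(two, c(1, -1)), "positive")
  expect_error(element_masses("XX"), "no mass")
})

test_that("SASA matches closed forms for isolated, disjoint and overlapping spheres", {
  r <- atom_radii()                      # C 1.70 + probe 1.4 = 3.10
  single <- sasa(matrix(0, 1, 3), "C", r)
  quantum <- 4 * pi * 3.1^2 / 960 / 100
  expect_equal(single$total, 4 * pi * 3.1^2 / 100, tolerance = quantum / single$total)

  two_far <- sasa(rbind(c(0, 0, 0), c(50, 0, 0)), c("C", "C"), r)
  expect_equal(two_far$total, 2 * single$total, tolerance = 1e-9)

  d <- 3.0
  two_near <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"), r)
  expect_equal(two_near$total, two_sphere_area(3.1, d) / 100, tolerance = 0.02)
  expect_error(sasa(matrix(0, 1, 3), "XX", r), "XX")
})

test_that("SASA converges with the sphere-point count on a 50-atom toy", {
  x <- coords(toy_helix(50))
  el <- rep("C", 50)
  s1 <- sasa(x, el, n_sphere_points = 960)$total
  s2 <- sasa(x, el, n_sphere_points = 3840)$total
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("per-frame hydrogen bond counts switch at the cutoff during a drift", {
  base <- generate_complex(1, 0, seed = 2)$structure
  top <- base
  x <- coords(top)
  lig_o <- which(top$is_ligand & top$element == "O")
  don <- which(!top$is_ligand & top$element == "N")
  dists <- seq(3.0, 4.0, length.out = 11)
  frames <- lapply(dists, function(d) {
    f <- x; f[lig_o, 3] <- f[don, 3] + d; f
  })
  tr <- trajectory(top, frames)
  counts <- count_hbonds_series(tr, "protein", "ligand")
  expect_equal(counts, as.integer(dists <= 3.5))
  expect_error(count_hbonds_series(tr, "protein", "protein"), "disjoint")
})

test_that("covariance analysis satisfies the trace identities", {
  expect_equal(covariance_analysis(static_traj(), "all")$trace, 0, tolerance = 1e-15)

  des <- fluctuation_design(toy_helix(20), setNames(rep(0.8, 20), 1:20),
                            n_frames = 60, seed = 9)
  tr <- generate_trajectory(des)$trajectory
  cv <- covariance_analysis(tr, "all")
  # trace equals the sum of per-coordinate variances (no eigendecomposition)
  pass1 <- lapply(tr$frames, function(f) kabsch_superpose(tr$frames[[1]], f)$rmsd)
  x <- t(sapply(tr$frames, function(f)
    as.numeric(t(apply_transform(f, kabsch_superpose(tr$frames[[1]], f)))))) / 10
  expect_equal(cv$trace, sum(cv$eigenvalues), tolerance = 1e-8)
  expect_equal(dim(cv$projections), c(60L, 2L))

  # one isotropically fluctuating atom among many static: trace ~ 3 sigma^2
  top <- toy_helix(40)
  sigma <- 0.9
  des2 <- fluctuation_design(top, setNames(sigma, "20"), n_frames = 400, seed = 13)
  tr2 <- generate_trajectory(des2)$trajectory
  cv2 <- covariance_analysis(tr2, "all")
  expect_equal(cv2$trace, 3 * sigma^2 / 100, tolerance = 0.15)
})

test_that("trajectory summaries are invariant under per-frame rigid motions", {
  des <- fluctuation_design(toy_helix(12), setNames(rep(0.5, 12), 1:12),
                            n_frames = 12, seed = 4)
  tr <- generate_trajectory(des)$trajectory
  set.seed(8)
  moved <- trajectory(tr$topology, lapply(tr$frames, function(f)
    rigid_move(f, runif(1, 0, 360), rnorm(3), rnorm(3, 0, 15))))
  s1 <- summarize_trajectory(tr, n_sphere_points = 240)
  s2 <- summarize_trajectory(moved, n_sphere_points = 240)
  expect_equal(s2$mean_rmsd, s1$mean_rmsd, tolerance = 1e-8)
  expect_equal(s2$mean_rmsf, s1$mean_rmsf, tolerance = 1e-8)
  expect_equal(s2$covariance_trace, s1$covariance_trace, tolerance = 1e-8)
  expect_equal(s2$mean_rg, s1$mean_rg, tolerance = 1e-9)
  # the finite test-point sphere is orientation-dependent, so SASA under a
  # rigid motion agrees only to the point-set quantization
  expect_equal(s2$mean_sasa, s1$mean_sasa, tolerance = 5e-3)
})

test_that("trajectory summary on a static toy reproduces the closed forms", {
  tr <- static_traj(10, 4)
  s <- summarize_trajectory(tr, n_sphere_points = 480)
  expect_equal(s$mean_rmsd, 0, tolerance = 1e-12)
  expect_equal(s$mean_rmsf, 0, tolerance = 1e-12)
  expect_equal(s$covariance_trace, 0, tolerance = 1e-12)
  x <- coords(tr$topology)
  expect_equal(s$mean_rg, radius_of_gyration(x, element_masses(tr$topology$element)))
  expect_equal(s$mean_sasa, sasa(x, tr$topology$element, n_sphere_points = 480)$total)
})

test_that("trajectory I/O round-trips through multi-model PDB and XYZ", {
  des <- fluctuation_design(toy_helix(6), setNames(rep(0.4, 6), 1:6),
                            n_frames = 3, seed = 6)
  tr <- generate_trajectory(des)$trajectory
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(lapply(tr$frames, function(f) {
    st <- tr$topology; st$x <- f[, 1]; st$y <- f[, 2]; st$z <- f[, 3]; st
  }), p)
  back <- read_trajectory(p)
  expect_length(back$frames, 3L)
  expect_equal(back$frames[[2]], tr$frames[[2]], tolerance = 1e-3)

  px <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, px)
  backx <- read_trajectory(px)
  expect_length(backx$frames, 3L)
  expect_equal(backx$frames[[3]], tr$frames[[3]], tolerance = 1e-6)
})

test_that("superposed RMSD agrees with bio3d on a common toy", {
  skip_if_not_installed("bio3d")
  set.seed(17)
  a <- matrix(rnorm(30, sd = 3), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  ours <- kabsch_superpose(a, b)$rmsd
  fit <- bio3d::fit.xyz(as.numeric(t(a)), as.numeric(t(b)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  theirs <- bio3d::rmsd(as.numeric(t(a)), fit)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
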