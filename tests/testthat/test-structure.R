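make_hb_pair <- function(d, with_h = FALSE, h_angle = 0) {
  # protein N at origin, ligand O at distance d along z; optional explicit
  # hydrogen on the donor at angle h_angle from the D-A axis
  rows <- list(
    atom("N", "N", "GLY", 1, 0, 0, 0),
    atom("CA", "C", "GLY", 2, 20, 0, 0),
    atom("CA", "C", "GLY", 3, 25, 5, 0),
    atom("CA", "C", "GLY", 4, 20, 5, 5),
    atom("O1", "O", "LIG", 900, 0, 0, d, lig = TRUE))
  if (with_h) {
    a <- h_angle * pi / 180
    rows <- c(rows, list(atom("H", "H", "GLY", 1, sin(a), 0, cos(a))))
  }
  do.call(atoms_df, rows)
}

test_that("PDB reading handles minimal files, models and waters", {
  p <- withr::local_tempfile(fileext = ".pdb")
  st <- atoms_df(atom("N", "N", "ALA", 1, 0, 0, 0),
                 atom("CA", "C", "ALA", 1, 1.5, 0, 0))
  write_pdb(st, p)
  back <- read_pdb(p)
  expect_s3_class(back, "pdb_structure")
  expect_equal(nrow(back), 2L)
  expect_false(any(back$is_ligand))
  expect_equal(coords(back), coords(st), tolerance = 1e-3)

  # multi-model files yield one structure per MODEL
  write_pdb(list(st, st), p)
  models <- read_pdb(p)
  expect_length(models, 2L)
  expect_equal(nrow(models[[1]]), nrow(models[[2]]))

  # waters are dropped; other HETATM become ligand
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  O   HOH A  90       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  C1  LIG A  91       3.000   0.000   0.000  1.00  0.00           C")
  writeLines(lines, p)
  st2 <- read_pdb(p)
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$is_ligand, c(FALSE, TRUE))

  writeLines("REMARK nothing here", p)
  expect_error(read_pdb(p), "no ATOM/HETATM")
  writeLines(c(lines[1], gsub("3.000", "x.xxx", lines[3])), p)
  expect_error(read_pdb(p), "line 2")
})

test_that("element inference falls back to the atom name", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
    "ATOM      2 1HB  ALA A   1       1.000   0.000   0.000",
    "HETATM    3  O1  LIG A  90       3.000   0.000   0.000")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  st <- read_pdb(p)
  expect_equal(st$element, c("C", "H", "O"))
})

test_that("PDB reader agrees with bio3d on a written fixture", {
  skip_if_not_installed("bio3d")
  p <- withr::local_tempfile(fileext = ".pdb")
  gc <- generate_complex(2, 2, seed = 5)
  write_pdb(gc$structure, p)
  ours <- read_pdb(p)
  ref <- bio3d::read.pdb(p)
  expect_equal(nrow(ours), nrow(ref$atom))
  expect_equal(coords(ours), matrix(ref$xyz, ncol = 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(ours$residue_number, ref$atom$resno)
})

test_that("hydrogen bond detection honors distance and angle criteria", {
  expect_equal(nrow(find_hbonds(make_hb_pair(2.9))), 1L)
  expect_equal(nrow(find_hbonds(make_hb_pair(3.6))), 0L)
  # explicit hydrogen pointing 60 degrees off the D-A axis blocks the bond
  expect_equal(nrow(find_hbonds(make_hb_pair(2.9, with_h = TRUE, h_angle = 60))), 0L)
  # well-aligned hydrogen keeps it, and the angle is recorded
  hb <- find_hbonds(make_hb_pair(2.9, with_h = TRUE, h_angle = 10))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 10, tolerance = 1e-6)
  # no ligand -> error
  st <- atoms_df(atom("N", "N", "GLY", 1, 0, 0, 0))
  expect_error(find_hbonds(st), "no ligand")
})

test_that("hydrophobic contacts require carbon-carbon pairs within cutoff", {
  st <- atoms_df(atom("CB", "C", "ALA", 1, 0, 0, 0),
                 atom("O", "O", "ALA", 2, 10, 0, 0),
                 atom("C1", "C", "LIG", 900, 0, 0, 3.8, lig = TRUE),
                 atom("O1", "O", "LIG", 900, 10, 0, 3.0, lig = TRUE))
  hc <- find_hydrophobic_contacts(st)
  expect_equal(nrow(hc), 1L)          # the O...C pair at 3.0 does not count
  expect_equal(hc$distance, 3.8, tolerance = 1e-9)
  st_far <- atoms_df(atom("CB", "C", "ALA", 1, 0, 0, 0),
                     atom("C1", "C", "LIG", 900, 0, 0, 4.5, lig = TRUE))
  expect_equal(nrow(find_hydrophobic_contacts(st_far)), 0L)
})

test_that("interaction summary tallies planted contacts per residue exactly", {
  gc <- generate_complex(2, 3, seed = 11)
  prof <- interaction_summary(gc$structure)
  expect_equal(nrow(prof$hydrogen_bonds), 2L)
  expect_equal(nrow(prof$hydrophobic_contacts), 3L)
  per <- prof$per_residue_counts
  expect_equal(per$residue_number, gc$truth$residue_number)
  expect_equal(per$n_hbond, gc$truth$n_hbond)
  expect_equal(per$n_hydrophobic, gc$truth$n_hydrophobic)
  # count sums match the contact lists
  expect_equal(sum(per$n_hbond), nrow(prof$hydrogen_bonds))
  expect_equal(sum(per$n_hydrophobic), nrow(prof$hydrophobic_contacts))

  empty <- generate_complex(0, 0, seed = 1)
  prof0 <- interaction_summary(empty$structure)
  expect_equal(nrow(prof0$per_residue_counts), 0L)

  lig_only <- atoms_df(atom("C1", "C", "LIG", 900, 0, 0, 0, lig = TRUE))
  expect_error(interaction_summary(lig_only), "no protein")
})

test_that("contact profiles are invariant under global rigid transforms", {
  gc <- generate_complex(3, 2, seed = 23)
  prof <- interaction_summary(gc$structure)
  set.seed(99)
  for (i in 1:5) {
    moved <- rigid_move_structure(gc$structure, runif(1, 0, 360), rnorm(3), rnorm(3, 0, 20))
    prof2 <- interaction_summary(moved)
    expect_equal(prof2$per_residue_counts, prof$per_residue_counts)
    expect_equal(prof2$hydrogen_bonds$distance, prof$hydrogen_bonds$distance,
                 tolerance = 1e-9)
    expect_equal(prof2$hydrophobic_contacts$distance,
                 prof$hydrophobic_contacts$distance, tolerance = 1e-9)
  }
})

test_that("contact counts are monotone non-decreasing in the cutoffs", {
  gc <- generate_complex(3, 3, seed = 31)
  hb_counts <- vapply(c(2.5, 3.0, 3.5, 4.0, 4.5),
                      function(d) nrow(find_hbonds(gc$structure, d)), 0L)
  hc_counts <- vapply(c(3.0, 3.5, 4.0, 4.5, 5.0),
                      function(d) nrow(find_hydrophobic_contacts(gc$structure, d)), 0L)
  expect_true(all(diff(hb_counts) >= 0))
  expect_true(all(diff(hc_counts) >= 0))
})
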