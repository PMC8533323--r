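test_that("clear-cut geometries are classified correctly", {
  # donor-acceptor at 2.8 A, near-linear angle: hydrogen bond
  tr <- boundary_frame(offset = 2.8 - interaction_criteria()$hbond_dist)
  cts <- detect_interactions(tr)
  expect_true(any(cts$type == "hydrogen_bond" & cts$resno == 1))
  # everything at 5 A beyond its threshold: nothing at all
  far <- boundary_frame(offset = 5.0)
  expect_identical(nrow(detect_interactions(far)), 0L)
})

test_that("contacts straddle their distance thresholds sharply", {
  inside <- boundary_frame(offset = -0.01)
  cts <- detect_interactions(inside)
  expect_identical(nrow(cts), 4L)
  expect_setequal(cts$type, c("hydrogen_bond", "hydrophobic", "ionic",
                              "water_bridge"))
  outside <- boundary_frame(offset = +0.01)
  expect_identical(nrow(detect_interactions(outside)), 0L)
})

test_that("missing hydrogens fall back to the distance-only criterion with a warning", {
  tr <- boundary_frame(offset = -0.5)
  keep <- tr$atoms$elem != "H"
  xyz_cols <- as.vector(t(matrix(seq_len(3 * nrow(tr$atoms)), ncol = 3,
                                 byrow = TRUE)[keep, ]))
  bare <- trajectory_frames(tr$xyz[, xyz_cols, drop = FALSE],
                            tr$atoms[keep, ])
  expect_warning(cts <- detect_interactions(bare), "distance-only")
  expect_true(any(cts$type == "hydrogen_bond"))
})

test_that("occupancy fractions are exact frame counts", {
  tr1 <- generate_complex_trajectory(n_frames = 20,
                                     occupancy = c(hydrogen_bond = 1),
                                     seed = 2)
  occ1 <- occupancy_fractions(tr1)
  expect_equal(occ1$fraction[occ1$type == "hydrogen_bond"], 1.0)

  tr37 <- generate_complex_trajectory(n_frames = 100,
                                      occupancy = c(hydrogen_bond = 0.37),
                                      seed = 2)
  occ37 <- occupancy_fractions(tr37)
  expect_identical(occ37$fraction[occ37$type == "hydrogen_bond"], 0.37)

  tr0 <- generate_complex_trajectory(n_frames = 50,
                                     occupancy = c(hydrogen_bond = 0),
                                     seed = 2)
  expect_false("hydrogen_bond" %in% occupancy_fractions(tr0)$type)
})

test_that("occupancy fractions are invariant under frame reordering", {
  tr <- generate_complex_trajectory(
    n_frames = 40,
    occupancy = c(hydrogen_bond = 0.4, ionic = 0.7, hydrophobic = 0.25,
                  water_bridge = 0.5),
    seed = 9)
  occ <- occupancy_fractions(tr)
  set.seed(1)
  perm <- sample(nrow(tr$xyz))
  tr2 <- trajectory_frames(tr$xyz[perm, , drop = FALSE], tr$atoms,
                           time_step_ns = tr$time_step_ns)
  occ2 <- occupancy_fractions(tr2)
  expect_identical(occ, occ2)
  # planted occupancies recovered exactly for all four types
  for (tp in c("hydrogen_bond", "ionic", "hydrophobic", "water_bridge")) {
    expect_identical(occ$fraction[occ$type == tp],
                     c(hydrogen_bond = 0.4, ionic = 0.7, hydrophobic = 0.25,
                       water_bridge = 0.5)[[tp]],
                     info = tp)
  }
})

test_that("RMSD is zero on identical frames and invariant to rigid motion", {
  tr <- generate_complex_trajectory(n_frames = 8, seed = 4)
  expect_equal(protein_rmsd(tr), rep(0, 8), tolerance = 1e-8)

  moved <- tr$xyz
  set.seed(21)
  for (f in 2:8) {
    R <- rigid_rotation(stats::runif(3), stats::runif(1, 0, pi))
    moved[f, ] <- apply_rigid(tr$xyz[f, ], R, stats::runif(3, -30, 30))
  }
  tr2 <- trajectory_frames(moved, tr$atoms)
  expect_equal(protein_rmsd(tr2), rep(0, 8), tolerance = 1e-8)
})

test_that("single-atom displacement RMSD matches a brute-force alignment search", {
  # 5 anchor atoms plus one atom displaced 1 A
  anchors <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(0, 0, 6),
                   c(6, 6, 0), c(2, 2, 2))
  moved <- anchors
  moved[6, ] <- moved[6, ] + c(1, 0, 0)
  atoms <- data.frame(
    elety = "CA", elem = "C", resno = 1:6, resid = "ALA", chain = "A",
    role = "protein", stringsAsFactors = FALSE
  )
  tr <- trajectory_frames(rbind(as.numeric(t(anchors)),
                                as.numeric(t(moved))), atoms)
  got <- protein_rmsd(tr, selection = 1:6)[2]
  want <- oracle_fit_rmsd(anchors, moved)
  # the numeric search gives an upper bound on the optimum; the analytic
  # superposition must reach it (within search convergence slack)
  expect_lte(got, want + 1e-8)
  expect_equal(got, want, tolerance = 1e-3)
  expect_lt(got, sqrt(1 / 6))  # superposition improves on the naive residual
})

test_that("degenerate selections are rejected", {
  tr <- generate_complex_trajectory(n_frames = 3, seed = 4)
  expect_error(protein_rmsd(tr, selection = 1:2),
               class = "ivs_superposition_error")
})

test_that("multi-model PDB round-trips frames, roles and analytics", {
  tr <- generate_complex_trajectory(
    n_frames = 6, occupancy = c(hydrogen_bond = 0.5, ionic = 0.5), seed = 8)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, path)
  tr2 <- read_multimodel_pdb(path, ligand_resnames = "LIG",
                             ligand_charges = c(N1 = 1))
  expect_identical(nrow(tr2$xyz), 6L)
  expect_identical(tr2$atoms$role, tr$atoms$role)
  expect_equal(tr2$xyz, tr$xyz, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(occupancy_fractions(tr2), occupancy_fractions(tr))
})
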