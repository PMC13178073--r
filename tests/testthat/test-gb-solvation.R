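single_ion <- function(q = 1, rho = 2.09) {
  at <- atom_table(1L, "O1", 1L, "ION", "A", 0, 0, 0, charge = q,
                   gb_radius = rho, lj_rmin_half = 1.6, lj_epsilon = 0.1)
  molecular_system(at, integer(0), at$serial, allow_empty_ligand = TRUE)
}

test_that("isolated and well-separated atoms recover intrinsic Born radii", {
  ## single atom: intrinsic minus the 0.09 A offset
  expect_equal(born_radii(single_ion(rho = 2.09), matrix(0, 1, 3)), 2.00,
               tolerance = 1e-12)
  ## two atoms 100 A apart: descreening vanishes
  at <- atom_table(1:2, c("O1", "O2"), 1:2, "ION", "A", x = c(0, 100), y = 0,
                   z = 0, charge = 1, gb_radius = 2.09, lj_rmin_half = 1.6,
                   lj_epsilon = 0.1)
  sys <- molecular_system(at, integer(0), at$serial, allow_empty_ligand = TRUE)
  r <- born_radii(sys, as.matrix(at[, c("x", "y", "z")]))
  expect_lt(max(abs(r - 2.00)), 1e-4)
  ## symmetric homonuclear dimer: equal radii
  at2 <- atom_table(1:2, c("C1", "C2"), 1:2, "MOL", "A", x = c(0, 2.5), y = 0,
                    z = 0, charge = 0.3, gb_radius = 1.7, lj_rmin_half = 1.6,
                    lj_epsilon = 0.1)
  sys2 <- molecular_system(at2, integer(0), at2$serial, allow_empty_ligand = TRUE)
  r2 <- born_radii(sys2, as.matrix(at2[, c("x", "y", "z")]))
  expect_equal(r2[1], r2[2], tolerance = 1e-12)
  expect_gt(r2[1], 1.61)  # descreening enlarges the effective radius
})

test_that("single-ion polar energy matches the Born closed form", {
  for (R in c(1, 2, 4)) {
    sys <- single_ion(q = 1, rho = R + 0.09)
    got <- gb_polar_energy(sys, matrix(0, 1, 3), eps_in = 1, eps_out = 78.5)
    want <- -0.5 * 332.0637 * (1 - 1 / 78.5) / R
    expect_equal(got, want, tolerance = 0.01)
  }
  ## the worked number: q = +1 e, effective radius 2.0 A
  expect_equal(gb_polar_energy(single_ion(1, 2.09), matrix(0, 1, 3), 1, 78.5),
               -81.96, tolerance = 1e-3)
})

test_that("polar energy degenerates correctly and scales quadratically", {
  sys <- single_ion(0)
  expect_equal(gb_polar_energy(sys, matrix(0, 1, 3), 1, 78.5), 0.0)
  ## no dielectric contrast
  expect_equal(gb_polar_energy(single_ion(1), matrix(0, 1, 3), 2, 2), 0.0)
  ## q -> 2q gives 4x for fixed geometry
  rs <- make_random_system(21)
  e1 <- gb_polar_energy(rs$system, rs$frame)
  at <- rs$system$atoms; at$charge <- 2 * at$charge
  sys2 <- molecular_system(
    atom_table(at$serial, at$name, at$residue_id, at$residue_name, at$chain,
               at$x, at$y, at$z, at$charge, at$gb_radius, at$lj_rmin_half,
               at$lj_epsilon), rs$system$ligand_serials)
  expect_equal(gb_polar_energy(sys2, rs$frame), 4 * e1, tolerance = 1e-9)
})

test_that("solvation terms are invariant under rigid motion", {
  rs <- make_random_system(22)
  moved <- rigid_motion(rs$frame)
  cfg <- bindmode_config()
  a <- solvation_energy(rs$system, rs$frame, cfg)
  b <- solvation_energy(rs$system, moved, cfg)
  expect_equal(a$g_polar, b$g_polar, tolerance = 1e-6)
  ## the fixed sphere-point grid makes SASA orientation-dependent at the
  ## quadrature level (~0.5% at 960 points)
  expect_equal(a$g_nonpolar, b$g_nonpolar, tolerance = 0.01)
  expect_equal(a$born_radii, b$born_radii, tolerance = 1e-9)
})

test_that("SASA matches sphere oracles", {
  ## isolated sphere r = 1.6, probe 1.4: 4 pi 3^2
  expect_equal(shrake_rupley(matrix(0, 1, 3), 1.6), 4 * pi * 9, tolerance = 1e-9)
  ## two distant atoms: additive
  two <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sum(shrake_rupley(two, c(1.6, 1.6))), 8 * pi * 9, tolerance = 1e-9)
  ## overlapping equal spheres vs the analytic two-cap formula, 960 points
  for (d in c(2.0, 3.5, 5.0)) {
    Rext <- 3.0
    got <- sum(shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.6, 1.6)))
    h <- Rext - d / 2
    want <- 2 * (4 * pi * Rext^2 - 2 * pi * Rext * h)
    expect_equal(got, want, tolerance = 0.02)
  }
  ## quadrature stability: 960 vs 5000 points within 0.5%
  rs <- make_random_system(23)
  s960 <- sum(shrake_rupley(rs$frame, rs$system$atoms$gb_radius, points = 960))
  s5000 <- sum(shrake_rupley(rs$frame, rs$system$atoms$gb_radius, points = 5000))
  expect_lt(abs(s960 - s5000) / s5000, 0.005)
})

test_that("nonpolar term follows gamma * SASA + b", {
  sys <- single_ion(1, rho = 1.6)
  fr <- matrix(0, 1, 3)
  expect_equal(sasa_nonpolar(sys, fr, gamma = 0.0072, beta_const = 0),
               0.0072 * 4 * pi * 9, tolerance = 1e-6)
  expect_equal(sasa_nonpolar(sys, fr, gamma = 0, beta_const = 1.25), 1.25)
})

test_that("delta_g_solv vanishes for distant non-interacting species", {
  ## an uncharged guest 120 A from the receptor: the species' self-energies
  ## cancel exactly in the complex (with charges the screened 1/r
  ## charge-charge tail would remain, which is real physics, not an error)
  hg <- make_host_guest(seed = 5, n_frames = 1, jitter_sigma = 0)
  at <- hg$system$atoms
  lig_rows <- at$residue_name == "LIG"
  at$x[lig_rows] <- at$x[lig_rows] + 120
  at$charge[lig_rows] <- 0
  sys <- molecular_system(
    atom_table(at$serial, at$name, at$residue_id, at$residue_name, at$chain,
               at$x, at$y, at$z, at$charge, at$gb_radius, at$lj_rmin_half,
               at$lj_epsilon), hg$system$ligand_serials)
  sys$atoms$gb_screen <- at$gb_screen
  ens <- snapshot_ensemble(sys, list(as.matrix(sys$atoms[, c("x", "y", "z")])))
  solv <- delta_g_solv(ens, bindmode_config())
  expect_lt(abs(solv$dg_solv[1]), 1e-3)
})

test_that("fast per-species solvation equals independent single-species calls", {
  hg <- make_host_guest(seed = 6, n_frames = 2, jitter_sigma = 0.1)
  cfg <- bindmode_config()
  solv <- delta_g_solv(hg$pose_a, cfg)
  fr <- hg$pose_a$frames[[2]]
  sys <- hg$pose_a$system
  ri <- which(sys$atoms$residue_name != "LIG")
  li <- which(sys$atoms$residue_name == "LIG")
  rec_at <- sys$atoms[ri, ]; class(rec_at) <- c("atom_table", "data.frame")
  lig_at <- sys$atoms[li, ]; class(lig_at) <- c("atom_table", "data.frame")
  rec <- molecular_system(rec_at, integer(0), rec_at$serial, allow_empty_ligand = TRUE)
  lig <- molecular_system(lig_at, integer(0), lig_at$serial, allow_empty_ligand = TRUE)
  sc <- solvation_energy(sys, fr, cfg)
  sr <- solvation_energy(rec, fr[ri, ], cfg)
  sl <- solvation_energy(lig, fr[li, ], cfg)
  expect_equal(solv$dg_solv[2], sc$g_solv - sr$g_solv - sl$g_solv,
               tolerance = 1e-9)
})
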