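## small helper ensembles for metric tests
static_ensemble <- function(seed = 31, n_frames = 4) {
  rs <- make_random_system(seed, n_rec = 10, n_lig = 3, n_res = 5)
  snapshot_ensemble(rs$system, rep(list(rs$frame), n_frames))
}

test_that("Kabsch superposition recovers rigid motions and hand cases", {
  rs <- make_random_system(30)
  sel <- seq_len(nrow(rs$frame))
  ## frame vs itself: identity rotation, RMSD 0
  s <- kabsch_superpose(rs$frame, rs$frame, sel)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  ## rigidly moved copy: RMSD < 1e-6, proper rotation
  moved <- rigid_motion(rs$frame)
  s2 <- kabsch_superpose(moved, rs$frame, sel)
  expect_lt(s2$rmsd, 1e-6)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
  ## same shape at double scale: centered deviations all equal the original
  ## radius, so optimal RMSD = sqrt(2) for the unit square (hand derivation)
  sq <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1), 0)
  s3 <- kabsch_superpose(2 * sq, sq, 1:4)
  expect_equal(s3$rmsd, sqrt(2), tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate fits", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line, 1:4), "collinear")
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(kabsch_superpose(tri, tri, 1:2), "at least 3")
})

test_that("RMSD series: zeros when static, calibrated under jitter, symmetric", {
  ens <- static_ensemble()
  bb <- seq_len(10)
  expect_true(all(rmsd_series(ens, bb)$value < 1e-9))
  ## Gaussian jitter sigma = 0.1 A: mean RMSD lands in the simulation band
  hg <- make_host_guest(seed = 32, n_frames = 20, jitter_sigma = 0.1)
  r <- rmsd_series(hg$pose_a, seq_len(60))
  expect_gt(mean(r$value[-1]), 0.05)
  expect_lt(mean(r$value[-1]), 0.3)
  ## mutual symmetry: RMSD(a on b) == RMSD(b on a)
  a <- hg$pose_a$frames[[2]]; b <- hg$pose_a$frames[[3]]
  sel <- seq_len(60)
  expect_equal(kabsch_superpose(a, b, sel)$rmsd,
               kabsch_superpose(b, a, sel)$rmsd, tolerance = 1e-9)
})

test_that("fit/measure swap leaves the series unchanged on a mirrored toy", {
  ## two congruent triangles receiving identical per-frame jitter: fitting on
  ## either and measuring the other gives the same series by symmetry
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  base <- rbind(tri, tri + matrix(rep(c(0, 0, 6), each = 3), 3))
  at <- atom_table(1:6, sprintf("C%d", 1:6), c(1L, 1L, 1L, 2L, 2L, 2L),
                   c(rep("REC", 3), rep("LIG", 3)), "A",
                   base[, 1], base[, 2], base[, 3],
                   charge = 0, gb_radius = 1.6, lj_rmin_half = 1.5,
                   lj_epsilon = 0.1)
  sys <- molecular_system(at, 4:6)
  set.seed(33)
  frames <- lapply(1:5, function(k) {
    jit <- matrix(rnorm(9, 0, 0.2), 3, 3)
    base + rbind(jit, jit)
  })
  ens <- snapshot_ensemble(sys, frames)
  r1 <- rmsd_series(ens, 1:3, 4:6)
  r2 <- rmsd_series(ens, 4:6, 1:3)
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
})

test_that("RMSF is zero for static ensembles and localizes planted motion", {
  ens <- static_ensemble()
  expect_true(all(rmsf_per_residue(ens, seq_len(10))$value < 1e-9))
  ## jitter only the atoms of one residue; fit on the static rest
  rs <- make_random_system(34, n_rec = 12, n_lig = 3, n_res = 4)
  jittered <- which(rs$system$atoms$residue_id == 2L)
  still <- setdiff(seq_len(12), jittered)
  set.seed(34)
  frames <- lapply(1:8, function(k) {
    fr <- rs$frame
    fr[jittered, ] <- fr[jittered, ] + matrix(rnorm(3 * length(jittered), 0, 0.3),
                                              length(jittered), 3)
    fr
  })
  ens2 <- snapshot_ensemble(rs$system, frames)
  rf <- rmsf_per_residue(ens2, still)
  expect_gt(rf$value[rf$residue_id == 2L], 0.1)
  expect_true(all(rf$value[!(rf$residue_id %in% c(2L))] < 0.05))
})

test_that("RMSF is invariant under a global rigid motion of every frame", {
  hg <- make_host_guest(seed = 35, n_frames = 6, jitter_sigma = 0.15)
  ens <- hg$pose_a
  moved <- snapshot_ensemble(ens$system, lapply(ens$frames, rigid_motion))
  f1 <- rmsf_per_residue(ens, seq_len(60))
  f2 <- rmsf_per_residue(moved, seq_len(60))
  expect_equal(f1$value, f2$value, tolerance = 1e-9)
})

test_that("region report covers configured residue ranges", {
  hg <- make_host_guest(seed = 36, n_frames = 5, jitter_sigma = 0.1)
  rf <- rmsf_per_residue(hg$pose_a, seq_len(60))
  rep <- region_report(rf, list(region_definition("pocket", 4, 4),
                                region_definition("far-side", 1, 2)))
  expect_equal(rep$n_residues, c(1L, 2L))
  expect_true(all(is.finite(rep$rmsf_mean)))
})

test_that("ensemble SASA tracks compactness and degenerate spread", {
  ## single sphere series
  at <- atom_table(1L, "C1", 1L, "LIG", "A", 0, 0, 0, charge = 0,
                   gb_radius = 1.6, lj_rmin_half = 1.5, lj_epsilon = 0.1)
  sys <- molecular_system(at, integer(0), 1L, allow_empty_ligand = TRUE)
  ens <- snapshot_ensemble(sys, rep(list(matrix(0, 1, 3)), 3))
  s <- ensemble_sasa(ens)
  expect_equal(s$value, rep(4 * pi * 9, 3), tolerance = 1e-9)
  expect_equal(attr(s, "sd"), 0)
  ## compact dimer buries more surface than a stretched one
  compact <- make_dimer(2.0); stretched <- make_dimer(6.0)
  e1 <- snapshot_ensemble(compact$system, list(compact$frame))
  e2 <- snapshot_ensemble(stretched$system, list(stretched$frame))
  expect_lt(ensemble_sasa(e1)$value, ensemble_sasa(e2)$value)
})

test_that("binding-site selection picks residues near the ligand", {
  hg <- make_host_guest(seed = 37, n_frames = 1)
  site <- select_binding_site(hg$pose_a, radius = 5)
  expect_gt(length(site), 0)
  ## every selected atom's residue has an atom within the cutoff
  sys <- hg$pose_a$system
  fr <- hg$pose_a$frames[[1]]
  li <- which(sys$atoms$residue_name == "LIG")
  for (res in unique(sys$atoms$residue_id[site])) {
    rows <- which(sys$atoms$residue_id == res)
    dmin <- min(as.matrix(dist(fr))[rows, li])
    expect_lte(dmin, 5)
  }
})
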