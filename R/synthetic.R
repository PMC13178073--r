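## Synthetic generators covering every pipeline input with known ground
## truth: a toy host-guest complex with two planted pose hypotheses of known
## relative stability (emulating the dual CA-like/BA-like setup), Gaussian
## interaction-energy streams for the entropy estimator, and 4PL
## dose-response plates. All generators are pure functions of (parameters,
## seed). Toy parameters are made-up but physically sane (charges <= 1 e,
## radii 1.2-2.2 A); the point is parameter and pose recovery, not chemistry.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Synthetic host-guest complex with two planted pose hypotheses
#'
#' A 60-atom ring-shaped "receptor" (6 residues of 10 atoms, ring radius 5 A)
#' carries a negatively charged pocket on one side; a 10-atom "guest" with
#' complementary positive charges is placed either at the ring center
#' adjacent to the pocket (pose A: deep Lennard-Jones contact plus favorable
#' Coulomb) or at a shallow site outside the ring, away from the pocket
#' (pose B). Frames are the rigid pose plus i.i.d. Gaussian coordinate
#' jitter. By construction pose A has the lower mean interaction enthalpy;
#' the generator's contract is that pose ranking recovers this ordering.
#'
#' @param seed RNG seed (the generator is a pure function of its arguments).
#' @param n_frames frames per pose ensemble (default 50).
#' @param jitter_sigma per-coordinate Gaussian jitter, Angstrom (default 0.08).
#' @param dir optional output directory; when given, writes pose_a.pdb,
#'   pose_b.pdb, system.pqr and system_lj.json in the package's own formats.
#' @return list with `pose_a`, `pose_b` (parameterized [snapshot_ensemble()]s)
#'   and `system` (the complex [molecular_system()] at pose-A geometry).
#' @export
make_host_guest <- function(seed = 1, n_frames = 50, jitter_sigma = 0.08,
                            dir = NULL) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0)
  ## receptor: ring of 60 atoms in the xy-plane, radius 5 A
  n_rec <- 60L
  theta <- 2 * pi * (seq_len(n_rec) - 1) / n_rec
  rec_xyz <- cbind(5 * cos(theta), 5 * sin(theta), 0)
  rec_res <- rep(1:6, each = 10L)
  ## charged pocket: the 10 atoms of residue 4 (angles around 180 deg)
  rec_q <- ifelse(rec_res == 4L, -0.25, 0)
  ## guest: ring of 8 (radius 1.5 A) plus 2 apical atoms
  phi <- 2 * pi * (0:7) / 8
  gue_xyz <- rbind(cbind(1.5 * cos(phi), 1.5 * sin(phi), 0),
                   c(0, 0, 0.8), c(0, 0, -0.8))
  n_gue <- nrow(gue_xyz)
  gue_q <- c(rep(c(0.25, 0), 4), 0, 0)   # 4 charged ring atoms, net +1 e
  place <- function(center) sweep(gue_xyz, 2, center, "+")
  pose_centers <- list(A = c(0, 0, 0), B = c(10, 0, 0))

  atoms <- atom_table(
    serial = seq_len(n_rec + n_gue),
    name = c(sprintf("C%d", ((seq_len(n_rec) - 1) %% 10) + 1),
             sprintf("G%d", seq_len(n_gue))),
    residue_id = c(rec_res, rep(7L, n_gue)),
    residue_name = c(rep("RNG", n_rec), rep("LIG", n_gue)),
    chain = "A",
    x = c(rec_xyz[, 1], place(pose_centers$A)[, 1]),
    y = c(rec_xyz[, 2], place(pose_centers$A)[, 2]),
    z = c(rec_xyz[, 3], place(pose_centers$A)[, 3]),
    charge = c(rec_q, gue_q),
    gb_radius = c(rep(1.7, n_rec), rep(1.5, n_gue)),
    lj_rmin_half = c(rep(1.6, n_rec), rep(1.4, n_gue)),
    lj_epsilon = c(rep(0.12, n_rec), rep(0.15, n_gue))
  )
  atoms$gb_screen <- rep(0.72, n_rec + n_gue)
  system <- molecular_system(atoms, ligand_serials = (n_rec + 1):(n_rec + n_gue))

  make_frames <- function(center, seed_offset) with_seed(seed + seed_offset, {
    base <- rbind(rec_xyz, place(center))
    lapply(seq_len(n_frames), function(k)
      base + matrix(rnorm(length(base), 0, jitter_sigma), nrow(base), 3))
  })
  pose_a <- snapshot_ensemble(system, make_frames(pose_centers$A, 0L))
  pose_b <- snapshot_ensemble(system, make_frames(pose_centers$B, 1000L))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pdb_ensemble(pose_a, file.path(dir, "pose_a.pdb"))
    write_pdb_ensemble(pose_b, file.path(dir, "pose_b.pdb"))
    write_pqr(system, file.path(dir, "system.pqr"))
    write_lj_sidecar(system, file.path(dir, "system_lj.json"))
  }
  list(pose_a = pose_a, pose_b = pose_b, system = system)
}

#' Gaussian interaction-energy sample stream
#'
#' i.i.d. normal samples exercising the interaction-entropy estimator, whose
#' Gaussian closed form is -T dS = sigma^2 / (2 kB T).
#'
#' @param sigma sample SD, kcal/mol (>= 0).
#' @param n number of samples (>= 2).
#' @param seed RNG seed.
#' @param mean sample mean, kcal/mol (shift-invariant for the estimator).
#' @return numeric vector of length `n`.
#' @export
make_gaussian_energy_traj <- function(sigma, n, seed = 1, mean = -50) {
  stopifnot(sigma >= 0, n >= 2)
  with_seed(seed, rnorm(n, mean, sigma))
}

#' Synthetic TR-FRET dose-response plate
#'
#' Doses are log-spaced over 1 pM - 100 uM; responses follow the 4PL model
#' plus Gaussian noise and are emitted as 520/495 channel pairs (constant
#' donor channel) whose ratio equals the noisy response.
#'
#' @param params list with `bottom`, `top`, `hill`, `log_mid` (log10 M).
#' @param noise_sd response noise SD (same unit as the response).
#' @param n_doses number of dose levels (default 10).
#' @param n_reps replicate wells per dose (default 3).
#' @param seed RNG seed.
#' @param path optional CSV output path.
#' @return plate data.frame with columns well, concentration, unit, em520,
#'   em495; attribute `truth` carries the generating parameters.
#' @export
make_dose_response <- function(params, noise_sd = 0, n_doses = 10, n_reps = 3,
                               seed = 1, path = NULL) {
  stopifnot(all(c("bottom", "top", "hill", "log_mid") %in% names(params)),
            noise_sd >= 0, n_doses >= 5, n_reps >= 1)
  conc <- 10^seq(-12, -4, length.out = n_doses)       # 1 pM .. 100 uM
  conc_all <- rep(conc, each = n_reps)
  resp <- pl4(log10(conc_all), params$bottom, params$top,
              params$hill, params$log_mid)
  resp <- resp + with_seed(seed, rnorm(length(resp), 0, noise_sd))
  donor <- 10000
  plate <- data.frame(
    well = sprintf("W%03d", seq_along(conc_all)),
    concentration = conc_all, unit = "M",
    em520 = resp * donor, em495 = donor
  )
  attr(plate, "truth") <- params
  if (!is.null(path)) write.csv(plate, path, row.names = FALSE)
  plate
}
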