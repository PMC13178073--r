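## Shared fixtures built in code: toy parameterized systems, random small
## systems for brute-force oracles, and minimal SDF/PDB/PQR writers.

## two-atom receptor/ligand dimer along x at separation `r`
make_dimer <- function(r, q = c(1, 1), rmin_half = c(1.6, 1.6),
                       epsilon = c(0.5, 0.5), gb_radius = c(1.7, 1.7)) {
  at <- atom_table(serial = 1:2, name = c("C1", "G1"),
                   residue_id = c(1L, 2L), residue_name = c("REC", "LIG"),
                   chain = "A", x = c(0, r), y = 0, z = 0,
                   charge = q, gb_radius = gb_radius,
                   lj_rmin_half = rmin_half, lj_epsilon = epsilon)
  sys <- molecular_system(at, ligand_serials = 2L)
  list(system = sys, frame = as.matrix(at[, c("x", "y", "z")]))
}

## random parameterized system: n_rec receptor atoms (split into residues)
## plus n_lig ligand atoms, coordinates in a box, no coincident pairs
make_random_system <- function(seed, n_rec = 12, n_lig = 5, n_res = 3,
                               box = 8) {
  set.seed(seed)
  n <- n_rec + n_lig
  repeat {
    xyz <- matrix(runif(n * 3, 0, box), n, 3)
    if (min(dist(xyz)) > 0.8) break
  }
  at <- atom_table(
    serial = seq_len(n),
    name = c(sprintf("C%d", seq_len(n_rec)), sprintf("G%d", seq_len(n_lig))),
    residue_id = c(rep(seq_len(n_res), length.out = n_rec), rep(n_res + 1L, n_lig)),
    residue_name = c(rep("REC", n_rec), rep("LIG", n_lig)),
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = round(runif(n, -0.5, 0.5), 3),
    gb_radius = round(runif(n, 1.2, 2.2), 3),
    lj_rmin_half = round(runif(n, 1.2, 2.0), 3),
    lj_epsilon = round(runif(n, 0.05, 0.3), 3)
  )
  sys <- molecular_system(at, ligand_serials = (n_rec + 1):n)
  list(system = sys, frame = xyz)
}

## rigid motion: proper rotation about given axis/angle plus translation
rigid_motion <- function(coords, angle = 0.7, axis = c(1, 2, 3),
                         shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(coords %*% t(R), 2, shift, "+")
}

## minimal V2000 SDF writer for tests (counts line + atom/bond blocks)
write_test_sdf <- function(path, elements, bonds,
                           coords = matrix(0, length(elements), 3)) {
  n_a <- length(elements); n_b <- nrow(bonds)
  lines <- c("test molecule", "  tester", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b))
  for (i in seq_len(n_a))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[i, 1], coords[i, 2], coords[i, 3], elements[i]))
  for (k in seq_len(n_b))
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$a[k], bonds$b[k], bonds$order[k]))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  path
}

ligand_fixture <- function(name) {
  system.file("extdata", "ligands", paste0(name, ".sdf"), package = "bindmode")
}

## brute-force double-loop nonbonded oracle (independent of the vectorized path)
brute_force_interaction <- function(system, frame, dielectric) {
  at <- system$atoms
  ri <- match(system$receptor_serials, at$serial)
  li <- match(system$ligand_serials, at$serial)
  e_ele <- 0; e_vdw <- 0
  for (i in ri) for (j in li) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    e_ele <- e_ele + 332.0637 * at$charge[i] * at$charge[j] / (dielectric * r)
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    e_vdw <- e_vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  list(e_ele = e_ele, e_vdw = e_vdw)
}
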