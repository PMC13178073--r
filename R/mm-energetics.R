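## Intermolecular molecular-mechanics interaction energies between receptor
## and ligand masks: Coulomb (screened by an interior dielectric) and 12-6
## Lennard-Jones with Lorentz-Berthelot combining. Single-trajectory
## convention: receptor and ligand conformations are taken from the complex
## frame, so internal (bonded) terms cancel and the interaction energy is the
## receptor-ligand nonbonded sum. No cutoff is applied: systems are finite
## and the rescoring is exact.

## pairwise distance matrix between two coordinate blocks (rows of frames)
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

check_coincident <- function(r, ser_i, ser_j, context) {
  if (any(r < 1e-6)) {
    k <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: coincident atoms (r < 1e-6 A) between serials %d and %d",
                 context, ser_i[k[1]], ser_j[k[2]]))
  }
}

#' Receptor-ligand Coulomb interaction energy of one frame
#'
#' Sum of k_e q_i q_j / (eps r_ij) over receptor-ligand atom pairs, with
#' k_e = 332.0637 kcal A / (mol e^2).
#'
#' @param system a [molecular_system()] with charges set.
#' @param frame n_atoms x 3 coordinate matrix, Angstrom.
#' @param dielectric interior dielectric constant (> 0), default 2.
#' @return energy in kcal/mol.
#' @export
coulomb_interaction <- function(system, frame, dielectric = 2) {
  stopifnot(dielectric > 0)
  ri <- receptor_idx(system); li <- ligand_idx(system)
  if (!length(li)) stop("ligand mask is empty")
  q <- system$atoms$charge
  if (anyNA(q[c(ri, li)])) stop("charges unset; attach a PQR first")
  r <- cross_dist(frame[ri, , drop = FALSE], frame[li, , drop = FALSE])
  check_coincident(r, system$atoms$serial[ri], system$atoms$serial[li], "coulomb_interaction")
  COULOMB_KE / dielectric * sum(outer(q[ri], q[li]) / r)
}

#' Receptor-ligand Lennard-Jones interaction energy of one frame
#'
#' 12-6 form eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) with
#' eps_ij = sqrt(eps_i eps_j) and rmin_ij = rmin_half_i + rmin_half_j.
#'
#' @inheritParams coulomb_interaction
#' @return energy in kcal/mol.
#' @export
lj_interaction <- function(system, frame) {
  ri <- receptor_idx(system); li <- ligand_idx(system)
  if (!length(li)) stop("ligand mask is empty")
  at <- system$atoms
  if (anyNA(at$lj_epsilon[c(ri, li)]) || anyNA(at$lj_rmin_half[c(ri, li)]))
    stop("LJ parameters unset; attach a topology sidecar first")
  r <- cross_dist(frame[ri, , drop = FALSE], frame[li, , drop = FALSE])
  check_coincident(r, at$serial[ri], at$serial[li], "lj_interaction")
  eps <- sqrt(outer(at$lj_epsilon[ri], at$lj_epsilon[li]))
  rmin <- outer(at$lj_rmin_half[ri], at$lj_rmin_half[li], "+")
  s6 <- (rmin / r)^6
  sum(eps * (s6^2 - 2 * s6))
}

#' Electrostatic + van der Waals interaction energy of one frame
#'
#' @inheritParams coulomb_interaction
#' @return list with `e_ele`, `e_vdw`, `e_int` (= e_ele + e_vdw), kcal/mol.
#' @export
frame_interaction <- function(system, frame, dielectric = 2) {
  e_ele <- coulomb_interaction(system, frame, dielectric)
  e_vdw <- lj_interaction(system, frame)
  list(e_ele = e_ele, e_vdw = e_vdw, e_int = e_ele + e_vdw)
}

#' Per-frame interaction-energy table for an ensemble
#'
#' @param ensemble a [snapshot_ensemble()].
#' @param dielectric interior dielectric constant.
#' @return data.frame with columns frame, e_ele, e_vdw, e_int.
#' @export
ensemble_interactions <- function(ensemble, dielectric = 2) {
  per_frame <- vapply(ensemble$frames, function(fr) {
    fi <- frame_interaction(ensemble$system, fr, dielectric)
    c(fi$e_ele, fi$e_vdw)
  }, numeric(2))
  data.frame(frame = seq_along(ensemble$frames),
             e_ele = per_frame[1, ], e_vdw = per_frame[2, ],
             e_int = per_frame[1, ] + per_frame[2, ])
}

#' Per-residue decomposition of the receptor-ligand interaction energy
#'
#' Each receptor residue's electrostatic and van der Waals contribution is
#' the pair sum over (atoms of that residue) x (ligand atoms), averaged over
#' frames; the SD column is the spread across frames. Contributions sum to
#' the total interaction energy by construction.
#'
#' @param system a [molecular_system()].
#' @param ensemble a [snapshot_ensemble()] over the same system.
#' @param dielectric interior dielectric constant.
#' @return data.frame with columns residue_id, ele_mean, ele_sd, vdw_mean, vdw_sd.
#' @export
per_residue_decomposition <- function(system, ensemble, dielectric = 2) {
  stopifnot(n_frames(ensemble) >= 1)
  ri <- receptor_idx(system); li <- ligand_idx(system)
  if (!length(li)) stop("ligand mask is empty")
  at <- system$atoms
  res_of <- at$residue_id[ri]
  res_ids <- sort(unique(res_of))
  q <- at$charge
  per_frame_ele <- matrix(0, n_frames(ensemble), length(res_ids))
  per_frame_vdw <- matrix(0, n_frames(ensemble), length(res_ids))
  for (k in seq_len(n_frames(ensemble))) {
    fr <- ensemble$frames[[k]]
    r <- cross_dist(fr[ri, , drop = FALSE], fr[li, , drop = FALSE])
    check_coincident(r, at$serial[ri], at$serial[li], "per_residue_decomposition")
    ele_pair <- COULOMB_KE / dielectric * outer(q[ri], q[li]) / r
    eps <- sqrt(outer(at$lj_epsilon[ri], at$lj_epsilon[li]))
    rmin <- outer(at$lj_rmin_half[ri], at$lj_rmin_half[li], "+")
    s6 <- (rmin / r)^6
    vdw_pair <- eps * (s6^2 - 2 * s6)
    for (m in seq_along(res_ids)) {
      rows <- res_of == res_ids[m]
      per_frame_ele[k, m] <- sum(ele_pair[rows, , drop = FALSE])
      per_frame_vdw[k, m] <- sum(vdw_pair[rows, , drop = FALSE])
    }
  }
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  data.frame(residue_id = res_ids,
             ele_mean = colMeans(per_frame_ele),
             ele_sd = apply(per_frame_ele, 2, sd0),
             vdw_mean = colMeans(per_frame_vdw),
             vdw_sd = apply(per_frame_vdw, 2, sd0))
}
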