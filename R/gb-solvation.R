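## Generalized-Born implicit solvation, OBC flavor (the igb=2 parameter set:
## alpha 0.8, beta 0.0, gamma 2.909125, intrinsic-radius offset 0.09 A),
## with a SASA-proportional nonpolar term from Shrake-Rupley quadrature.
## Species energies for the single-trajectory protocol are evaluated at the
## complex-frame geometry.

## HCT descreening scales by element (AMBER conventions); fallback 0.8
GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, F = 0.88,
               P = 0.86, S = 0.96)

element_from_name <- function(name) {
  lead <- sub("^[0-9]*", "", name)
  two <- toupper(substr(lead, 1, 2))
  one <- toupper(substr(lead, 1, 1))
  ifelse(two %in% c("CL", "BR"), two, one)
}

screen_factors <- function(atoms) {
  if (!is.null(atoms$gb_screen) && !all(is.na(atoms$gb_screen))) {
    s <- atoms$gb_screen
    s[is.na(s)] <- 0.8
    return(s)
  }
  s <- GB_SCREEN[element_from_name(atoms$name)]
  s[is.na(s)] <- 0.8
  unname(s)
}

#' Effective Born radii (HCT descreening with OBC rescaling)
#'
#' Pairwise-descreening integrals over scaled neighbor spheres, rescaled by
#' tanh(alpha psi - beta psi^2 + gamma psi^3) as in the igb=2 model. An
#' isolated atom's effective radius is its intrinsic radius minus the 0.09 A
#' offset.
#'
#' @param system a [molecular_system()] with gb_radius set for all atoms.
#' @param frame n_atoms x 3 coordinate matrix, Angstrom.
#' @param gb list of OBC parameters `alpha`, `beta`, `gamma`, `offset`
#'   (defaults are the igb=2 set, see [bindmode_config()]).
#' @return numeric vector of per-atom effective Born radii, Angstrom.
#' @export
born_radii <- function(system, frame, gb = bindmode_config()$gb) {
  at <- system$atoms
  rho <- at$gb_radius
  if (anyNA(rho)) stop("gb_radius unset; attach a PQR first")
  if (any(rho - gb$offset <= 0))
    stop("intrinsic radius minus offset must be positive; offending serials: ",
         paste(at$serial[rho - gb$offset <= 0], collapse = ", "))
  n <- nrow(at)
  rho_t <- rho - gb$offset                 # offset-reduced intrinsic radii
  if (n == 1) return(rho_t)
  s <- screen_factors(at)
  D <- cross_dist(frame, frame)
  diag(D) <- Inf
  term <- descreen_matrix(rho_t, s, D)
  radii_from_descreen(rowSums(term), rho, rho_t, gb, at$serial)
}

## HCT pairwise-descreening integral contributions; term[i, j] is atom j's
## contribution to atom i's integral (depends only on D[i, j], the scaled
## neighbor radius s_j rho_t_j, and rho_t_i, so submatrices are valid for
## single-species subsystems at the same geometry)
descreen_matrix <- function(rho_t, s, D) {
  n <- length(rho_t)
  SR <- matrix(s * rho_t, n, n, byrow = TRUE)  # scaled neighbor radius, by column j
  RHO <- matrix(rho_t, n, n)                   # descreened atom radius, by row i
  active <- D + SR > RHO                       # neighbor sphere not buried
  L <- pmax(abs(D - SR), RHO)
  U <- D + SR
  engulf <- SR > D + RHO                       # atom i inside scaled sphere j
  term <- 0.5 * (1 / L - 1 / U +
                 0.25 * (D - SR^2 / D) * (1 / U^2 - 1 / L^2) +
                 0.5 * log(L / U) / D +
                 ifelse(engulf, 2 * (1 / RHO - 1 / L), 0))
  term[!active] <- 0
  diag(term) <- 0      # no self-descreening
  term
}

radii_from_descreen <- function(I, rho, rho_t, gb, serials) {
  psi <- I * rho_t
  inv_R <- 1 / rho_t - tanh(gb$alpha * psi - gb$beta * psi^2 + gb$gamma * psi^3) / rho
  R <- 1 / inv_R
  if (any(!is.finite(R) | R <= 0))
    stop("nonpositive effective Born radius; offending serials: ",
         paste(serials[!is.finite(R) | R <= 0], collapse = ", "))
  R
}

#' Generalized-Born polar solvation energy of one frame
#'
#' Still-style pair sum -(k_e/2)(1/eps_in - exp(-kappa f)/eps_out)
#' sum_ij q_i q_j / f_GB with f_GB = sqrt(r^2 + Ri Rj exp(-r^2/(4 Ri Rj)));
#' the diagonal (i = j, f = Ri) supplies the Born self terms.
#'
#' @inheritParams born_radii
#' @param eps_in,eps_out interior/solvent dielectric constants (eps_out > eps_in > 0).
#' @param kappa Debye screening constant, 1/Angstrom (0 = no salt).
#' @param radii optional precomputed effective Born radii.
#' @return energy in kcal/mol.
#' @export
gb_polar_energy <- function(system, frame, eps_in = 2, eps_out = 78.5,
                            kappa = 0, gb = bindmode_config()$gb, radii = NULL) {
  stopifnot(eps_out >= eps_in, eps_in > 0)
  q <- system$atoms$charge
  if (anyNA(q)) stop("charges unset; attach a PQR first")
  if (is.null(radii)) radii <- born_radii(system, frame, gb)
  D <- cross_dist(frame, frame)
  RR <- outer(radii, radii)
  f <- sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
  pref <- if (kappa > 0) (1 / eps_in - exp(-kappa * f) / eps_out)
          else (1 / eps_in - 1 / eps_out)
  -0.5 * COULOMB_KE * sum(pref * outer(q, q) / f)
}

## deterministic near-uniform unit-sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point quadrature on each atom's solvent-expanded sphere
#' (radius + probe); a point is accessible when outside every other atom's
#' expanded sphere. Neighbor lists keep the cost near-linear for compact
#' systems.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param radii per-atom radii, Angstrom.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param points sphere points per atom (default 960).
#' @return numeric vector of per-atom accessible areas, Angstrom^2.
#' @export
shrake_rupley <- function(coords, radii, probe = 1.4, points = 960) {
  stopifnot(nrow(coords) == length(radii), probe >= 0, points >= 1)
  n <- nrow(coords)
  ext <- radii + probe
  pts <- sphere_points(points)
  areas <- numeric(n)
  D <- cross_dist(coords, coords)
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] < ext[i] + ext & seq_len(n) != i)
    if (!length(nbr)) { areas[i] <- 4 * pi * ext[i]^2; next }
    ## for surface point p = c_i + ext_i u: |p - c_j|^2 =
    ## D_ij^2 + ext_i^2 + 2 ext_i u.(c_i - c_j), so burial by sphere j is a
    ## per-column threshold on the projections u.(c_i - c_j)
    diffs <- t(coords[i, ] - t(coords[nbr, , drop = FALSE]))
    proj <- pts %*% t(diffs)
    thr <- (ext[nbr]^2 - D[i, nbr]^2 - ext[i]^2) / (2 * ext[i])
    exposed <- rowSums(proj < rep(thr, each = points)) == 0
    areas[i] <- 4 * pi * ext[i]^2 * sum(exposed) / points
  }
  areas
}

#' Nonpolar (cavity/dispersion) solvation term
#'
#' gamma * SASA + b, with SASA from [shrake_rupley()] over the atoms'
#' intrinsic (PQR) radii.
#'
#' @inheritParams born_radii
#' @param gamma surface tension, kcal/mol/Angstrom^2 (default 0.0072).
#' @param beta_const additive constant b, kcal/mol (default 0).
#' @param probe probe radius, Angstrom.
#' @param points Shrake-Rupley sphere points.
#' @return energy in kcal/mol.
#' @export
sasa_nonpolar <- function(system, frame, gamma = 0.0072, beta_const = 0,
                          probe = 1.4, points = 960) {
  stopifnot(gamma >= 0, probe >= 0)
  if (gamma == 0) return(beta_const)
  radii <- system$atoms$gb_radius
  if (anyNA(radii)) stop("radii unset; attach a PQR first")
  gamma * sum(shrake_rupley(frame, radii, probe, points)) + beta_const
}

#' Total solvation free energy of one species at one frame
#'
#' @inheritParams gb_polar_energy
#' @param config full configuration list, see [bindmode_config()].
#' @return list with `g_polar`, `g_nonpolar`, `g_solv`, `born_radii`.
#' @export
solvation_energy <- function(system, frame, config = bindmode_config()) {
  radii <- born_radii(system, frame, config$gb)
  g_pol <- gb_polar_energy(system, frame, config$eps_in, config$eps_out,
                           config$kappa, config$gb, radii = radii)
  g_np <- sasa_nonpolar(system, frame, config$sasa$gamma, config$sasa$beta_const,
                        config$sasa$probe, config$sasa$points)
  list(g_polar = g_pol, g_nonpolar = g_np, g_solv = g_pol + g_np,
       born_radii = radii)
}

## single-species subsystem at the rows `idx` of the complex atom table
subsystem <- function(system, idx) {
  at <- system$atoms[idx, , drop = FALSE]
  class(at) <- c("atom_table", "data.frame")
  molecular_system(at, ligand_serials = integer(0),
                   receptor_serials = at$serial, allow_empty_ligand = TRUE)
}

#' Per-frame solvation contribution to binding (single-trajectory protocol)
#'
#' dG_solv(frame) = G_solv(complex) - G_solv(receptor) - G_solv(ligand),
#' every species evaluated at the complex-frame geometry. Because the three
#' species share that geometry, the descreening integrals and the SASA
#' point-burial distances are computed once per frame and subset per
#' species.
#'
#' @param ensemble a [snapshot_ensemble()] with charges/radii attached.
#' @param config configuration list, see [bindmode_config()].
#' @return data.frame with columns frame, dg_polar, dg_nonpolar, dg_solv.
#' @export
delta_g_solv <- function(ensemble, config = bindmode_config()) {
  sys <- ensemble$system
  ri <- receptor_idx(sys); li <- ligand_idx(sys)
  if (!length(li)) stop("ligand mask is empty")
  at <- sys$atoms
  rho <- at$gb_radius
  if (anyNA(rho)) stop("gb_radius unset; attach a PQR first")
  if (any(rho - config$gb$offset <= 0))
    stop("intrinsic radius minus offset must be positive; offending serials: ",
         paste(at$serial[rho - config$gb$offset <= 0], collapse = ", "))
  rho_t <- rho - config$gb$offset
  s <- screen_factors(at)
  q <- at$charge
  if (anyNA(q)) stop("charges unset; attach a PQR first")
  species <- list(complex = seq_len(nrow(at)), receptor = ri, ligand = li)

  polar_of <- function(idx, D_inf, D0, term) {
    I <- rowSums(term[idx, idx, drop = FALSE])
    R <- radii_from_descreen(I, rho[idx], rho_t[idx], config$gb, at$serial[idx])
    Ds <- D0[idx, idx, drop = FALSE]
    RR <- outer(R, R)
    f <- sqrt(Ds^2 + RR * exp(-Ds^2 / (4 * RR)))
    pref <- if (config$kappa > 0)
      (1 / config$eps_in - exp(-config$kappa * f) / config$eps_out)
    else (1 / config$eps_in - 1 / config$eps_out)
    -0.5 * COULOMB_KE * sum(pref * outer(q[idx], q[idx]) / f)
  }

  per_frame <- vapply(seq_len(n_frames(ensemble)), function(k) {
    fr <- ensemble$frames[[k]]
    D0 <- cross_dist(fr, fr)
    D_inf <- D0; diag(D_inf) <- Inf
    term <- descreen_matrix(rho_t, s, D_inf)
    pol <- vapply(species, polar_of, 0, D_inf = D_inf, D0 = D0, term = term)
    np <- if (config$sasa$gamma == 0) c(complex = 0, receptor = 0, ligand = 0) else {
      sas <- sasa_by_species(fr, rho, config$sasa$probe, config$sasa$points,
                             species, D0)
      config$sasa$gamma * sas + config$sasa$beta_const
    }
    c(pol[["complex"]] - pol[["receptor"]] - pol[["ligand"]],
      np[["complex"]] - np[["receptor"]] - np[["ligand"]])
  }, numeric(2))
  data.frame(frame = seq_len(n_frames(ensemble)),
             dg_polar = per_frame[1, ],
             dg_nonpolar = per_frame[2, ],
             dg_solv = per_frame[1, ] + per_frame[2, ])
}

## total SASA of each species at a shared geometry, reusing each atom's
## surface-point/neighbor distances across the species containing it
sasa_by_species <- function(coords, radii, probe, points, species, D = NULL) {
  n <- nrow(coords)
  if (is.null(D)) D <- cross_dist(coords, coords)
  ext <- radii + probe
  pts <- sphere_points(points)
  member <- lapply(species, function(idx) {
    m <- rep(FALSE, n); m[idx] <- TRUE; m
  })
  totals <- setNames(numeric(length(species)), names(species))
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] < ext[i] + ext & seq_len(n) != i)
    full <- 4 * pi * ext[i]^2
    if (!length(nbr)) {
      for (sp in names(species)) if (member[[sp]][i]) totals[sp] <- totals[sp] + full
      next
    }
    diffs <- t(coords[i, ] - t(coords[nbr, , drop = FALSE]))
    proj <- pts %*% t(diffs)
    thr <- (ext[nbr]^2 - D[i, nbr]^2 - ext[i]^2) / (2 * ext[i])
    inside <- proj < rep(thr, each = points)
    for (sp in names(species)) {
      if (!member[[sp]][i]) next
      cols <- member[[sp]][nbr]
      exposed <- if (any(cols))
        rowSums(inside[, cols, drop = FALSE]) == 0 else rep(TRUE, points)
      totals[sp] <- totals[sp] + full * sum(exposed) / points
    }
  }
  totals
}
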