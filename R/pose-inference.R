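## Binding-mode inference: per-pose MM-GBSA estimates (interaction energy +
## GB solvation + interaction entropy), assembled into a report that ranks
## pose hypotheses per ligand by binding free energy. Identities enforced on
## every estimate: e_int = e_ele + e_vdw, dH = e_int + dG_solv,
## dG = dH - TdS, with TdS <= 0 as the interaction-entropy term is
## nonnegative as -TdS.

#' Binding estimate from component energies (combination step)
#'
#' Combines mean interaction-energy components, solvation and the signed
#' entropy term into dH = E_int + dG_solv and dG = dH - TdS. This is the
#' arithmetic applied to every (ligand, pose) record, whether the components
#' come from ensembles or from a published table.
#'
#' @param ligand_label,pose_label free-text labels (e.g. "Po", "BA-like").
#' @param e_ele,e_vdw mean electrostatic / van der Waals interaction
#'   energies, kcal/mol.
#' @param g_solv mean solvation contribution, kcal/mol.
#' @param t_delta_s signed entropy term TdS, kcal/mol (<= 0; equal to minus
#'   the interaction-entropy estimate -TdS).
#' @param delta_g_sd spread of dG across replicas, kcal/mol (NA when single).
#' @return object of class `binding_estimate`.
#' @export
binding_estimate <- function(ligand_label, pose_label, e_ele, e_vdw, g_solv,
                             t_delta_s, delta_g_sd = NA_real_) {
  if (t_delta_s > 1e-9)
    stop("t_delta_s must be <= 0 (the interaction-entropy term -TdS is nonnegative)")
  e_int <- e_ele + e_vdw
  delta_h <- e_int + g_solv
  delta_g <- delta_h - t_delta_s
  structure(list(ligand_label = ligand_label, pose_label = pose_label,
                 e_ele = e_ele, e_vdw = e_vdw, e_int_mean = e_int,
                 g_solv_mean = g_solv, delta_h = delta_h,
                 t_delta_s = t_delta_s, delta_g = delta_g,
                 delta_g_sd = delta_g_sd),
            class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  cat(sprintf(paste0("<binding_estimate> %s / %s: E_int %.1f (%.1f, %.1f), ",
                     "dG_solv %.1f, dH %.1f, TdS %.1f, dG %.1f%s kcal/mol\n"),
              x$ligand_label, x$pose_label, x$e_int_mean, x$e_ele, x$e_vdw,
              x$g_solv_mean, x$delta_h, x$t_delta_s, x$delta_g,
              if (is.na(x$delta_g_sd)) "" else sprintf(" +/- %.1f", x$delta_g_sd)))
  invisible(x)
}

#' MM-GBSA binding estimate from snapshot-ensemble replicas
#'
#' For each replica: per-frame interaction energies and solvation terms are
#' averaged into dH; the interaction entropy of the per-frame E_int samples
#' gives -TdS; dG = dH - TdS. Replicas are aggregated as mean +/- SD on
#' every column (the SD on dG is the conventional one to quote).
#'
#' @param replicas a [snapshot_ensemble()] or list of them (>= 2 frames each).
#' @param config configuration list, see [bindmode_config()].
#' @param ligand_label,pose_label labels carried into the estimate.
#' @return a [binding_estimate()] with extra fields `replica_table`
#'   (per-replica components) and `entropy` (per-replica estimates).
#' @export
mmgbsa_estimate <- function(replicas, config = bindmode_config(),
                            ligand_label = "ligand", pose_label = "pose") {
  if (inherits(replicas, "snapshot_ensemble")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1)
  counts <- vapply(replicas, n_frames, 0L)
  if (any(counts < 2)) stop("each replica needs at least 2 frames")
  if (length(unique(counts)) > 1)
    warning("replica frame counts differ: ", paste(counts, collapse = ", "))
  ent <- vector("list", length(replicas))
  rows <- lapply(seq_along(replicas), function(i) {
    ens <- replicas[[i]]
    ei <- ensemble_interactions(ens, config$eps_in)
    solv <- delta_g_solv(ens, config)
    ent[[i]] <<- interaction_entropy(ei$e_int, config$temperature)
    tds <- -ent[[i]]$minus_t_delta_s
    dh <- mean(ei$e_int + solv$dg_solv)
    data.frame(replica = i, n_frames = counts[i],
               e_ele = mean(ei$e_ele), e_vdw = mean(ei$e_vdw),
               e_int = mean(ei$e_int), g_solv = mean(solv$dg_solv),
               delta_h = dh, t_delta_s = tds, delta_g = dh - tds)
  })
  tab <- do.call(rbind, rows)
  est <- binding_estimate(ligand_label, pose_label,
                          e_ele = mean(tab$e_ele), e_vdw = mean(tab$e_vdw),
                          g_solv = mean(tab$g_solv),
                          t_delta_s = mean(tab$t_delta_s),
                          delta_g_sd = if (nrow(tab) > 1) sd(tab$delta_g) else NA_real_)
  est$replica_table <- tab
  est$entropy <- ent
  est
}

#' Rank pose hypotheses of one ligand by binding free energy
#'
#' The preferred pose has the lowest dG; the margin is the gap to the
#' second-best. Ties (dG equal within 1e-6 kcal/mol) are broken toward the
#' lower replica SD, then lexicographic pose label, and flagged.
#'
#' @param estimates list of [binding_estimate()]s for the same ligand (>= 2).
#' @return object of class `pose_comparison`: `estimates`, `preferred_pose`,
#'   `margin` (kcal/mol), `tie` flag, `ranking` (data.frame).
#' @export
compare_poses <- function(estimates) {
  if (inherits(estimates, "binding_estimate")) estimates <- list(estimates)
  if (length(estimates) < 2) stop("need at least 2 pose estimates to compare")
  ligs <- unique(vapply(estimates, `[[`, "", "ligand_label"))
  if (length(ligs) > 1)
    stop("mixed ligand labels in pose comparison: ", paste(ligs, collapse = ", "))
  tab <- do.call(rbind, lapply(estimates, function(e)
    data.frame(pose = e$pose_label, delta_g = e$delta_g,
               delta_g_sd = ifelse(is.na(e$delta_g_sd), Inf, e$delta_g_sd))))
  ord <- order(tab$delta_g, tab$delta_g_sd, tab$pose)
  tab <- tab[ord, ]
  tie <- abs(tab$delta_g[1] - tab$delta_g[2]) <= 1e-6
  structure(list(estimates = estimates[ord],
                 preferred_pose = tab$pose[1],
                 margin = tab$delta_g[2] - tab$delta_g[1],
                 tie = tie,
                 ranking = data.frame(pose = tab$pose, delta_g = tab$delta_g)),
            class = "pose_comparison")
}

#' @export
print.pose_comparison <- function(x, ...) {
  cat(sprintf("<pose_comparison> preferred: %s (margin %.2f kcal/mol%s)\n",
              x$preferred_pose, x$margin, if (x$tie) ", TIE" else ""))
  invisible(x)
}

#' Run the full binding-mode analysis pipeline from a configuration
#'
#' The configuration (a list, or a path to a JSON file) must name, per
#' entry of `ensembles`: `ligand`, `pose`, `pdb` (one or more multi-MODEL
#' PDB paths, one per replica), `pqr` and `sidecar`; `ligand_resname` names
#' the ligand residue. Stages: read -> interaction energies -> solvation ->
#' entropy -> structural metrics -> per-residue decomposition -> pose
#' comparison. Any stage error aborts with the stage name; every default in
#' force is echoed to the log.
#'
#' @param config list or JSON path.
#' @param out_dir optional output directory for the CSV/JSON report bundle.
#' @return list with `estimates`, `comparisons` (per ligand), `metrics`,
#'   `decomposition`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  for (key in c("ensembles"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  base <- bindmode_config()
  for (k in setdiff(names(base), names(config))) config[[k]] <- base[[k]]
  message("pipeline defaults in force: eps_in=", config$eps_in,
          ", eps_out=", config$eps_out, ", T=", config$temperature,
          ", ligand_resname=", config$ligand_resname)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  estimates <- list(); metrics <- list(); decomposition <- list()
  for (entry in config$ensembles) {
    for (key in c("ligand", "pose"))
      if (is.null(entry[[key]])) stop("config ensemble entry missing key: ", key)
    label <- paste(entry$ligand, entry$pose, sep = "/")
    replicas <- if (!is.null(entry$replicas)) entry$replicas else
      stage(paste0("read:", label), {
        if (is.null(entry$pdb)) stop("missing key: pdb")
        lapply(unlist(entry$pdb), function(p) {
          ens <- read_pdb_ensemble(p, config$ligand_resname)
          sys <- read_pqr_parameters(entry$pqr, ens$system, entry$sidecar)
          snapshot_ensemble(sys, ens$frames)
        })
      })
    est <- stage(paste0("mmgbsa:", label),
                 mmgbsa_estimate(replicas, config, entry$ligand, entry$pose))
    estimates[[label]] <- est
    metrics[[label]] <- stage(paste0("metrics:", label), {
      ens <- replicas[[1]]
      bb <- select_backbone(ens)
      if (length(bb) < 3) bb <- receptor_idx(ens$system)
      rmsf <- rmsf_per_residue(ens, bb)
      list(rmsd_fit = rmsd_series(ens, bb, label = "fit-selection"),
           rmsd_ligand = rmsd_series(ens, bb, select_ligand(ens), label = "ligand"),
           rmsf = rmsf,
           regions = region_report(rmsf, config$metrics$regions),
           sasa = ensemble_sasa(ens, config$sasa$probe, config$sasa$points))
    })
    decomposition[[label]] <- stage(paste0("decomposition:", label),
      per_residue_decomposition(replicas[[1]]$system, replicas[[1]], config$eps_in))
  }
  comparisons <- list()
  for (lig in unique(vapply(config$ensembles, `[[`, "", "ligand"))) {
    of_lig <- Filter(function(e) e$ligand_label == lig, estimates)
    if (length(of_lig) >= 2)
      comparisons[[lig]] <- stage(paste0("compare:", lig), compare_poses(of_lig))
  }
  report <- list(estimates = estimates, comparisons = comparisons,
                 metrics = metrics, decomposition = decomposition,
                 config = config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## CSV/JSON report bundle with fixed column layouts
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  est_tab <- do.call(rbind, lapply(report$estimates, function(e)
    data.frame(ligand = e$ligand_label, pose = e$pose_label,
               e_ele = e$e_ele, e_vdw = e$e_vdw, e_int = e$e_int_mean,
               g_solv = e$g_solv_mean, delta_h = e$delta_h,
               t_delta_s = e$t_delta_s, delta_g = e$delta_g,
               delta_g_sd = e$delta_g_sd)))
  write.csv(est_tab, file.path(out_dir, "binding_estimates.csv"), row.names = FALSE)
  for (label in names(report$decomposition)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", label)
    write.csv(report$decomposition[[label]],
              file.path(out_dir, paste0("decomposition_", safe, ".csv")),
              row.names = FALSE)
  }
  comp <- lapply(report$comparisons, function(cp)
    list(preferred_pose = cp$preferred_pose, margin = cp$margin, tie = cp$tie,
         ranking = cp$ranking))
  jsonlite::write_json(comp, file.path(out_dir, "pose_comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
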