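## Structural stability analytics over snapshot ensembles: Kabsch (SVD)
## superposition, RMSD series for arbitrary fit/measure selections,
## per-residue RMSF about the mean structure, and per-frame complex SASA.
## Selections are integer row-index vectors into the system's atom table.

#' Atom selections for trajectory metrics
#'
#' `select_backbone` returns atoms named N, CA, C, O; `select_ligand` the
#' ligand-mask atoms; `select_binding_site` all atoms of receptor residues
#' having any atom within `radius` Angstrom of the ligand in the reference
#' frame.
#'
#' @param ensemble a [snapshot_ensemble()].
#' @param radius binding-site cutoff, Angstrom (default 5).
#' @param reference reference frame index (default 1).
#' @return integer vector of atom-table row indices.
#' @export
select_backbone <- function(ensemble) {
  which(ensemble$system$atoms$name %in% c("N", "CA", "C", "O"))
}

#' @rdname select_backbone
#' @export
select_ligand <- function(ensemble) ligand_idx(ensemble$system)

#' @rdname select_backbone
#' @export
select_binding_site <- function(ensemble, radius = 5, reference = 1L) {
  sys <- ensemble$system
  fr <- ensemble$frames[[reference]]
  ri <- receptor_idx(sys); li <- ligand_idx(sys)
  if (!length(li)) stop("ligand mask is empty")
  d <- cross_dist(fr[ri, , drop = FALSE], fr[li, , drop = FALSE])
  near_res <- unique(sys$atoms$residue_id[ri][apply(d, 1, min) <= radius])
  which(sys$atoms$residue_id %in% near_res & sys$atoms$serial %in% sys$receptor_serials)
}

#' Kabsch superposition of one frame onto a reference
#'
#' Least-squares rigid-body fit (SVD; proper rotation, det = +1) of
#' `mobile_frame` onto `reference_frame` over `fit_selection`; the returned
#' transform is applied to the whole mobile frame.
#'
#' @param mobile_frame,reference_frame n_atoms x 3 coordinate matrices.
#' @param fit_selection integer row indices used for the fit (>= 3,
#'   non-collinear).
#' @return list with `coords` (transformed mobile frame), `rotation` (3 x 3),
#'   `rmsd` (over the fit selection, Angstrom).
#' @export
kabsch_superpose <- function(mobile_frame, reference_frame, fit_selection) {
  if (length(fit_selection) < 3) stop("fit selection needs at least 3 atoms")
  A <- mobile_frame[fit_selection, , drop = FALSE]
  B <- reference_frame[fit_selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2) stop("degenerate (collinear) fit selection")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mobile_frame, 2, ca) %*% t(R), 2, cb, "+")
  dev <- moved[fit_selection, , drop = FALSE] - B
  list(coords = moved, rotation = R, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' RMSD series over an ensemble
#'
#' Each frame is superposed on the reference over `fit_selection`, then RMSD
#' is measured over `measure_selection` (fit on backbone, measure on ligand
#' reproduces the usual ligand-RMSD convention).
#'
#' @param ensemble a [snapshot_ensemble()].
#' @param fit_selection,measure_selection integer atom-row selections
#'   (`measure_selection` defaults to the fit selection).
#' @param reference frame index or an n_atoms x 3 matrix (default frame 1).
#' @param label selection label carried into the result.
#' @return data.frame of class `metric_series` with columns frame, value
#'   (Angstrom); attribute `label`.
#' @export
rmsd_series <- function(ensemble, fit_selection,
                        measure_selection = fit_selection,
                        reference = 1L, label = "rmsd") {
  if (!length(fit_selection) || !length(measure_selection))
    stop("empty selection")
  ref <- if (is.matrix(reference)) reference else ensemble$frames[[reference]]
  vals <- vapply(seq_len(n_frames(ensemble)), function(k) {
    sup <- kabsch_superpose(ensemble$frames[[k]], ref, fit_selection)
    dev <- sup$coords[measure_selection, , drop = FALSE] -
           ref[measure_selection, , drop = FALSE]
    sqrt(mean(rowSums(dev^2)))
  }, 0)
  structure(data.frame(frame = seq_along(vals), value = vals),
            label = label, class = c("metric_series", "data.frame"))
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed on the first frame over `fit_selection`; the RMSF of
#' each atom is its root-mean-square deviation from its time-averaged
#' position, averaged within residues.
#'
#' @inheritParams rmsd_series
#' @return data.frame of class `metric_series` with columns residue_id,
#'   value (Angstrom).
#' @export
rmsf_per_residue <- function(ensemble, fit_selection = select_backbone(ensemble),
                             label = "rmsf") {
  if (n_frames(ensemble) < 2) stop("RMSF needs at least 2 frames")
  ref <- ensemble$frames[[1]]
  fitted <- lapply(ensemble$frames, function(fr)
    kabsch_superpose(fr, ref, fit_selection)$coords)
  arr <- simplify2array(fitted)               # n_atoms x 3 x n_frames
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- apply(sweep(arr, c(1, 2), mean_xyz)^2, c(1, 3), sum)
  atom_rmsf <- sqrt(rowMeans(dev2))
  res <- ensemble$system$atoms$residue_id
  agg <- tapply(atom_rmsf, res, mean)
  structure(data.frame(residue_id = as.integer(names(agg)),
                       value = as.numeric(agg)),
            label = label, class = c("metric_series", "data.frame"))
}

#' Per-frame complex SASA series
#'
#' @param ensemble a [snapshot_ensemble()] with radii attached.
#' @param probe probe radius, Angstrom.
#' @param points Shrake-Rupley sphere points.
#' @return data.frame of class `metric_series` with columns frame, value
#'   (Angstrom^2); attributes `mean` and `sd`.
#' @export
ensemble_sasa <- function(ensemble, probe = 1.4, points = 960) {
  radii <- ensemble$system$atoms$gb_radius
  if (anyNA(radii)) stop("radii unset; attach a PQR first")
  vals <- vapply(ensemble$frames, function(fr)
    sum(shrake_rupley(fr, radii, probe, points)), 0)
  structure(data.frame(frame = seq_along(vals), value = vals),
            label = "sasa", mean = mean(vals),
            sd = if (length(vals) > 1) sd(vals) else 0,
            class = c("metric_series", "data.frame"))
}

#' Region summary of a per-residue RMSF series
#'
#' @param rmsf a series from [rmsf_per_residue()].
#' @param regions list of [region_definition()]s.
#' @return data.frame with columns label, from, to, n_residues, rmsf_mean.
#' @export
region_report <- function(rmsf, regions) {
  do.call(rbind, lapply(regions, function(rg) {
    if (is.list(rg) && !inherits(rg, "region_definition"))
      rg <- region_definition(rg$label, rg$from, rg$to)
    sel <- rmsf$residue_id >= rg$from & rmsf$residue_id <= rg$to
    data.frame(label = rg$label, from = rg$from, to = rg$to,
               n_residues = sum(sel),
               rmsf_mean = if (any(sel)) mean(rmsf$value[sel]) else NA_real_)
  }))
}
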