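#' Atom table constructor
#'
#' Builds the per-atom parameter table used by every energy routine. Charges
#' and Born radii are carried as data (read from PQR + sidecar files); they
#' are never derived here.
#'
#' @param serial integer atom serial numbers (unique).
#' @param name atom names (e.g. "CA").
#' @param residue_id integer residue numbers, as in the input file.
#' @param residue_name residue names (e.g. "ALA", "LIG").
#' @param chain chain identifiers.
#' @param x,y,z reference coordinates, Angstrom.
#' @param charge partial charges, elementary units (NA until a PQR is attached).
#' @param gb_radius intrinsic Born radii, Angstrom (> 0 when set).
#' @param lj_rmin_half Lennard-Jones rmin/2, Angstrom.
#' @param lj_epsilon Lennard-Jones well depth, kcal/mol (>= 0).
#' @return data.frame of class `atom_table`.
#' @export
atom_table <- function(serial, name, residue_id, residue_name, chain = "A",
                       x, y, z, charge = NA_real_, gb_radius = NA_real_,
                       lj_rmin_half = NA_real_, lj_epsilon = NA_real_) {
  at <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    residue_id = as.integer(residue_id), residue_name = as.character(residue_name),
    chain = rep_len(as.character(chain), length(serial)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = rep_len(as.numeric(charge), length(serial)),
    gb_radius = rep_len(as.numeric(gb_radius), length(serial)),
    lj_rmin_half = rep_len(as.numeric(lj_rmin_half), length(serial)),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), length(serial)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(at$serial)) stop("atom serials must be unique")
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    stop("atom positions must be finite")
  bad_r <- which(!is.na(at$gb_radius) & at$gb_radius <= 0)
  if (length(bad_r))
    stop("gb_radius must be > 0; offending serials: ",
         paste(at$serial[bad_r], collapse = ", "))
  bad_e <- which(!is.na(at$lj_epsilon) & at$lj_epsilon < 0)
  if (length(bad_e))
    stop("lj_epsilon must be >= 0; offending serials: ",
         paste(at$serial[bad_e], collapse = ", "))
  class(at) <- c("atom_table", "data.frame")
  at
}

#' Molecular system: atoms plus a receptor/ligand partition
#'
#' The partition is stored as serial-number sets. Masks must be disjoint and
#' jointly cover all atoms; an empty ligand mask is only permitted for
#' solvation-only single-species calls (`allow_empty_ligand = TRUE`).
#'
#' @param atoms an [atom_table()].
#' @param ligand_serials integer serials of the ligand atoms.
#' @param receptor_serials integer serials of the receptor atoms; defaults to
#'   the complement of `ligand_serials`.
#' @param allow_empty_ligand allow an empty ligand mask (single-species system).
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, ligand_serials,
                             receptor_serials = setdiff(atoms$serial, ligand_serials),
                             allow_empty_ligand = FALSE) {
  stopifnot(inherits(atoms, "atom_table"))
  ligand_serials <- as.integer(ligand_serials)
  receptor_serials <- as.integer(receptor_serials)
  if (length(intersect(ligand_serials, receptor_serials)))
    stop("ligand and receptor masks must be disjoint")
  covered <- sort(c(ligand_serials, receptor_serials))
  if (!identical(covered, sort(atoms$serial)))
    stop("masks must jointly cover all atoms exactly once")
  if (!length(receptor_serials)) stop("receptor mask must contain at least one atom")
  if (!length(ligand_serials) && !allow_empty_ligand)
    stop("ligand mask is empty; pass allow_empty_ligand = TRUE for single-species systems")
  structure(list(atoms = atoms,
                 ligand_serials = sort(ligand_serials),
                 receptor_serials = sort(receptor_serials)),
            class = "molecular_system")
}

## row indices (into the atom table) of each mask
ligand_idx <- function(system) match(system$ligand_serials, system$atoms$serial)
receptor_idx <- function(system) match(system$receptor_serials, system$atoms$serial)

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d atoms (%d receptor, %d ligand), %d residues\n",
              nrow(x$atoms), length(x$receptor_serials), length(x$ligand_serials),
              length(unique(x$atoms$residue_id))))
  invisible(x)
}

#' Snapshot ensemble: ordered coordinate frames over a fixed system
#'
#' @param system a [molecular_system()].
#' @param frames list of n_atoms x 3 coordinate matrices, Angstrom; atom order
#'   follows the system's atom table in every frame.
#' @param frame_labels optional numeric labels (e.g. times in ns).
#' @return object of class `snapshot_ensemble`.
#' @export
snapshot_ensemble <- function(system, frames, frame_labels = NULL) {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.list(frames) || !length(frames)) stop("need at least one frame")
  n_atoms <- nrow(system$atoms)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3 || nrow(fr) != n_atoms)
      stop(sprintf("frame %d must be a %d x 3 coordinate matrix", k, n_atoms))
    if (!all(is.finite(fr))) stop(sprintf("frame %d has non-finite coordinates", k))
  }
  if (!is.null(frame_labels) && length(frame_labels) != length(frames))
    stop("frame_labels length must match the number of frames")
  structure(list(system = system, frames = frames, frame_labels = frame_labels),
            class = "snapshot_ensemble")
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble> %d frames x %d atoms\n",
              length(x$frames), nrow(x$system$atoms)))
  invisible(x)
}

n_frames <- function(ensemble) length(ensemble$frames)

#' Region definition for per-region trajectory reports
#'
#' @param label region label, e.g. "H12".
#' @param from,to inclusive residue-number interval (input-file numbering).
#' @return object of class `region_definition`.
#' @export
region_definition <- function(label, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (to < from) stop("empty residue range: to < from")
  structure(list(label = as.character(label), from = from, to = to),
            class = "region_definition")
}
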