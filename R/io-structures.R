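## Structure file I/O: multi-MODEL PDB ensembles, PQR charge/radius transport,
## and the JSON topology sidecar carrying Lennard-Jones parameters (PQR has no
## LJ columns). Sidecar schema (frozen):
##   { "atoms": { "<serial>": { "rmin_half": <Angstrom>,
##                              "epsilon":   <kcal/mol>,
##                              "screen":    <GB descreening scale, optional> } } }

#' Read a multi-MODEL PDB file as a snapshot ensemble
#'
#' Frames are the MODEL blocks in file order (a file without MODEL records is
#' a one-frame ensemble). The ligand is identified by residue name; all other
#' atoms form the receptor. Atom order must be identical across models.
#'
#' @param path PDB file path.
#' @param ligand_resname residue name of the ligand (default "LIG").
#' @return a [snapshot_ensemble()] (charges/LJ parameters unset until a PQR
#'   and sidecar are attached with [read_pqr_parameters()]).
#' @export
read_pdb_ensemble <- function(path, ligand_resname = "LIG") {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ## validate per-model atom counts before parsing
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) > 1) {
      ref <- counts[1]
      bad <- which(counts != ref)[1]
      stop(sprintf("atom-count mismatch: model %d has %d atoms, model 1 has %d",
                   bad, counts[bad], ref))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- atom_table(serial = at$eleno, name = at$elety,
                      residue_id = at$resno, residue_name = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      x = at$x, y = at$y, z = at$z)
  lig <- atoms$serial[atoms$residue_name == ligand_resname]
  if (!length(lig))
    stop(sprintf("unknown ligand residue name '%s': not present in %s",
                 ligand_resname, path))
  system <- molecular_system(atoms, ligand_serials = lig)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3, byrow = TRUE))
  snapshot_ensemble(system, frames)
}

#' Write a snapshot ensemble as a multi-MODEL PDB file
#'
#' Fixed-column PDB ATOM records at the format's native 3-decimal coordinate
#' precision; one MODEL block per frame.
#'
#' @param ensemble a [snapshot_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  at <- ensemble$system$atoms
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name), at$name)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       at$serial, name4, at$residue_name, at$chain, at$residue_id,
                       fr[, 1], fr[, 2], fr[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Attach PQR charges/radii and sidecar LJ parameters to a system
#'
#' PQR atom lines supply the partial charge and intrinsic Born radius,
#' matched to the system by (serial, atom name). Lennard-Jones parameters
#' (and optional GB descreening scales) come from a JSON sidecar keyed by
#' atom serial; see the schema at the top of this file's source.
#'
#' @param path PQR file path.
#' @param system a [molecular_system()].
#' @param sidecar_path JSON sidecar path; `NULL` skips LJ attachment.
#' @return the system with charge, gb_radius, lj_rmin_half, lj_epsilon (and
#'   gb_screen, if provided) filled in.
#' @export
read_pqr_parameters <- function(path, system, sidecar_path = NULL) {
  pqr <- bio3d::read.pqr(path)
  at <- system$atoms
  key_sys <- paste(at$serial, at$name)
  key_pqr <- paste(pqr$atom$eleno, pqr$atom$elety)
  hit <- match(key_sys, key_pqr)
  if (anyNA(hit))
    stop("unmatched atoms in PQR (serial name): ",
         paste(key_sys[is.na(hit)], collapse = ", "))
  at$charge <- pqr$atom$o[hit]      # bio3d maps the PQR charge column to o
  at$gb_radius <- pqr$atom$b[hit]   # and the radius column to b
  if (any(at$gb_radius <= 0))
    stop("gb_radius must be > 0; offending serials: ",
         paste(at$serial[at$gb_radius <= 0], collapse = ", "))
  at <- atom_table(at$serial, at$name, at$residue_id, at$residue_name, at$chain,
                   at$x, at$y, at$z, at$charge, at$gb_radius,
                   at$lj_rmin_half, at$lj_epsilon)
  if (!is.null(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path)
    entries <- side$atoms
    missing <- setdiff(as.character(at$serial), names(entries))
    if (length(missing))
      stop("sidecar missing LJ entries for serials: ",
           paste(missing, collapse = ", "))
    idx <- as.character(at$serial)
    at$lj_rmin_half <- vapply(entries[idx], function(e) as.numeric(e$rmin_half), 0)
    at$lj_epsilon <- vapply(entries[idx], function(e) as.numeric(e$epsilon), 0)
    screens <- vapply(entries[idx], function(e)
      if (is.null(e$screen)) NA_real_ else as.numeric(e$screen), 0)
    if (!all(is.na(screens))) at$gb_screen <- screens
    if (any(at$lj_epsilon < 0))
      stop("lj_epsilon must be >= 0; offending serials: ",
           paste(at$serial[at$lj_epsilon < 0], collapse = ", "))
  }
  molecular_system(at, system$ligand_serials, system$receptor_serials,
                   allow_empty_ligand = !length(system$ligand_serials))
}

#' Write a PQR file from a parameterized system
#'
#' @param system a [molecular_system()] with charges and radii set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(system, path) {
  at <- system$atoms
  if (anyNA(at$charge) || anyNA(at$gb_radius))
    stop("system has unset charges or radii")
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name), at$name)
  lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                   at$serial, name4, at$residue_name, at$chain, at$residue_id,
                   at$x, at$y, at$z, at$charge, at$gb_radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the JSON topology sidecar for a system
#'
#' @param system a [molecular_system()] with LJ parameters set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lj_sidecar <- function(system, path) {
  at <- system$atoms
  entries <- lapply(seq_len(nrow(at)), function(i) {
    e <- list(rmin_half = at$lj_rmin_half[i], epsilon = at$lj_epsilon[i])
    if (!is.null(at$gb_screen)) e$screen <- at$gb_screen[i]
    e
  })
  names(entries) <- as.character(at$serial)
  jsonlite::write_json(list(atoms = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
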