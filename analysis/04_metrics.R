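#!/usr/bin/env Rscript
## Structural stability metrics over the simulated ensembles: RMSD series
## (whole receptor fit; guest measured after receptor fit), per-residue RMSF
## with region means, and per-frame complex SASA, pose A vs pose B.

suppressMessages(library(bindmode))

sim <- "results/simulated"
dir.create("results/metrics", showWarnings = FALSE, recursive = TRUE)

for (pose in c("a", "b")) {
  ens <- read_pdb_ensemble(file.path(sim, sprintf("pose_%s.pdb", pose)), "LIG")
  sys <- read_pqr_parameters(file.path(sim, "system.pqr"), ens$system,
                             file.path(sim, "system_lj.json"))
  ens <- snapshot_ensemble(sys, ens$frames)
  rec <- which(sys$atoms$residue_name != "LIG")
  rmsd_rec <- rmsd_series(ens, rec, label = "receptor")
  rmsd_lig <- rmsd_series(ens, rec, select_ligand(ens), label = "guest")
  rmsf <- rmsf_per_residue(ens, rec)
  regions <- region_report(rmsf, list(
    region_definition("charged pocket (res 4)", 4, 4),
    region_definition("far side (res 1-2)", 1, 2)))
  sasa <- ensemble_sasa(ens)
  write.csv(data.frame(frame = rmsd_rec$frame, rmsd_receptor = rmsd_rec$value,
                       rmsd_guest = rmsd_lig$value, sasa = sasa$value),
            sprintf("results/metrics/series_pose_%s.csv", pose), row.names = FALSE)
  write.csv(rmsf, sprintf("results/metrics/rmsf_pose_%s.csv", pose),
            row.names = FALSE)
  write.csv(regions, sprintf("results/metrics/regions_pose_%s.csv", pose),
            row.names = FALSE)
  message(sprintf(
    "pose %s: mean receptor RMSD %.3f A, mean guest RMSD %.3f A, SASA %.0f +/- %.0f A^2",
    toupper(pose), mean(rmsd_rec$value), mean(rmsd_lig$value),
    attr(sasa, "mean"), attr(sasa, "sd")))
}
message("series, RMSF and region tables written under results/metrics/")
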