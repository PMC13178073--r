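#!/usr/bin/env Rscript
## TR-FRET pharmacology: 4PL fit of the simulated competitive-binding plate
## (planted IC50 4.98 uM), Cheng-Prusoff conversion with the kit's tracer
## constants, efficacy normalization of the partial coactivator curve
## against the reference agonist, and the ligand-profile decision table
## applied to the pomolic-acid-like and hederagenin-like profiles.

suppressMessages(library(bindmode))

sim <- "results/simulated"
dir.create("results/pharmacology", showWarnings = FALSE, recursive = TRUE)

fit_comp <- fit_plate_csv(file.path(sim, "plate_competitive.csv"))
ic50_uM <- fit_comp$ic50_or_ec50 * 1e6
ki_uM <- cheng_prusoff_ki(ic50_uM, tracer_conc = 5e-9 * 1e6,
                          tracer_kd = 2.8e-9 * 1e6)
message(sprintf("competitive fit: IC50 %.2f uM (planted 4.98), Ki %.2f uM, hill %.2f",
                ic50_uM, ki_uM, fit_comp$hill))

fit_ref <- fit_plate_csv(file.path(sim, "plate_coactivator_reference.csv"))
fit_part <- fit_plate_csv(file.path(sim, "plate_coactivator_partial.csv"))
eff <- normalize_efficacy(fit_part, fit_ref)
message(sprintf("partial coactivator curve: %.1f%% of reference efficacy (planted 19%%)", eff))

## published-value conversions (printed IC50s, kit tracer constants)
ki_po <- cheng_prusoff_ki(4.98, 5, 2.8)
ki_hede <- cheng_prusoff_ki(13.54, 5, 2.8)

profiles <- rbind(
  data.frame(ligand = "pomolic-acid-like", ki_uM = ki_po, coact = 0, corep = 0),
  data.frame(ligand = "hederagenin-like", ki_uM = ki_hede, coact = eff, corep = 0),
  data.frame(ligand = "inverse-agonist control", ki_uM = 0.00064, coact = 0, corep = 100))
profiles$classification <- vapply(seq_len(nrow(profiles)), function(i)
  classify_ligand(profiles$ki_uM[i] * 1e-6, profiles$coact[i],
                  profiles$corep[i])$classification, "")
print(profiles)

write.csv(data.frame(
  quantity = c("fit_ic50_uM", "fit_ki_uM", "partial_efficacy_pct",
               "ki_pomolic_uM", "ki_hederagenin_uM"),
  value = c(ic50_uM, ki_uM, eff, round(ki_po, 2), round(ki_hede, 2))),
  "results/pharmacology/summary.csv", row.names = FALSE)
write.csv(profiles, "results/pharmacology/profiles.csv", row.names = FALSE)
message(sprintf("printed-pair conversions: Ki(Po) %.2f uM, Ki(Hede) %.2f uM",
                round(ki_po, 2), round(ki_hede, 2)))
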