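#!/usr/bin/env Rscript
## Generate every synthetic input the downstream analyses consume:
## - a host-guest complex with two pose hypotheses (A planted deeper than B),
##   written as multi-MODEL PDB + PQR + LJ sidecar;
## - Gaussian interaction-energy streams for the entropy diagnostics;
## - TR-FRET dose-response plates: a competitive-binding curve, a reference
##   full-agonist coactivator curve and a 19%-efficacy partial curve.
## Everything is a pure function of the seeds fixed here.

suppressMessages(library(bindmode))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- host-guest ensembles (60-atom ring receptor, 10-atom guest) --")
hg <- make_host_guest(seed = 101, n_frames = 50, jitter_sigma = 0.08, dir = out)
message(sprintf("wrote pose_a.pdb / pose_b.pdb (%d frames each), system.pqr, system_lj.json",
                length(hg$pose_a$frames)))

message("-- interaction-energy streams --")
for (sigma in c(0.5, 1.0, 3.0)) {
  e <- make_gaussian_energy_traj(sigma, n = 2000, seed = 200 + sigma * 10)
  write.csv(data.frame(sample = seq_along(e), e_int = e),
            sprintf("%s/energies_sigma%.1f.csv", out, sigma), row.names = FALSE)
}
message("wrote energies_sigma{0.5,1.0,3.0}.csv (n = 2000 each)")

message("-- dose-response plates (1 pM - 100 uM, 10 doses x 3 reps) --")
plates <- list(
  competitive = list(bottom = 0.45, top = 1.30, hill = -1.0,
                     log_mid = log10(4.98e-6)),   # descending, IC50 4.98 uM
  coactivator_reference = list(bottom = 0.40, top = 1.40, hill = 1.0,
                               log_mid = log10(5.5e-10)),
  coactivator_partial = list(bottom = 0.40, top = 0.40 + 0.19 * 1.0, hill = 1.0,
                             log_mid = log10(4.49e-6))  # 19% of reference span
)
for (nm in names(plates)) {
  make_dose_response(plates[[nm]], noise_sd = 0.01, n_doses = 10, n_reps = 3,
                     seed = 300 + match(nm, names(plates)),
                     path = sprintf("%s/plate_%s.csv", out, nm))
}
message("wrote plate_{competitive,coactivator_reference,coactivator_partial}.csv")
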