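#!/usr/bin/env Rscript
## Radius-2 circular-fingerprint Tanimoto similarity among the five ligands
## (pomolic acid, hederagenin, caulophyllogenin, betulinic acid,
## rosiglitazone), on the packaged SDF structures. Count-based similarities
## are the headline numbers; the folded 2048-bit variant is written
## alongside.

suppressMessages(library(bindmode))

dir.create("results/similarity", showWarnings = FALSE, recursive = TRUE)
fix <- function(n) system.file("extdata", "ligands", paste0(n, ".sdf"),
                               package = "bindmode")
paths <- c(pomolic_acid = fix("pomolic_acid"),
           hederagenin = fix("hederagenin"),
           caulophyllogenin = fix("caulophyllogenin"),
           betulinic_acid = fix("betulinic_acid"),
           rosiglitazone = fix("rosiglitazone"))

m_counts <- similarity_matrix(paths, radius = 2, on = "counts")
m_bits <- similarity_matrix(paths, radius = 2, n_bits = 2048, on = "bits")
write.csv(round(m_counts, 4), "results/similarity/tanimoto_counts.csv")
write.csv(round(m_bits, 4), "results/similarity/tanimoto_bits2048.csv")

print(round(m_counts, 3))
tri <- c("pomolic_acid", "hederagenin")
ctl <- c("caulophyllogenin", "betulinic_acid")
message(sprintf(
  "triterpenoids vs rosiglitazone: max %.3f (< 0.1); vs CA/BA: range %.3f-%.3f (0.4-0.8)",
  max(m_counts[tri, "rosiglitazone"]),
  min(m_counts[tri, ctl]), max(m_counts[tri, ctl])))
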