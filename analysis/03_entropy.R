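#!/usr/bin/env Rscript
## Interaction-entropy convergence diagnostics: block and cumulative
## estimates on the simulated energy streams, against the Gaussian closed
## form -TdS = sigma^2 / (2 kB T), plus the known fragility at large spread.

suppressMessages(library(bindmode))

sim <- "results/simulated"
dir.create("results/entropy", showWarnings = FALSE, recursive = TRUE)
kbt <- 0.0019872 * 298

rows <- list()
for (f in list.files(sim, pattern = "^energies_sigma", full.names = TRUE)) {
  e <- read.csv(f)$e_int
  sigma <- as.numeric(sub(".*sigma([0-9.]+)\\.csv", "\\1", f))
  cv <- entropy_convergence(e, temperature = 298, n_blocks = 4)
  est <- cv$overall
  rows[[f]] <- data.frame(
    sigma = sigma, n = est$n_samples,
    minus_t_delta_s = est$minus_t_delta_s,
    closed_form = sigma^2 / (2 * kbt),
    sigma_e = est$sigma_e, converged = cv$converged)
  write.csv(cv$cumulative,
            sprintf("results/entropy/cumulative_sigma%.1f.csv", sigma),
            row.names = FALSE)
  message(sprintf(
    "sigma = %.1f kcal/mol: -TdS = %.3f (closed form %.3f), %s",
    sigma, est$minus_t_delta_s, sigma^2 / (2 * kbt),
    if (cv$converged) "converged" else "NOT converged (spread > 2 kBT)"))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/entropy/summary.csv", row.names = FALSE)
message("the sigma = 3 stream illustrates why microsecond-scale spreads make")
message("the exponential-average estimator unreliable; the flag records it")
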