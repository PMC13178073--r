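## Interaction-entropy estimator: -T dS = kB T ln < exp(beta dE_int) >, where
## dE_int is the deviation of the per-frame receptor-ligand interaction
## energy from its ensemble mean. The exponential average is evaluated in log
## space (max-shifted) because beta |dE| can exceed 700 and overflow exp().

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Interaction-entropy term from interaction-energy samples
#'
#' Computes -T dS = kB T ln <exp(beta dE)> with kB = 0.0019872 kcal/mol/K.
#' The estimate is nonnegative for any input (Jensen's inequality) and zero
#' for constant samples. The estimator is exponentially sensitive to the
#' energy spread, so `converged` is set to FALSE when the sample SD exceeds
#' 2 kB T (a documented reliability heuristic, roughly the spread beyond
#' which the exponential average is dominated by a handful of frames).
#'
#' @param e_int_samples per-frame interaction energies, kcal/mol (>= 2 values).
#' @param temperature temperature in K (default 298).
#' @return object of class `entropy_estimate`: list with `minus_t_delta_s`
#'   (kcal/mol), `temperature`, `n_samples`, `sigma_e`, `converged`.
#' @export
interaction_entropy <- function(e_int_samples, temperature = 298) {
  stopifnot(temperature > 0)
  n <- length(e_int_samples)
  if (n < 2) stop("need at least 2 interaction-energy samples")
  bad <- which(!is.finite(e_int_samples))
  if (length(bad))
    stop("non-finite interaction-energy sample at index ",
         paste(bad, collapse = ", "))
  kbt <- KBOLTZ * temperature
  de <- e_int_samples - mean(e_int_samples)
  mts <- kbt * (logsumexp(de / kbt) - log(n))
  mts <- max(mts, 0)   # guard against rounding slightly below zero
  structure(list(minus_t_delta_s = mts, temperature = temperature,
                 n_samples = n, sigma_e = sd(e_int_samples),
                 converged = sd(e_int_samples) <= 2 * kbt),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> -TdS = %.3f kcal/mol (n = %d, sigma = %.3f, %s)\n",
              x$minus_t_delta_s, x$n_samples, x$sigma_e,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Block and cumulative convergence diagnostics for the interaction entropy
#'
#' Splits the sample stream into contiguous blocks and reports the per-block
#' estimate next to the cumulative estimate as a function of sample count,
#' diagnosing the estimator's known sampling fragility (a single high-energy
#' frame can dominate the exponential average).
#'
#' @inheritParams interaction_entropy
#' @param n_blocks number of contiguous blocks (>= 2).
#' @return list with `blocks` (data.frame: block, n, minus_t_delta_s,
#'   sigma_e), `cumulative` (data.frame: n, minus_t_delta_s), `overall`
#'   (the full-sample [interaction_entropy()] estimate) and `converged`
#'   (overall flag AND block agreement within 3 between-block SEs).
#' @export
entropy_convergence <- function(e_int_samples, temperature = 298, n_blocks = 4) {
  stopifnot(n_blocks >= 2)
  n <- length(e_int_samples)
  if (n < 2 * n_blocks) stop("need at least 2 samples per block")
  idx <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  blocks <- do.call(rbind, lapply(seq_along(idx), function(b) {
    est <- interaction_entropy(e_int_samples[idx[[b]]], temperature)
    data.frame(block = b, n = est$n_samples,
               minus_t_delta_s = est$minus_t_delta_s, sigma_e = est$sigma_e)
  }))
  grid <- unique(pmax(2L, floor(seq(2, n, length.out = min(50, n - 1)))))
  cumulative <- data.frame(
    n = grid,
    minus_t_delta_s = vapply(grid, function(m)
      interaction_entropy(e_int_samples[seq_len(m)], temperature)$minus_t_delta_s, 0)
  )
  overall <- interaction_entropy(e_int_samples, temperature)
  ## blocks must scatter within 3 between-block SDs of their mean (with many
  ## blocks this catches a single dominated block; the overall sigma_e
  ## heuristic catches lone outliers regardless of blocking)
  spread_ok <- {
    s <- sd(blocks$minus_t_delta_s)
    all(abs(blocks$minus_t_delta_s - mean(blocks$minus_t_delta_s)) <=
          3 * max(s, 1e-12))
  }
  list(blocks = blocks, cumulative = cumulative, overall = overall,
       converged = overall$converged && spread_ok)
}
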