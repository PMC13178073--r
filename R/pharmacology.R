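## TR-FRET dose-response analysis: 520/495 emission ratios, four-parameter
## logistic (4PL) fits by Levenberg-Marquardt least squares with multi-start
## initialization, Cheng-Prusoff inhibition constants, efficacy
## normalization against a reference agonist, and a ligand-profile decision
## table. Concentrations are handled internally in log10 molar.

#' TR-FRET emission ratio
#'
#' Elementwise 520/495 ratio; the ratio cancels well-to-well variation in
#' donor loading.
#'
#' @param em520,em495 acceptor (520 nm) and donor (495 nm) channel readings.
#' @return numeric ratio series.
#' @export
tr_fret_ratio <- function(em520, em495) {
  stopifnot(length(em520) == length(em495))
  bad <- which(!(em495 > 0))
  if (length(bad))
    stop("nonpositive 495 nm reading at well index ", paste(bad, collapse = ", "))
  em520 / em495
}

pl4 <- function(logx, bottom, top, hill, log_mid) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_mid - logx)))
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of y = bottom + (top - bottom) /
#' (1 + 10^(hill (log_mid - log10 x))) by Levenberg-Marquardt with
#' multi-start initialization (both hill signs, several midpoint guesses);
#' the 95% CI of the log-midpoint comes from the covariance at the optimum.
#'
#' @param concentrations dose series, molar (> 0; >= 5 distinct values).
#' @param responses response series (same length).
#' @return object of class `dose_response_fit`: bottom, top, hill,
#'   log_midpoint (log10 M), ic50_or_ec50 (molar), ci95 (log10 M interval),
#'   residual_sd, midpoint_in_range flag.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses), all(concentrations > 0))
  if (length(unique(concentrations)) < 5)
    stop("need at least 5 distinct concentrations")
  logx <- log10(concentrations)
  df <- data.frame(logx = logx, y = responses)
  span <- diff(range(responses))
  mid_guesses <- stats::quantile(logx, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list()
  for (mg in mid_guesses) for (h in c(1, -1))
    starts[[length(starts) + 1]] <- list(bottom = min(responses), top = max(responses),
                                         hill = h, log_mid = mg)
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ pl4(logx, bottom, top, hill, log_mid),
                        data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("4PL fit did not converge from any start (best residual: none)")
  cf <- as.list(coef(best))
  ## the 4PL is invariant under (bottom, top, hill) -> (top, bottom, -hill);
  ## canonicalize so top is the upper asymptote
  if (cf$top < cf$bottom) {
    tmp <- cf$top; cf$top <- cf$bottom; cf$bottom <- tmp
    cf$hill <- -cf$hill
  }
  dof <- length(responses) - 4L
  residual_sd <- sqrt(best_rss / max(dof, 1))
  if (abs(cf$top - cf$bottom) < 2 * residual_sd)
    stop(sprintf(paste0("4PL fit did not converge: no resolvable dose ",
                        "dependence (span %.3g vs residual SD %.3g)"),
                 abs(cf$top - cf$bottom), residual_sd))
  se_mid <- tryCatch(sqrt(vcov(best)["log_mid", "log_mid"]), error = function(e) NA_real_)
  tcrit <- qt(0.975, max(dof, 1))
  ci <- cf$log_mid + c(-1, 1) * tcrit * se_mid
  in_range <- cf$log_mid >= min(logx) && cf$log_mid <= max(logx)
  if (!in_range)
    warning("fitted midpoint lies outside the tested concentration range")
  structure(list(bottom = cf$bottom, top = cf$top, hill = cf$hill,
                 log_midpoint = cf$log_mid, ic50_or_ec50 = 10^cf$log_mid,
                 ci95 = ci, residual_sd = residual_sd,
                 midpoint_in_range = in_range, n = length(responses)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> midpoint %.3g M (log10 %.3f, 95%% CI ",
                     "[%.3f, %.3f]), hill %.2f, span [%.3g, %.3g]\n"),
              x$ic50_or_ec50, x$log_midpoint, x$ci95[1], x$ci95[2],
              x$hill, x$bottom, x$top))
  invisible(x)
}

#' Cheng-Prusoff inhibition constant from a competitive-binding IC50
#'
#' Ki = IC50 / (1 + [tracer]/Kd_tracer). IC50 and the returned Ki share
#' whatever concentration unit IC50 is given in; tracer concentration and Kd
#' must share a unit with each other.
#'
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param tracer_conc tracer concentration (> 0), default 5 nM.
#' @param tracer_kd tracer dissociation constant (> 0), default 2.8 nM.
#' @return Ki, in the unit of `ic50`.
#' @export
cheng_prusoff_ki <- function(ic50, tracer_conc = 5, tracer_kd = 2.8) {
  if (!(ic50 > 0) || !(tracer_conc > 0) || !(tracer_kd > 0))
    stop("ic50, tracer_conc and tracer_kd must all be positive")
  ic50 / (1 + tracer_conc / tracer_kd)
}

#' Efficacy normalized to a reference agonist
#'
#' 100 * (top - bottom) / (top_ref - bottom_ref): the fitted response span as
#' a percentage of the reference compound's maximal response.
#'
#' @param fit,reference_fit [fit_4pl()] objects.
#' @return efficacy, percent.
#' @export
normalize_efficacy <- function(fit, reference_fit) {
  ref_span <- reference_fit$top - reference_fit$bottom
  if (ref_span == 0) stop("reference fit has zero span")
  100 * (fit$top - fit$bottom) / ref_span
}

#' Ligand-profile classification from coregulator-recruitment efficacies
#'
#' Decision table over coactivator (e.g. TRAP220) and corepressor (e.g.
#' NCoR-1) recruitment efficacies, both expressed as % of their respective
#' reference agonists: coactivator >= `threshold_full` gives a full agonist;
#' coactivator in [`threshold_partial`, `threshold_full`) a
#' partial/selective modulator; both below `threshold_partial` a neutral
#' (silent) antagonist; corepressor >= `threshold_full` an inverse agonist;
#' corepressor in between an antagonist.
#'
#' @param ki inhibition constant establishing binding (finite, > 0), molar
#'   or any consistent unit.
#' @param coactivator_pct,corepressor_pct recruitment efficacies, percent (>= 0).
#' @param threshold_full,threshold_partial decision thresholds, percent.
#' @return object of class `ligand_profile`: binds, ki, efficacies and
#'   `classification`.
#' @export
classify_ligand <- function(ki, coactivator_pct, corepressor_pct,
                            threshold_full = 80, threshold_partial = 10) {
  if (missing(coactivator_pct) || missing(corepressor_pct) ||
      is.na(coactivator_pct) || is.na(corepressor_pct))
    stop("both coactivator and corepressor efficacies are required")
  if (!is.finite(ki) || ki <= 0)
    stop("classification requires established binding (finite positive Ki)")
  stopifnot(coactivator_pct >= 0, corepressor_pct >= 0)
  classification <-
    if (coactivator_pct >= threshold_full) "full agonist"
    else if (coactivator_pct >= threshold_partial) "partial/selective modulator"
    else if (corepressor_pct >= threshold_full) "inverse agonist"
    else if (corepressor_pct >= threshold_partial) "antagonist"
    else "neutral antagonist"
  structure(list(binds = TRUE, ki = ki,
                 trap220_efficacy_pct = coactivator_pct,
                 ncor1_efficacy_pct = corepressor_pct,
                 classification = classification,
                 thresholds = c(full = threshold_full, partial = threshold_partial)),
            class = "ligand_profile")
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat(sprintf("<ligand_profile> Ki = %.3g, coactivator %.1f%%, corepressor %.1f%% -> %s\n",
              x$ki, x$trap220_efficacy_pct, x$ncor1_efficacy_pct, x$classification))
  invisible(x)
}

#' Read a plate CSV and fit a dose-response curve
#'
#' Expects columns well, concentration, unit (uM/nM/M), em520, em495; the
#' response is the TR-FRET ratio.
#'
#' @param path plate CSV path.
#' @return a [fit_4pl()] object.
#' @export
fit_plate_csv <- function(path) {
  plate <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "concentration", "unit", "em520", "em495")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols))
    stop("plate CSV missing columns: ", paste(missing_cols, collapse = ", "))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[plate$unit]
  if (anyNA(scale)) stop("unknown concentration unit in plate CSV")
  conc_molar <- plate$concentration * scale
  fit_4pl(conc_molar, tr_fret_ratio(plate$em520, plate$em495))
}
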