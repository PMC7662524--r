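## Biolayer-interferometry kinetics: global 1:1 Langmuir fitting across
## analyte concentrations (shared kon, koff, rmax), KD arithmetic,
## mutational-dissection tables, and condition equivalence.

langmuir_response <- function(time_s, conc, phase_boundary,
                              kon, koff, rmax) {
  kd <- koff / kon
  req <- rmax * conc / (conc + kd)
  kobs <- kon * conc + koff
  rend <- req * (1 - exp(-kobs * phase_boundary))
  ifelse(time_s <= phase_boundary,
         req * (1 - exp(-kobs * time_s)),
         rend * exp(-koff * (time_s - phase_boundary)))
}

#' Equilibrium dissociation constant from rate constants
#'
#' KD = koff / kon for the 1:1 Langmuir binding model.
#'
#' @param kon Association rate constant (1/(M s)), must be positive.
#' @param koff Dissociation rate constant (1/s).
#' @return KD in molar.
#' @examples
#' compute_kd(131308, 2.907e-4)  # ~2.21 nM
#' @export
compute_kd <- function(kon, koff) {
  if (any(kon <= 0)) stop("kon must be positive")
  koff / kon
}

#' Globally fit the 1:1 Langmuir model to a sensorgram set
#'
#' Minimizes the summed squared residuals over all concentration traces
#' jointly, with shared kon, koff and Rmax: association
#' `R(t) = Rmax*C/(C + koff/kon) * (1 - exp(-(kon*C + koff) t))`,
#' dissociation `R = R_end * exp(-koff (t - boundary))`. Optimization is
#' Levenberg-Marquardt in log-parameter space, multi-started from a
#' log-spaced (kon, koff) grid; no randomness. R-squared is pooled
#' (1 - SS_res/SS_tot over all points). Traces whose maximal response
#' stays within three times the residual-noise estimate are declared
#' no-binding and left unfit.
#'
#' @param sensorgrams `data.frame` with columns time_s, response,
#'   concentration_M, phase (as produced by [simulate_sensorgram()] or
#'   [read_sensorgrams()]).
#' @param phase_boundary Association/dissociation boundary (s); taken
#'   from the `phase` column (last association time) when NULL.
#' @param kon_grid,koff_grid Multi-start grids (default 5 log-spaced
#'   values over 1e3..1e7 and 1e-5..1e-1).
#' @return A `kinetic_fit` list: `kon`, `koff`, `kd` (= koff/kon exactly),
#'   `rmax`, `r_squared`, `converged`, `no_binding`, `ssr`,
#'   `n_concentrations`.
#' @export
fit_global <- function(sensorgrams, phase_boundary = NULL,
                       kon_grid = 10^seq(3, 7, length.out = 5),
                       koff_grid = 10^seq(-5, -1, length.out = 5)) {
  d <- sensorgrams
  need <- c("time_s", "response", "concentration_M")
  if (!all(need %in% names(d)))
    stop("sensorgrams must have columns: ", paste(need, collapse = ", "))
  concs <- unique(d$concentration_M)
  if (length(concs) < 2)
    stop("global fitting needs at least 2 distinct concentrations")
  if (is.null(phase_boundary)) {
    if (!"phase" %in% names(d))
      stop("supply phase_boundary or a phase column")
    phase_boundary <- max(d$time_s[d$phase == "association"])
  }

  ## residual-noise estimate from first differences within each trace
  noise <- stats::median(vapply(concs, function(cc) {
    r <- d$response[d$concentration_M == cc]
    if (length(r) < 3) return(0)
    stats::sd(diff(r)) / sqrt(2)
  }, numeric(1)))
  max_resp <- max(abs(d$response))
  if (max_resp < 3 * noise + 1e-12) {
    return(structure(list(kon = NA_real_, koff = NA_real_, kd = NA_real_,
                          rmax = NA_real_, r_squared = NA_real_,
                          converged = FALSE, no_binding = TRUE,
                          ssr = NA_real_,
                          n_concentrations = length(concs)),
                     class = "kinetic_fit"))
  }

  resid_fn <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3])
    d$response - langmuir_response(d$time_s, d$concentration_M,
                                   phase_boundary, kon, koff, rmax)
  }
  rmax0 <- max(max_resp, 1e-6)
  best <- NULL
  for (k1 in kon_grid) for (k2 in koff_grid) {
    fit <- try(minpack.lm::nls.lm(
      par = log(c(k1, k2, rmax0)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    return(structure(list(kon = NA_real_, koff = NA_real_, kd = NA_real_,
                          rmax = NA_real_, r_squared = NA_real_,
                          converged = FALSE, no_binding = FALSE,
                          ssr = NA_real_,
                          n_concentrations = length(concs)),
                     class = "kinetic_fit"))
  par <- exp(best$fit$par)
  sst <- sum((d$response - mean(d$response))^2)
  structure(list(
    kon = par[1], koff = par[2], kd = par[2] / par[1], rmax = par[3],
    r_squared = 1 - best$ssr / sst,
    converged = best$fit$info %in% 1:4,
    no_binding = FALSE,
    ssr = best$ssr,
    n_concentrations = length(concs)),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (isTRUE(x$no_binding)) {
    cat("Kinetic fit: no apparent binding\n")
  } else {
    cat(sprintf(
      "Kinetic fit: kon %.4g /M/s, koff %.4g /s, KD %.4g M, R^2 %.4f%s\n",
      x$kon, x$koff, x$kd, x$r_squared,
      if (!isTRUE(x$converged)) " (not converged)" else ""))
  }
  invisible(x)
}

#' Mutational-dissection table of kinetic fits
#'
#' Tabulates a set of probe fits (e.g. consensus plus point mutants)
#' against a reference probe, reporting the KD fold-change
#' (kd / reference kd). Rows are ordered by the position of the first
#' lowercase (mutated) base in `sequences` when given, reference first.
#'
#' @param fits Named list of `kinetic_fit` objects.
#' @param reference Name of the reference fit; must be present,
#'   converged, and show binding.
#' @param sequences Optional named character of probe sequences
#'   (lowercase marks mutated positions, as in dissection tables).
#' @return `data.frame` with columns name, sequence, kon, koff, kd,
#'   r_squared, fold_change (values displayed at 4 significant figures
#'   by the writer; stored unrounded).
#' @export
dissection_table <- function(fits, reference, sequences = NULL) {
  if (!reference %in% names(fits))
    stop("reference '", reference, "' not among fits")
  ref <- fits[[reference]]
  if (isTRUE(ref$no_binding))
    stop("reference fit shows no binding; cannot form fold-changes")
  if (!isTRUE(ref$converged))
    stop("reference fit did not converge")
  nm <- names(fits)
  mut_pos <- vapply(nm, function(x) {
    if (x == reference) return(-1)
    if (!is.null(sequences) && x %in% names(sequences)) {
      p <- regexpr("[acgt]", sequences[[x]])
      if (p > 0) return(as.numeric(p))
    }
    Inf
  }, numeric(1))
  ord <- order(mut_pos, nm)
  rows <- lapply(nm[ord], function(x) {
    f <- fits[[x]]
    data.frame(
      name = x,
      sequence = if (!is.null(sequences) && x %in% names(sequences))
        sequences[[x]] else NA_character_,
      kon = f$kon, koff = f$koff, kd = f$kd, r_squared = f$r_squared,
      no_binding = isTRUE(f$no_binding),
      fold_change = if (isTRUE(f$no_binding)) NA_real_ else f$kd / ref$kd,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Equivalence verdict between two kinetic fits
#'
#' Two conditions are called equivalent when their KDs agree within a
#' relative tolerance (used e.g. to test cofactor independence of
#' binding).
#'
#' @param fit_a,fit_b Converged `kinetic_fit` objects.
#' @param tolerance Relative KD tolerance (default 0.10).
#' @return List with `verdict` ("equivalent"/"not_equivalent") and
#'   `relative_difference`.
#' @export
compare_condition <- function(fit_a, fit_b, tolerance = 0.10) {
  for (f in list(fit_a, fit_b))
    if (!isTRUE(f$converged) || isTRUE(f$no_binding))
      stop("both fits must be converged binding fits")
  rel <- abs(fit_a$kd - fit_b$kd) / fit_a$kd
  list(verdict = if (rel <= tolerance) "equivalent" else "not_equivalent",
       relative_difference = rel)
}
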