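#' Extracellular consumption and production rates
#'
#' Rates are computed from start/end medium concentrations and cell counts
#' over an incubation window, normalized to cell number:
#' rate = (C0 - Ct) * V / integral N(tau) dtau, in nmol per 1e6 cells per
#' hour, with N(tau) interpolated exponentially through the two counts
#' (integral = t * (Nt - N0) / log(Nt / N0), and N * t when Nt = N0).
#' Positive rates are consumption, negative are production.
#'
#' @name extracellular_rates
NULL

#' Rate from a two-point time course
#'
#' @param c0,ct concentrations at time 0 and t, in mM
#' @param volume_ml medium volume in mL
#' @param n0,nt cell counts at time 0 and t
#' @param hours incubation duration in hours
#' @param metabolite optional id carried through to the result
#' @return a `rate_result`: list with `metabolite`, `rate`
#'   (nmol/1e6 cells/h), `direction` ("consumption", "production" or
#'   "unchanged")
#' @export
extracellular_rate <- function(c0, ct, volume_ml, n0, nt, hours,
                               metabolite = NA_character_) {
  if (c0 < 0 || ct < 0) stop("concentrations must be non-negative")
  if (n0 <= 0 || nt <= 0) stop("cell counts must be positive")
  if (hours <= 0) stop("duration must be positive")
  # cell-hours in units of 1e6 cells * h
  if (abs(nt - n0) < 1e-9 * n0) {
    cellh <- n0 / 1e6 * hours
  } else {
    cellh <- hours * (nt - n0) / log(nt / n0) / 1e6
  }
  # mM * mL = umol = 1000 nmol
  rate <- (c0 - ct) * volume_ml * 1000 / cellh
  structure(list(metabolite = metabolite, rate = rate,
                 direction = if (rate > 0) "consumption"
                             else if (rate < 0) "production" else "unchanged"),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%s: %.3f nmol/1e6 cells/h (%s)\n",
              if (is.na(x$metabolite)) "rate" else x$metabolite,
              x$rate, x$direction))
  invisible(x)
}

#' Amino-acid balance against protein synthesis demand
#'
#' Compares measured amino-acid uptake rates with the demand implied by the
#' protein synthesis flux: surplus = uptake - protein_flux * stoichiometry.
#' A positive surplus means uptake beyond the protein requirement (carbon
#' available to other pathways); near-zero surplus means uptake matched to
#' protein synthesis.
#'
#' @param uptake named numeric: amino acid -> uptake rate (consumption
#'   positive), nmol/1e6 cells/h
#' @param protein_flux protein synthesis rate, nmol protein/1e6 cells/h
#' @param composition named numeric: amino acid -> residues per protein unit
#' @return data.frame (amino_acid, uptake, demand, surplus)
#' @export
amino_acid_balance_check <- function(uptake, protein_flux, composition) {
  missing <- setdiff(names(uptake), names(composition))
  if (length(missing))
    stop("composition missing amino acids: ", paste(missing, collapse = ", "))
  aa <- names(uptake)
  demand <- protein_flux * composition[aa]
  data.frame(amino_acid = aa,
             uptake = unname(uptake),
             demand = unname(demand),
             surplus = unname(uptake - demand),
             row.names = NULL, stringsAsFactors = FALSE)
}
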