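#' Measurement sets for flux fitting
#'
#' A `measurement_set` bundles the data a stationary flux fit consumes:
#' corrected MIDs per tracer experiment (with per-channel standard
#' deviations) and extracellular rates or fixed fluxes (each a linear
#' functional of the net-flux vector, usually a single reaction).
#'
#' @param mids list of [mid_measurement()] records
#' @param rates list of [rate_measurement()] records
#' @return a `measurement_set`
#' @export
measurement_set <- function(mids = list(), rates = list()) {
  for (m in mids) {
    if (abs(sum(m$mid) - 1) > 0.05 || any(m$mid < -0.05))
      stop("measured MID for ", m$met, " is not close to a distribution")
    if (length(m$sd) != length(m$mid)) stop("mid/sd length mismatch")
    if (any(m$sd <= 0)) stop("MID sds must be positive")
  }
  for (r in rates) if (r$sd <= 0) stop("rate sds must be positive")
  structure(list(mids = mids, rates = rates), class = "measurement_set")
}

#' @rdname measurement_set
#' @param experiment tracer experiment label (must match the experiment
#'   names used when fitting)
#' @param met metabolite id
#' @param mid measured MID vector
#' @param sd per-channel standard deviations
#' @param positions measured fragment carbon positions (NULL = whole
#'   molecule)
#' @param renormalized whether the measured MID was renormalized to sum 1
#'   (the usual case); renormalized MIDs carry one fewer independent channel
#' @export
mid_measurement <- function(experiment, met, mid, sd, positions = NULL,
                            renormalized = TRUE) {
  list(experiment = experiment, met = met, positions = positions,
       mid = mid, sd = sd, renormalized = renormalized)
}

#' @rdname measurement_set
#' @param name label for the measured process
#' @param value measured rate, nmol/1e6 cells/h (positive in the direction
#'   of the reaction as written)
#' @param coef named coefficients over reaction net fluxes defining the
#'   predicted value (defaults to the single reaction `name`)
#' @export
rate_measurement <- function(name, value, sd, coef = NULL) {
  if (is.null(coef)) coef <- stats::setNames(1, name)
  list(name = name, value = value, sd = sd, coef = coef)
}

#' @export
print.measurement_set <- function(x, ...) {
  nch <- sum(vapply(x$mids, function(m) length(m$mid), 0))
  cat(sprintf("<measurement_set> %d MIDs (%d channels), %d rates\n",
              length(x$mids), nch, length(x$rates)))
  invisible(x)
}

#' Effective number of independent measurements
#'
#' Each renormalized MID of length k contributes k - 1 (the unit sum makes
#' one channel redundant); a non-renormalized MID contributes k; each rate
#' contributes 1.
#' @param data a `measurement_set`
#' @return integer count
#' @export
n_independent_measurements <- function(data) {
  sum(vapply(data$mids, function(m)
    length(m$mid) - as.integer(isTRUE(m$renormalized)), 0L)) +
    length(data$rates)
}
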