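#' Mass isotopologue distributions and tracer specifications
#'
#' An MID is the normalized vector (m0..mn) of fractions of molecules (or
#' fragments) carrying 0..n extra mass units from tracer carbon.
#'
#' @name mid
NULL

#' Validate an MID vector
#' @param x numeric vector (m0..mn)
#' @param tol tolerance on the unit sum
#' @return `x`, invisibly, after checks
#' @export
check_mid <- function(x, tol = 1e-9) {
  if (any(x < -1e-12)) stop("MID has negative entries")
  if (abs(sum(x) - 1) > tol) stop("MID does not sum to 1 (sum = ", sum(x), ")")
  invisible(x)
}

#' Convolve two MIDs
#'
#' The MID of a molecule assembled from two independent parts is the discrete
#' convolution of the parts' MIDs; length is `length(a) + length(b) - 1`.
#'
#' @param a,b numeric MID vectors
#' @return numeric MID vector
#' @export
convolve_mid <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Mean mass shift of an MID
#' @param x MID vector
#' @return expected number of tracer carbons
#' @export
mean_mass <- function(x) sum((seq_along(x) - 1) * x) / sum(x)

#' Declare a labeled substrate
#'
#' @param substrate metabolite id of a source-role metabolite
#' @param pattern positional labeling as a 0/1 string, one character per
#'   carbon (e.g. `"110000"` for glucose labeled at carbons 1 and 2,
#'   `"11111"` for uniformly labeled glutamine); or a list of patterns
#' @param fraction fraction of molecules fed with each pattern (defaults to
#'   1 split over patterns); remainder is unlabeled
#' @param purity isotopic enrichment of the labeled positions; a molecule
#'   matches its pattern with probability `purity`, else is unlabeled
#' @return a `tracer_spec`
#' @export
tracer_spec <- function(substrate, pattern, fraction = NULL, purity = 1) {
  if (is.character(pattern) && length(pattern) == 1L) pattern <- list(pattern)
  if (is.null(fraction)) fraction <- rep(1 / length(pattern), length(pattern))
  if (length(fraction) != length(pattern))
    stop("fraction must have one entry per pattern")
  if (any(fraction < 0) || sum(fraction) > 1 + 1e-12)
    stop("pattern fractions must be >= 0 and sum to at most 1")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  for (p in pattern)
    if (!grepl("^[01]+$", p)) stop("pattern must be a 0/1 string: ", p)
  structure(list(substrate = substrate,
                 pattern = unlist(pattern),
                 fraction = fraction,
                 purity = purity),
            class = "tracer_spec")
}

# positional labeling probability table: list of (bits, fraction) where bits
# is an integer vector of labeled positions; includes the unlabeled remainder
.tracer_components <- function(tr) {
  comp <- list()
  eff <- tr$fraction * tr$purity
  for (i in seq_along(tr$pattern)) {
    pos <- which(strsplit(tr$pattern[i], "")[[1]] == "1")
    comp[[length(comp) + 1L]] <- list(positions = pos, fraction = eff[i])
  }
  rem <- 1 - sum(eff)
  if (rem > 1e-15)
    comp[[length(comp) + 1L]] <- list(positions = integer(0), fraction = rem)
  comp
}

# MID of a position subset of a source metabolite under the tracers
.source_mid <- function(met, positions, tracers, carbons) {
  tr <- NULL
  for (t in tracers) if (t$substrate == met) tr <- t
  n <- length(positions)
  out <- numeric(n + 1L)
  if (is.null(tr)) { out[1] <- 1; return(out) }
  for (p in tr$pattern)
    if (nchar(p) != carbons)
      stop(sprintf("tracer pattern '%s' has %d positions but %s has %d carbons",
                   p, nchar(p), met, carbons))
  for (comp in .tracer_components(tr)) {
    k <- sum(positions %in% comp$positions)
    out[k + 1L] <- out[k + 1L] + comp$fraction
  }
  out
}
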