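#' Natural isotope abundance correction of GC/MS spectra
#'
#' Measured ion intensity distributions contain mass shifts contributed by
#' naturally occurring heavy isotopes of every element in the derivatized
#' fragment (13C, 2H, 15N, 17/18O, 29/30Si, 33/34S), on top of the
#' tracer-derived 13C. Correction builds, from the elemental formula, the
#' matrix whose column j is the expected spectrum of a fragment carrying
#' exactly j tracer carbons, then solves a non-negatively constrained least
#' squares problem for the tracer MID.
#'
#' @name natural_abundance
NULL

# natural isotope abundance by mass shift (IUPAC representative values)
.isotope_abundance <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  S  = c(0.9499, 0.0075, 0.0425, 0.0001),
  P  = c(1)
)

#' Parse an elemental formula string
#' @param formula e.g. `"C11H21NO3Si2"` (Hill-style tokens, counts >= 1)
#' @return named integer vector element -> count
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  out <- integer()
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[^0-9]", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

# mass-shift distribution of k atoms of one element (repeated convolution)
.element_dist <- function(p, k, trunc = NULL) {
  d <- 1
  for (i in seq_len(k)) d <- convolve_mid(d, p)
  if (!is.null(trunc) && length(d) > trunc) {
    d <- d[seq_len(trunc)]
  }
  d
}

#' Natural-abundance contribution matrix for a fragment
#'
#' Column j (j = 0..n tracked carbons) is the expected mass-shift spectrum of
#' a fragment whose tracked carbons carry exactly j tracer 13C atoms:
#' the convolution of the natural-isotope distributions of all non-carbon
#' atoms, of the untracked carbons, and of the (n - j) unlabeled tracked
#' carbons, shifted by j.
#'
#' @param formula elemental formula of the derivatized ion (string or named
#'   counts from [parse_formula()])
#' @param n_tracked number of tracer-derived (tracked) carbon positions
#' @param n_channels number of measured mass channels (rows); defaults to
#'   `n_tracked + 1`
#' @param carbon_only if TRUE only 13C natural abundance is corrected
#' @param abundances isotope abundance table (element -> fraction vector by
#'   mass shift)
#' @return `n_channels` x `(n_tracked + 1)` matrix
#' @export
correction_matrix <- function(formula, n_tracked, n_channels = n_tracked + 1L,
                              carbon_only = FALSE,
                              abundances = .isotope_abundance) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (nC < n_tracked)
    stop("formula has fewer carbons than tracked positions")
  base <- 1
  if (!carbon_only) {
    for (el in setdiff(names(counts), "C")) {
      if (!el %in% names(abundances))
        stop("no abundance data for element: ", el)
      base <- convolve_mid(base, .element_dist(abundances[[el]], counts[[el]],
                                               trunc = n_channels))
      if (length(base) > n_channels) base <- base[seq_len(n_channels)]
    }
  }
  untracked <- .element_dist(abundances$C, nC - n_tracked, trunc = n_channels)
  base <- convolve_mid(base, untracked)
  if (length(base) > n_channels) base <- base[seq_len(n_channels)]
  M <- matrix(0, n_channels, n_tracked + 1L)
  for (j in 0:n_tracked) {
    col <- convolve_mid(base, .element_dist(abundances$C, n_tracked - j,
                                            trunc = n_channels))
    shifted <- numeric(n_channels)
    upto <- min(length(col), n_channels - j)
    if (upto > 0) shifted[j + seq_len(upto)] <- col[seq_len(upto)]
    M[, j + 1L] <- shifted
  }
  M
}

#' Forward-synthesize a measured spectrum from a tracer MID
#' @param mid tracer MID (length `n_tracked + 1`)
#' @param formula elemental formula of the derivatized ion
#' @param n_channels channels to emit
#' @inheritParams correction_matrix
#' @return intensity vector over consecutive nominal masses (sums to <= 1)
#' @export
synthesize_spectrum <- function(mid, formula, n_channels = length(mid) + 4L,
                                carbon_only = FALSE) {
  M <- correction_matrix(formula, length(mid) - 1L, n_channels,
                         carbon_only = carbon_only)
  drop(M %*% mid)
}

#' Correct a raw ion distribution for natural isotope abundance
#'
#' @param intensities non-negative intensity vector over consecutive nominal
#'   masses starting at the unlabeled monoisotopic mass
#' @param formula elemental formula of the derivatized ion
#' @param n_tracked number of tracked (tracer-derived) carbons
#' @param carbon_only correct for natural 13C only
#' @param sd_floor lower bound applied to the per-channel standard deviation
#' @param sd_rel relative standard deviation (fraction of the corrected m_i)
#' @return a `corrected_mid`: list with `mid` (normalized, length
#'   `n_tracked + 1`), `sd` (per channel, `max(sd_floor, sd_rel * m_i)`),
#'   `condition` (condition number of the correction matrix), and
#'   `flagged` (TRUE when condition > 1e8; a warning is raised)
#' @export
natural_abundance_correct <- function(intensities, formula, n_tracked,
                                      carbon_only = FALSE,
                                      sd_floor = 0.003, sd_rel = 0.01) {
  if (any(intensities < 0)) stop("negative intensities")
  if (all(intensities == 0)) stop("all-zero intensity vector")
  if (length(intensities) < n_tracked + 1L)
    stop("need at least n_tracked + 1 intensity channels")
  M <- correction_matrix(formula, n_tracked, length(intensities),
                         carbon_only = carbon_only)
  kap <- kappa(M, exact = TRUE)
  flagged <- is.finite(kap) && kap > 1e8
  if (flagged)
    warning("ill-conditioned correction matrix (condition number ",
            signif(kap, 3), "); corrected MID flagged")
  y <- intensities / sum(intensities)
  x <- pracma::lsqnonneg(M, y)$x
  if (sum(x) <= 0) stop("correction produced an all-zero MID")
  mid <- x / sum(x)
  structure(list(mid = mid,
                 sd = pmax(sd_floor, sd_rel * mid),
                 condition = kap, flagged = flagged),
            class = "corrected_mid")
}
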