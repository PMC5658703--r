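#' Descriptive label statistics
#'
#' Summary statistics used to read labeling patterns off corrected MIDs:
#' total label enrichment (the summed labeled fractions, used as a
#' normalization denominator) and ratios of matched mass-shift channels
#' between a metabolite and a reference (e.g. m2 of a TCA intermediate over
#' m2 pyruvate).
#'
#' @name label_summaries
NULL

#' Total label enrichment and normalized labeled fractions
#'
#' @param mid MID vector (m0..mn)
#' @param include_m0 include m0 in the denominator (default FALSE: the
#'   enrichment is the labeled mass only)
#' @return list: `sigma_m` (total enrichment), `normalized` (m_i / sigma_m
#'   for i >= 1; empty when sigma_m is 0)
#' @export
total_label_enrichment <- function(mid, include_m0 = FALSE) {
  check_mid(mid)
  labeled <- mid[-1]
  sm <- if (include_m0) sum(mid) else sum(labeled)
  if (sm <= 0)
    return(list(sigma_m = 0, normalized = numeric(0)))
  norm <- labeled / sm
  names(norm) <- paste0("m", seq_along(labeled))
  list(sigma_m = sm, normalized = norm)
}

#' Ratio of matched mass-shift channels between two MIDs
#'
#' @param met MID of the metabolite of interest
#' @param ref MID of the reference metabolite
#' @param k mass shift (e.g. 2 for m2/m2 ratios)
#' @return `met[k] / ref[k]`
#' @export
m_ratio <- function(met, ref, k) {
  if (length(met) < k + 1L || length(ref) < k + 1L)
    stop("mass shift m", k, " not present in both MIDs")
  if (ref[k + 1L] == 0) stop("reference m", k, " is zero; ratio undefined")
  met[k + 1L] / ref[k + 1L]
}
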