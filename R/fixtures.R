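#' Packaged example networks
#'
#' Network model files shipped with the package:
#' \describe{
#'   \item{hct116_central_carbon}{central carbon metabolism of a colorectal
#'     carcinoma cell: glycolysis, oxidative and non-oxidative pentose
#'     phosphate pathway, PDH/PC/ME pyruvate branch points, full TCA cycle
#'     with succinate symmetry, reversible IDH (reductive carboxylation) and
#'     ATP-citrate lyase, glutaminolysis (GLS, GDH), lactate/glutamate/
#'     alanine secretion, glucose/glutamine/essential-amino-acid uptake, a
#'     glycogen branch and a lumped protein-synthesis drain. Annotations
#'     carry the electron-pair coefficients used to couple fluxes to oxygen
#'     consumption.}
#'   \item{tca_reduced}{reduced glycolysis + TCA + glutaminolysis network
#'     used for parameter-recovery studies: 12 reactions, 7 balanced pools,
#'     5 free net fluxes plus IDH and MDH exchange fluxes.}
#'   \item{tca_first_turn_oxidative}{single-pass oxidative TCA scheme fed by
#'     glutamine through glutaminase/glutamate dehydrogenase, with unlabeled
#'     acetyl-CoA condensing onto the glutamine-derived oxaloacetate.}
#'   \item{tca_first_turn_reductive}{single-pass reductive carboxylation
#'     scheme: glutamine-derived alpha-ketoglutarate carboxylated with
#'     unlabeled CO2 to citrate, cleaved by citrate lyase to acetyl-CoA and
#'     oxaloacetate, the latter transaminated to aspartate.}
#'   \item{glycolysis_only}{glucose split into two pyruvate halves with the
#'     standard C1-C2-C3 / C6-C5-C4 atom mapping.}
#' }
#'
#' @param name one of the names above
#' @return a validated `flux_network`
#' @export
example_network <- function(name = c("hct116_central_carbon", "tca_reduced",
                                     "tca_first_turn_oxidative",
                                     "tca_first_turn_reductive",
                                     "glycolysis_only")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".net"), package = "emuflux")
  if (!nzchar(path)) path <- file.path("inst", "extdata", paste0(name, ".net"))
  if (!file.exists(path)) stop("fixture network not found: ", name)
  read_network(path)
}

#' Standard tracers for the parallel labeling experiments
#'
#' Experiment "glc": glucose labeled at carbons 1 and 2 (10 mM feed),
#' glutamine unlabeled. Experiment "gln": uniformly labeled glutamine
#' (2 mM feed), glucose unlabeled.
#'
#' @param experiment `"glc"` or `"gln"`
#' @param glucose,glutamine source metabolite ids in the network
#' @param purity isotopic purity of the labeled substrate
#' @return list of [tracer_spec()] (only the labeled substrate is listed;
#'   unlabeled sources need no spec)
#' @export
standard_tracers <- function(experiment = c("glc", "gln"),
                             glucose = "glc.x", glutamine = "gln.x",
                             purity = 1) {
  experiment <- match.arg(experiment)
  if (experiment == "glc")
    list(tracer_spec(glucose, "110000", purity = purity))
  else
    list(tracer_spec(glutamine, "11111", purity = purity))
}

#' Oxygen consumption implied by a flux vector
#'
#' Reads the `electron_pairs` annotation (comma-separated `reaction=pairs`
#' terms) and maps the summed electron-pair production to O2 consumption at
#' the annotated `o2_per_pair` stoichiometry (default 1/2 O2 per NADH or
#' FADH2 oxidized).
#'
#' @param net a `flux_network` with an `electron_pairs` annotation
#' @param v a `flux_vector`
#' @return predicted O2 consumption rate, nmol/1e6 cells/h
#' @export
predicted_ocr <- function(net, v) {
  ann <- net$annotations[["electron_pairs"]]
  if (is.null(ann) || is.na(ann)) stop("network has no electron_pairs annotation")
  terms <- strsplit(ann, ",", fixed = TRUE)[[1]]
  total <- 0
  for (t in terms) {
    kv <- strsplit(trimws(t), "=", fixed = TRUE)[[1]]
    total <- total + as.numeric(kv[2]) * v$net[[kv[1]]]
  }
  per <- net$annotations[["o2_per_pair"]]
  per <- if (is.null(per) || is.na(per)) 0.5 else as.numeric(per)
  per * total
}
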