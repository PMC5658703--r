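#!/usr/bin/env Rscript

# Knockdown vs control flux comparison.
#
# Reads the fitted runs of analysis/03_fit_fluxes.R (rerunning them if the
# output directory is missing), then classifies each profiled flux by the
# highest confidence level at which the two conditions' profile intervals
# separate, mirroring the flux-map comparison: red/green arrows = fold
# changes whose intervals are disjoint, with the level annotated.

suppressPackageStartupMessages(library(emuflux))

if (!file.exists("results/fit/comparison.tsv")) {
  cat("fit outputs missing; running the fit stage first\n")
  source("analysis/03_fit_fluxes.R")
}
cmp <- read.delim("results/fit/comparison.tsv")
cat("Flux fold changes (knockdown / control) and separation classes:\n\n")
print(cmp, row.names = FALSE)
up <- cmp$reaction[cmp$direction == "up" & cmp$type == "net"]
cat("\nFluxes classified up in the knockdown:",
    paste(up, collapse = ", "), "\n")
cat("Expected signature: glutaminolysis (GDH), glutamine-derived\n")
cat("secretions (GLUOUT), glycolysis/lactate (LDH) and TCA throughput up;\n")
cat("the MDH exchange, unchanged by construction, should overlap.\n")
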