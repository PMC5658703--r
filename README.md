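# emuflux

Stationary ¹³C metabolic flux analysis (MFA) of central carbon metabolism
in R, built for two-condition comparisons of the kind used to characterize
metabolic reprogramming in cancer cells: parallel tracer cultures
([1,2-¹³C₂]-glucose and [U-¹³C₅]-glutamine), GC/MS mass isotopologue
distributions (MIDs), extracellular consumption/production rates, and a
flux model of glycolysis, the pentose phosphate pathway, the TCA cycle and
glutaminolysis fitted to all of it at once.

For a metabolic network with carbon atom transitions and steady-state
constraint **S v = 0**, the package predicts the MID of any metabolite
fragment from a flux vector *v* and tracer specification by elementary
metabolite unit (EMU) decomposition, and estimates the free fluxes by
minimizing the variance-weighted residual sum of squares

SSR(v) = Σᵢ ((predᵢ(v) − measᵢ) / σᵢ)²

over MID channels and rates, with bounded Levenberg–Marquardt from
multiple starts. Inference is by profile likelihood: the interval for a
flux at level α is bounded where the re-optimized SSR crosses
SSR_min + χ²₁(α); two conditions are compared by best-fit fold changes,
classified by the highest level in {95%, 90%, 80%} at which their
intervals are disjoint. Goodness of fit is the χ² upper tail of SSR at
(independent measurements − free parameters) degrees of freedom.

The package includes:

- a plain-text network format with atom maps, symmetry (dual-weighted
  maps) and annotations, plus a packaged HCT116-style central-carbon model
  and single-turn TCA fixtures (`example_network()`);
- exact rational null-space machinery (`build_stoichiometry()`), EMU
  simulation (`emu_decompose()`, `simulate_mids()`) and a brute-force
  positional-isotopomer oracle used to verify it;
- natural-abundance correction of GC/MS spectra from full elemental
  formulas (`natural_abundance_correct()`), label summary statistics
  (Σm-normalized fractions, m-ratios) and extracellular rate calculation
  with exponential cell-growth interpolation;
- fitting, profile CIs and condition comparison (`fit_fluxes()`,
  `profile_ci()`, `compare_conditions()`);
- a synthetic two-condition, two-tracer generator with ground truth
  (`default_scenario()`, `generate_dataset()`) and an orchestrated
  pipeline (`run_analysis()`).

## Worked example

Single-turn label propagation from uniformly labeled glutamine through the
oxidative TCA cycle:

```r
library(emuflux)
net <- example_network("tca_first_turn_oxidative")
v <- flux_vector(c(GLS = 1, GDH = 1, AKGDH = 1, SDH = 1, MDH = 1,
                   CS = 0.5, CITOUT = 0.5, AST = 0.5, ASPOUT = 0.5),
                 network = net)
em <- emu_decompose(net, whole_molecule_targets(net, c("cit", "glu")))
mids <- simulate_mids(em, v, list(tracer_spec("gln.x", "11111")))
round(mid_of(mids, "cit"), 3)
#> [1] 0 0 0 0 1 0 0
which.max(mid_of(mids, "glu")) - 1
#> [1] 5
```

Citrate is m4 (four glutamine carbons survive the oxidative turn into
oxaloacetate; the condensing acetyl-CoA is unlabeled) and glutamate is m5 —
the oxidative-route signature. The reductive-carboxylation fixture gives m5
citrate and m3 aspartate instead, and the glycolysis fixture gives the
dominant labeled pyruvate at m2 from [1,2-¹³C₂]-glucose.

Fitting the packaged two-condition scenario end to end:

```r
cfg <- run_config(scenario = default_scenario(replicates = 1, seed = 17),
                  out_dir = "results/fit", seed = 7, n_starts = 4)
rep <- run_analysis(cfg)
rep$fits$control
#> <fit_result> SSR = 37.04, dof = 42, chi-square p = 0.688
head(rep$comparison, 3)
#>  reaction type fold_change classification direction
#>       LDH  net    1.351323   separated_95        up
#>       MDH  net    1.193932   separated_95        up
#>       GDH  net    1.490076   separated_95        up
```

Per reaction this gives the knockdown/control fold change and its
classification — in the packaged scenario glutaminolysis (truth ×1.5,
fitted 1.49), glycolysis (×1.3, fitted 1.35) and the doubled reductive IDH
exchange (fitted 2.05) separate at the 95% level with the correct
direction, while the untouched MDH exchange (fitted 1.06) overlaps.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (label propagation → dataset generation → fitting → comparison →
the full central-carbon model demo) and write their tables under
`results/`.

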