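---
title: "Stationary 13C flux analysis with emuflux: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary 13C flux analysis with emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The problem

Proliferating cells reorganize central carbon metabolism — glycolysis, the
pentose phosphate pathway, the TCA cycle and glutaminolysis — and the
reorganization is quantified by intracellular fluxes that cannot be measured
directly. Stationary ^13^C metabolic flux analysis (MFA) infers them by
feeding positionally labeled substrates (here [1,2-^13^C~2~]-glucose and
[U-^13^C~5~]-glutamine in parallel cultures), measuring mass isotopologue
distributions (MIDs) of intracellular and secreted metabolites by GC/MS
together with extracellular consumption/production rates, and fitting a flux
model of the reaction network, with carbon-atom transitions, to all of these
data at once. `emuflux` implements that workflow end to end, including a
synthetic-data generator that emulates a two-condition experiment (control
vs CDK4/6-knockdown-like) so that every statistical property of the pipeline
can be validated against known ground truth.

## Network model

A network is a set of metabolites (with carbon counts and a role: balanced,
source, or sink), reactions with atom-transition maps written as letter
strings (`akg (abcde) -> suc (bcde) + co2 (a)`), and annotations. Molecular
symmetry (succinate/fumarate) is encoded as two atom maps weighted 0.5 each;
this is required for correct label scrambling after the first TCA turn. CO~2~
is an untracked source/sink: carbons routed to it are dropped and carbons
drawn from it are unlabeled. Reversible reactions are parameterized as a net
flux plus a non-negative exchange flux (forward = max(net, 0) + exchange),
which keeps the optimization box-constrained while letting exchange shape
labeling without affecting mass balance.

Steady state is `S v = 0` over the balanced metabolites. The null space is
computed by exact rational Gauss-Jordan elimination, so `S %*% basis` is
exactly zero and the free coordinates are actual reaction fluxes (the
non-pivot columns); every flux vector in the pipeline is `basis %*% theta`.
An independent rational-rank oracle guards the degrees-of-freedom count in
the tests.

Respiration is coupled to the flux map through a network annotation listing
electron-pair coefficients per reaction (NADH/FADH~2~ producers +1, lactate
export -1 for the cytosolic redox drain), mapped to O~2~ consumption at 1/2
O~2~ per pair by `predicted_ocr()`. This expresses the same constraint as a
respiration pseudo-reaction without introducing a carbon-free pseudo-
metabolite into `S`.

The packaged `hct116_central_carbon` network covers glycolysis, oxidative
and non-oxidative PPP, PDH/PC/ME, the full TCA cycle, reversible IDH
(reductive carboxylation) with ATP-citrate lyase, glutaminolysis, secretion
and uptake reactions, a glycogen branch and a lumped protein-synthesis
drain. It uses single (uncompartmentalized) pools; distinguishing cytosolic
from mitochondrial pools would change some exchange-flux interpretations but
none of the machinery. The protein drain consumes one unit of each amino
acid per unit flux — a deliberate simplification; a realistic residue
composition would only rescale that column of `S`.

## EMU simulation

MIDs are predicted with the elementary metabolite unit (EMU) decomposition:
starting from the measured fragments, the atom maps are traced backward and
the minimal set of carbon-subset units whose MIDs are needed is collected,
stratified by size. Within a size the balances are linear given the fluxes;
condensations couple a size to smaller sizes through convolutions of MIDs.
Systems are solved densely size by size; all shipped and generated systems
have at most a few dozen unknowns per size, far below where sparse
factorization would pay. Residual tolerances are at solver precision, and
solutions are clamped at zero and renormalized (negative excursions are at
rounding level).

Flux-dead branches need care: a decomposition is structural, so an EMU can
appear whose pools receive no flux under a particular flux vector (e.g. the
glutamate pool when glutaminolysis is switched off). Such units carry no
material; they receive an unlabeled placeholder, and an error is raised only
when a requested target itself has zero influx.

The test oracle is an independent brute-force solver over full positional
isotopomer distributions (2^n states per n-carbon metabolite) iterated to
stationarity with Gauss-Seidel sweeps. The EMU path and the oracle agree to
below 1e-8 across five toy topologies (linear, branched-reconverging,
cleaving, condensing, cyclic with reversible exchange) at 50 random flux
draws each.

One observation from these simulations is worth recording: the popular
"m2 metabolite / m2 pyruvate" ratio read from [1,2-^13^C~2~]-glucose
labeling rises with the pyruvate-dehydrogenase share only in the
single-pass (first-turn) regime. At full cyclic steady state the dominant
m2-citrate term is (acetyl m2) x (oxaloacetate m0), so increasing TCA
turnover can *lower* the ratio while raising absolute label incorporation.
The ratio is therefore reported as a descriptive statistic only; the fit
consumes individual MID channels.

## Measurement processing

GC/MS spectra of derivatized fragments are corrected for natural isotope
abundance with a correction matrix built from the full elemental formula
(C, H, N, O, Si, S multinomials), not carbon alone — silicon in TMS
derivatives shifts spectra substantially, and a carbon-only mode exists for
pre-stripped data. Correction solves a non-negative least squares problem
and renormalizes; matrices with condition number above 1e8 are flagged. The
forward model (`synthesize_spectrum()`) and the correction round-trip to
1e-6 over random MID/formula pairs.

Extracellular rates use two-point concentration differences normalized to
the time integral of cell number, with exponential interpolation between
the two counts (cultures in exponential phase): rate = dC * V / (t *
(N_t - N_0) / ln(N_t / N_0)), in nmol per 10^6 cells per hour, the unit
used throughout. The amino-acid balance check compares measured uptakes
with protein-synthesis demand; in the packaged scenario the control
condition is constructed to match demand and the knockdown condition takes
up surplus glutamine-family carbon.

## The synthetic experiment

The generator is the stand-in for the wet experiment and defines the study
conditions; its defaults are fixed and not tuned per analysis:

* control fluxes at literature-scale magnitudes for a proliferating
  colorectal carcinoma line: glucose uptake 150, lactate output 240 (highly
  fermentative), glutamine uptake 40, glutamate secretion 15, PDH 50, PC 10,
  aspartate drain 35 nmol/10^6 cells/h, IDH exchange 5, MDH exchange 100;
* knockdown condition derived by multipliers expressing the reported
  directions — glutamine uptake and glutamate dehydrogenase x1.5, reductive
  IDH exchange x2, glucose uptake and lactate output x1.3 — followed by a
  least-squares re-projection onto the steady-state manifold holding the
  multiplied fluxes fixed (the magnitudes are synthetic choices, not
  measured values);
* two tracer experiments per condition (glucose labeled at carbons 1-2;
  uniformly labeled glutamine), whole-molecule MIDs of citrate,
  alpha-ketoglutarate, malate, secreted lactate and aspartate, and five
  extracellular rates;
* noise: truncated-Gaussian channel noise with raw sd
  max(0.003, 0.01 m) — a conventional GC/MS repeatability scale — followed
  by renormalization to keep MIDs valid; rates carry 5% CV with a 1-unit
  floor.

Because renormalization makes channel errors correlated and slightly
heteroscedastic, the generator reports the first-order-propagated standard
deviation of each renormalized channel, sd^2 (1-m)^2 + m^2 (sum sd^2 - sd^2),
as the measurement sd. Weighting renormalized channels with the raw sds
demonstrably understates large-channel variance and led to under-covered
profile intervals in development; the propagated sds restore near-nominal
coverage while keeping the objective in the stated diagonal form. What the
generator does not emulate: chromatographic peak integration, fragment-
specific carbon subsets (whole molecules by default, though arbitrary
position sets are supported), inter-batch drift, and non-stationary
labeling. Passing tests therefore validate the inference machinery under
its stated error model, not instrument-specific artifacts.

## Fitting, inference, and the two-condition comparison

The objective is the variance-weighted sum of squared residuals over all
MID channels and rates, minimized over the free net fluxes and exchange
fluxes with bounded Levenberg-Marquardt. Multistart uses one deterministic
rate-preconditioned start (ridge-regularized linear solve of the rate
equations, which fixes most free coordinates near the data before the
nonlinear refinement) plus Latin-hypercube starts blended toward an
interior point found by penalized phase-1 search; all randomness flows from
the configured seed and reruns are bitwise identical. Bounds on dependent
fluxes enter as hinge penalty residuals, inactive at any feasible optimum.

Goodness of fit compares the SSR to a chi-square with dof = (independent
measurements) - (free parameters), where a renormalized MID of k channels
counts k - 1 (its unit sum makes one channel redundant) and a
non-renormalized MID counts k. On correctly specified data (Gaussian
channel noise without renormalization) the 5% rejection rate is recovered
(0.03-0.065 across generator seeds, 200 replicates). Under the default
renormalizing noise the test is only approximately calibrated — the known
cost of the diagonal error model.

Confidence intervals are one-parameter profile likelihoods: the target flux
(net value, or exchange magnitude) is stepped from its optimum with
geometric growth, re-optimizing all other parameters warm-started at each
step, and each crossing of SSR_min + qchisq(level, 1) is refined by
monotone interpolation to a tolerance of 1e-3 |flux| + 1e-3. Profiles that
never cross within the search range are reported open at the range limit
(the unidentifiable-flux case). Nesting of 80/90/95% intervals holds by
construction of the thresholds and is asserted in tests. Coverage of the
95% intervals on the packaged scenario lies within the 0.88-1.00 band for
every flux over 50 replicates (typically 0.90-0.98), measured by the
exactly equivalent profile-likelihood-ratio test at the ground truth (one
constrained re-optimization per flux, rather than two full interval
constructions).

Two conditions are compared on best-fit fold changes (knockdown / control),
with each flux classified by the highest level in {95, 90, 80} at which the
two profile intervals are disjoint, else "overlapping"; exchange fluxes are
compared on magnitudes, and near-zero or sign-crossing denominators yield
an undefined fold change with the direction taken from the values. In the
packaged scenario the one flux whose ground-truth ratio is exactly 1 (the
MDH exchange) is classified overlapping in 9 of 10 replicates, and every
separation of a truly changed flux carries the true direction.

## Problem sizes and numerical choices

The validation studies use the reduced fixture (12 reactions, 7 free
parameters): 50 replicates for coverage, 10 for the full interval/
classification study, 200 for the chi-square calibration on a three-carbon
mixing toy, and 5 x 50 draws for oracle equivalence. These sizes give
stable rates (binomial sd of a 95% proportion at 50 replicates is 3%)
while keeping the whole suite within a routine local run. Dense linear
algebra throughout; rational arithmetic only where exactness matters (the
null-space basis); LM tolerances 1e-12, profile refinement as above.
Degenerate inputs are handled explicitly: zero-influx target EMUs error by
name, infeasible bounds return a violated-constraint certificate, and
over-parameterized fits (dof < 1) refuse a p-value.

## Known limitations

Single-pool compartments; no confidence intervals by Monte-Carlo or
Bayesian sampling (profile likelihood only); diagonal measurement
covariance (see above); tracer purity defaults to 1 and natural abundance
of the tracer substrate itself is not modeled; no non-stationary (time-
resolved) mode; no tandem-MS positional isotopomer output.
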