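# toy networks built in code, shared across tests

# linear chain: in -> A -> B -> out, 2 carbons, identity maps
chain_net <- function() parse_network(c(
  "METABOLITE\tin.x\t2\tsource",
  "METABOLITE\tA\t2\tbalanced",
  "METABOLITE\tB\t2\tbalanced",
  "METABOLITE\tout.x\t2\tsink",
  "REACTION\tUP\tirr\tin.x (ab) -> A (ab)",
  "REACTION\tAB\tirr\tA (ab) -> B (ab)",
  "REACTION\tOUT\tirr\tB (ab) -> out.x (ab)"))

# diamond: A -> B -> D and A -> C -> D, with uptake and output
diamond_net <- function() parse_network(c(
  "METABOLITE\tin.x\t2\tsource",
  "METABOLITE\tA\t2\tbalanced",
  "METABOLITE\tB\t2\tbalanced",
  "METABOLITE\tC\t2\tbalanced",
  "METABOLITE\tD\t2\tbalanced",
  "METABOLITE\tout.x\t2\tsink",
  "REACTION\tUP\tirr\tin.x (ab) -> A (ab)",
  "REACTION\tAB\tirr\tA (ab) -> B (ab)",
  "REACTION\tAC\tirr\tA (ab) -> C (ba)",
  "REACTION\tBD\tirr\tB (ab) -> D (ab)",
  "REACTION\tCD\tirr\tC (ab) -> D (ab)",
  "REACTION\tOUT\tirr\tD (ab) -> out.x (ab)"))

# cleavage: C3 -> C2 + C1
cleave_net <- function() parse_network(c(
  "METABOLITE\tC.x\t3\tsource",
  "METABOLITE\tC\t3\tbalanced",
  "METABOLITE\tA\t2\tbalanced",
  "METABOLITE\tB\t1\tbalanced",
  "METABOLITE\tA.x\t2\tsink",
  "METABOLITE\tB.x\t1\tsink",
  "REACTION\tUP\tirr\tC.x (abc) -> C (abc)",
  "REACTION\tCLV\tirr\tC (abc) -> A (ab) + B (c)",
  "REACTION\tAOUT\tirr\tA (ab) -> A.x (ab)",
  "REACTION\tBOUT\tirr\tB (a) -> B.x (a)"))

# condensation + reversible step + symmetric map: stresses the EMU path
condense_net <- function() parse_network(c(
  "METABOLITE\tA.x\t2\tsource",
  "METABOLITE\tB.x\t1\tsource",
  "METABOLITE\tP\t3\tbalanced",
  "METABOLITE\tQ\t3\tbalanced",
  "METABOLITE\tQ.x\t3\tsink",
  "REACTION\tCND\tirr\tA.x (ab) + B.x (c) -> P (abc)",
  "REACTION\tISO\trev\tP (abc) -> Q (abc)",
  "MAP2\tP (abc) -> Q (cba)",
  "REACTION\tOUT\tirr\tQ (abc) -> Q.x (abc)"))

# branch with recombination and a cycle through a reversible exchange
cycle_net <- function() parse_network(c(
  "METABOLITE\tS.x\t3\tsource",
  "METABOLITE\tU\t3\tbalanced",
  "METABOLITE\tV\t2\tbalanced",
  "METABOLITE\tW\t3\tbalanced",
  "METABOLITE\tco2\t1\tsource",
  "METABOLITE\tW.x\t3\tsink",
  "REACTION\tUP\tirr\tS.x (abc) -> U (abc)",
  "REACTION\tDC\tirr\tU (abc) -> V (bc) + co2 (a)",
  "REACTION\tCB\tirr\tV (ab) + co2 (c) -> W (abc)",
  "REACTION\tWU\trev\tW (abc) -> U (abc)",
  "REACTION\tOUT\tirr\tW (abc) -> W.x (abc)"))

# three-carbon mixing toy with a condensation; used for the chi-square
# calibration study (channels well away from 0 and 1)
mixing_toy <- function() parse_network(c(
  "METABOLITE\tA.x\t3\tsource",
  "METABOLITE\tB.x\t3\tsource",
  "METABOLITE\tC\t3\tbalanced",
  "METABOLITE\tF\t6\tbalanced",
  "METABOLITE\tE.x\t3\tsink",
  "METABOLITE\tF.x\t6\tsink",
  "REACTION\tR1\tirr\tA.x (abc) -> C (abc)",
  "REACTION\tR2\tirr\tB.x (abc) -> C (abc)",
  "REACTION\tRF\tirr\tC (abc) + C (def) -> F (abcdef)",
  "REACTION\tR3\tirr\tC (abc) -> E.x (abc)",
  "REACTION\tRFO\tirr\tF (abcdef) -> F.x (abcdef)"))

mixing_toy_scenario <- function(replicates, seed, renormalize = TRUE) {
  list(network = mixing_toy(),
       base_flux = list(net = c(R1 = 50, R2 = 50, RF = 30, R3 = 40,
                                RFO = 30), exchange = NULL),
       conditions = list(only = list()),
       experiments = list(mix = list(tracer_spec(
         "A.x", list("100", "110", "111"), fraction = c(.25, .25, .25)))),
       measured_mids = c("C", "F"),
       measured_rates = c(a_uptake = "R1", e_out = "R3", f_out = "RFO"),
       noise = list(mid_sd_floor = 0.003, mid_sd_rel = 0.01,
                    rate_cv = 0.05, rate_floor = 1,
                    renormalize = renormalize),
       replicates = replicates, seed = seed)
}

# random feasible flux vector for a network (uniform free coordinates,
# retried until bounds hold)
random_flux <- function(net, decomp = build_stoichiometry(net),
                        fmax = 10, exch_max = 5) {
  rids <- rownames(decomp$free_basis)
  rev_ids <- rids[vapply(net$reactions, `[[`, TRUE, "reversible")]
  repeat {
    theta <- stats::runif(decomp$free_count, 0.1, fmax)
    v <- drop(decomp$free_basis %*% theta)
    names(v) <- rids
    irr <- setdiff(rids, rev_ids)
    if (all(v[irr] >= 0.01)) break
  }
  exch <- stats::setNames(stats::runif(length(rev_ids), 0, exch_max), rev_ids)
  structure(list(net = v, exchange = exch), class = "flux_vector")
}

# tracer pulling positions from a fixed pattern set for a source metabolite
random_tracer <- function(net, met) {
  n <- met_carbons(net, met)
  pat <- paste(sample(c("0", "1"), n, replace = TRUE), collapse = "")
  frac <- stats::runif(1, 0.3, 1)
  tracer_spec(met, pat, fraction = frac)
}
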