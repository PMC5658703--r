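test_that("total label enrichment and normalized fractions", {
  r <- total_label_enrichment(c(0.5, 0.25, 0.25))
  expect_equal(r$sigma_m, 0.5)
  expect_equal(unname(r$normalized), c(0.5, 0.5))
  expect_equal(sum(r$normalized), 1)

  r0 <- total_label_enrichment(c(1, 0))
  expect_equal(r0$sigma_m, 0)
  expect_length(r0$normalized, 0)

  # switchable denominator including m0
  rm0 <- total_label_enrichment(c(0.5, 0.25, 0.25), include_m0 = TRUE)
  expect_equal(unname(rm0$normalized), c(0.25, 0.25))
})

test_that("oxidative simulation: normalized m4 citrate dominates", {
  sc <- default_scenario()
  ds <- generate_dataset(sc)
  net <- ds$network
  em <- emu_decompose(net, whole_molecule_targets(net, "cit"))
  mids <- simulate_mids(em, ds$conditions$control$truth,
                        sc$experiments$gln)
  tle <- total_label_enrichment(mid_of(mids, "cit"))
  expect_equal(unname(which.max(tle$normalized)), 4)
  # oxidative signature (m4) dominates the reductive one (m5)
  expect_gt(tle$normalized[["m4"]], tle$normalized[["m5"]])
})

test_that("m-ratio channel comparisons", {
  m <- c(0.3, 0.2, 0.5)
  expect_equal(m_ratio(m, m, 2), 1)
  expect_equal(m_ratio(c(1, 0, 0), m, 2), 0)
  expect_error(m_ratio(m, c(1, 0, 0), 2), "undefined")
  expect_error(m_ratio(c(1, 0), m, 2), "not present")
})

test_that("m2 citrate over m2 pyruvate rises with the PDH flux share", {
  # single-pass condensation with a competing unlabeled acetyl source:
  # the m2 ratio tracks the share of acetyl-CoA drawn through PDH
  net <- parse_network(c(
    "METABOLITE\tpyr.x\t3\tsource",
    "METABOLITE\tac.x\t2\tsource",
    "METABOLITE\toaa.x\t4\tsource",
    "METABOLITE\tpyr\t3\tbalanced",
    "METABOLITE\taccoa\t2\tbalanced",
    "METABOLITE\tcit\t6\tbalanced",
    "METABOLITE\tcit.x\t6\tsink",
    "METABOLITE\tco2\t1\tsource",
    "REACTION\tPYRUP\tirr\tpyr.x (abc) -> pyr (abc)",
    "REACTION\tPDH\tirr\tpyr (abc) -> accoa (bc) + co2 (a)",
    "REACTION\tACS\tirr\tac.x (ab) -> accoa (ab)",
    "REACTION\tCS\tirr\taccoa (ab) + oaa.x (cdef) -> cit (abcdef)",
    "REACTION\tCITOUT\tirr\tcit (abcdef) -> cit.x (abcdef)"))
  tr <- list(tracer_spec("pyr.x", "011"))  # doubly labeled pyruvate
  em <- emu_decompose(net, whole_molecule_targets(net, c("cit", "pyr")))
  ratios <- sapply(c(0.2, 0.5, 0.8), function(phi) {
    v <- flux_vector(c(PYRUP = phi, PDH = phi, ACS = 1 - phi,
                       CS = 1, CITOUT = 1), network = net)
    mids <- simulate_mids(em, v, tr)
    m_ratio(mid_of(mids, "cit"), mid_of(mids, "pyr"), 2)
  })
  expect_true(all(diff(ratios) > 0))
  expect_equal(unname(ratios), c(0.2, 0.5, 0.8), tolerance = 1e-9)
})

test_that("extracellular rates from two-point time courses", {
  # no concentration change, no flux
  expect_equal(extracellular_rate(10, 10, 1, 1e6, 1e6, 24)$rate, 0)

  # constant 1e6 cells, 1 mL, 1 mM drop over 24 h
  r <- extracellular_rate(10, 9, 1, 1e6, 1e6, 24)
  expect_equal(r$rate, 1000 / 24, tolerance = 1e-12)
  expect_equal(r$direction, "consumption")

  # doubling culture: exponential cell integral matches quadrature
  n0 <- 1e6; nt <- 2e6; t <- 24
  mu <- log(nt / n0) / t
  quad <- stats::integrate(function(tau) n0 * exp(mu * tau), 0, t)$value
  r2 <- extracellular_rate(10, 7, 2, n0, nt, t)
  expect_equal(r2$rate, (10 - 7) * 2 * 1000 / (quad / 1e6),
               tolerance = 1e-3)

  # antisymmetry under swapping the two concentrations
  r3 <- extracellular_rate(7, 10, 2, n0, nt, t)
  expect_equal(r3$rate, -r2$rate)
  expect_equal(r3$direction, "production")

  expect_error(extracellular_rate(-1, 5, 1, 1e6, 1e6, 24), "non-negative")
  expect_error(extracellular_rate(5, 5, 1, 0, 1e6, 24), "positive")
})

test_that("amino-acid surplus against protein synthesis demand", {
  comp <- c(gln = 4, leu = 8, lys = 6)
  # uptake exactly matching demand: all surpluses zero
  up <- 10 * comp
  bal <- amino_acid_balance_check(up, 10, comp)
  expect_equal(bal$surplus, rep(0, 3))
  # zero protein flux: surplus equals uptake
  bal0 <- amino_acid_balance_check(up, 0, comp)
  expect_equal(bal0$surplus, unname(up))
  expect_error(amino_acid_balance_check(c(val = 5), 1, comp), "missing")

  # knockdown-style scenario: control uptake matched to protein demand,
  # the knockdown condition takes up extra glutamine-family carbon
  sc <- default_scenario()
  ds <- generate_dataset(sc)
  ctrl_gln <- ds$conditions$control$truth$net[["GLNUP"]]
  kd_gln <- ds$conditions$kd$truth$net[["GLNUP"]]
  comp2 <- c(gln = ctrl_gln / 10)
  kd_bal <- amino_acid_balance_check(c(gln = kd_gln), 10, comp2)
  expect_equal(amino_acid_balance_check(c(gln = ctrl_gln), 10,
                                        comp2)$surplus, 0)
  expect_gt(kd_bal$surplus, 0)
})
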