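test_that("parser builds networks and preserves declaration order", {
  net <- parse_network(c(
    "METABOLITE\tA\t2\tsource",
    "METABOLITE\tB\t2\tsink",
    "REACTION\tR1\tirr\tA (ab) -> B (ab)"))
  expect_s3_class(net, "flux_network")
  expect_equal(nrow(net$metabolites), 2)
  expect_equal(length(net$reactions), 1)
  expect_equal(net$metabolites$id, c("A", "B"))
})

test_that("parse errors name the offending line", {
  expect_error(parse_network(c(
    "METABOLITE\tA\t2\tsource",
    "REACTION\tR1\tirr\tA (ab) -> B (ab)")), "line 2.*unknown metabolite")
  expect_error(parse_network(c(
    "METABOLITE\tA\t2\tsource",
    "METABOLITE\tB\t1\tsink",
    "REACTION\tR1\tirr\tA (ab) -> B (ab)")), "line 3.*2 letters.*1 carbons")
  expect_error(parse_network(c(
    "METABOLITE\tA\t2\tsource",
    "METABOLITE\tB\t2\tsink",
    "REACTION\tR1\tirr\tA (ab) -> B (ab)",
    "REACTION\tR1\tirr\tA (ab) -> B (ab)")), "line 4.*duplicate reaction")
  expect_error(parse_network("  \n  "), "empty")
})

test_that("carbon loss without an absorbing sink is a violation", {
  # B declared 1-carbon, no sink absorbs the second carbon of A
  net <- parse_network(c(
    "METABOLITE\tA\t2\tsource",
    "METABOLITE\tB\t1\tbalanced",
    "METABOLITE\tB.x\t1\tsink",
    "REACTION\tR1\tirr\tA (ab) -> B (a)",
    "REACTION\tR2\tirr\tB (a) -> B.x (a)"))
  v <- validate_atom_balance(net)
  expect_true(any(grepl("unaccounted", v$problem)))
})

test_that("writer round-trips through the parser", {
  for (nm in c("hct116_central_carbon", "tca_reduced",
               "tca_first_turn_oxidative")) {
    net <- example_network(nm)
    net2 <- parse_network(write_network(net))
    expect_equal(net2$metabolites, net$metabolites)
    expect_equal(net2$reactions, net$reactions)
    expect_equal(net2$annotations, net$annotations)
    # and the canonical text is a fixed point of write/parse/write
    expect_identical(write_network(net2), write_network(net))
  }
})

test_that("atom-balance validation passes fixtures and flags bad weights", {
  for (nm in c("hct116_central_carbon", "tca_reduced",
               "tca_first_turn_oxidative", "tca_first_turn_reductive",
               "glycolysis_only"))
    expect_equal(nrow(validate_atom_balance(example_network(nm))), 0)

  # symmetric double map with equal weights is legal
  net <- condense_net()
  expect_equal(nrow(validate_atom_balance(net)), 0)

  # tampered weights 0.5/0.6 are caught
  bad <- net
  bad$reactions$ISO$transitions[[2]]$weight <- 0.6
  v <- validate_atom_balance(bad)
  expect_true(any(grepl("weights sum", v$problem)))
})

test_that("stoichiometric decomposition: free counts and exact null space", {
  expect_equal(build_stoichiometry(chain_net())$free_count, 1)
  expect_equal(build_stoichiometry(diamond_net())$free_count, 2)

  for (nm in c("hct116_central_carbon", "tca_reduced")) {
    d <- build_stoichiometry(example_network(nm))
    # rational rank oracle agrees with the decomposition
    expect_equal(d$rank, rational_rank(d$S))
    expect_equal(d$free_count, ncol(d$S) - rational_rank(d$S))
    # exact integer-scaled basis: S %*% basis is exactly zero
    expect_identical(max(abs(d$S %*% d$free_basis_exact)), 0)
    # floating basis columns are unit at the free reactions
    expect_equal(unname(d$free_basis[d$free_reactions, ]),
                 diag(d$free_count))
  }
})

test_that("structurally dead pools are reported by name", {
  net <- parse_network(c(
    "METABOLITE\tA.x\t1\tsource",
    "METABOLITE\tB\t1\tbalanced",
    "METABOLITE\tC\t1\tbalanced",
    "METABOLITE\tC.x\t1\tsink",
    "REACTION\tR1\tirr\tA.x (a) -> B (a)",
    "REACTION\tR2\tirr\tB (a) -> C.x (a)",
    "REACTION\tR3\tirr\tC (a) -> C.x (a)"))
  expect_error(build_stoichiometry(net), "dead network.*'C'")
})

test_that("apply_bounds finds interior points and certifies infeasibility", {
  net <- chain_net()
  d <- build_stoichiometry(net)
  # uptake pinned to 10 determines the whole chain
  rep <- apply_bounds(d, bounds = list(UP = c(10, 10)), net = net)
  expect_true(rep$feasible)
  expect_equal(unname(rep$flux), rep(10, 3), tolerance = 1e-6)
  expect_lt(max(abs(d$S %*% rep$flux)), 1e-9 * max(abs(rep$flux)))

  # contradictory bounds on the same determined flux
  rep2 <- apply_bounds(d, bounds = list(UP = c(5, 6), OUT = c(7, 8)),
                       net = net)
  expect_false(rep2$feasible)
  expect_gt(nrow(rep2$violations), 0)

  # fixture with glucose uptake pinned near a physiological value
  netf <- example_network("tca_reduced")
  df <- build_stoichiometry(netf)
  repf <- apply_bounds(df, bounds = list(GLYC = c(150, 150)), net = netf)
  expect_true(repf$feasible)
  expect_equal(unname(repf$flux["GLYC"]), 150, tolerance = 1e-6)
  expect_lt(max(abs(df$S %*% repf$flux)), 1e-9 * max(abs(repf$flux)))
})

test_that("flux_vector enforces the reversibility contract", {
  net <- example_network("tca_reduced")
  expect_error(flux_vector(c(GLYC = -5), network = net),
               "names must match")
  v <- random_flux(net)
  dirs <- emuflux:::flux_directions(v)
  expect_true(all(dirs$forward >= 0) && all(dirs$backward >= 0))
  expect_equal(unname(dirs$forward - dirs$backward), unname(v$net))
})
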