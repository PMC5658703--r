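test_that("sample_base_fluxes matches anchors and steady state", {
  net <- chain_net()
  v <- sample_base_fluxes(net, c(UP = 10), seed = 1, vmax = 100)
  expect_equal(unname(v$net), rep(10, 3), tolerance = 1e-9)

  # same seed, same vector; different seed may move the free directions
  netf <- example_network("tca_reduced")
  v1 <- sample_base_fluxes(netf, c(GLYC = 150, GLNUP = 40), seed = 3)
  v2 <- sample_base_fluxes(netf, c(GLYC = 150, GLNUP = 40), seed = 3)
  expect_identical(v1$net, v2$net)

  d <- build_stoichiometry(netf)
  for (s in 1:25) {
    v <- sample_base_fluxes(netf, c(GLYC = 150, GLNUP = 40), seed = s)
    expect_lt(max(abs(d$S %*% v$net)), 1e-9 * max(abs(v$net)))
    expect_equal(unname(v$net["GLYC"]), 150, tolerance = 1e-9)
  }

  expect_error(sample_base_fluxes(netf, c(GLYC = -50), seed = 1),
               "infeasible")
})

test_that("make_condition re-projects onto the steady-state manifold", {
  net <- example_network("tca_reduced")
  base <- flux_vector(default_scenario()$base_flux$net,
                      exchange = default_scenario()$base_flux$exchange,
                      network = net)
  d <- build_stoichiometry(net)

  # identity multipliers leave the base untouched
  same <- make_condition(net, base, c(GLYC = 1, GLNUP = 1))
  expect_equal(same$net, base$net, tolerance = 1e-9)

  # raising glutamine uptake alone raises glutaminolysis strictly
  up <- make_condition(net, base, c(GLNUP = 1.5))
  expect_equal(unname(up$net["GLNUP"]), 60, tolerance = 1e-9)
  expect_gt(up$net[["GDH"]], base$net[["GDH"]])
  expect_lt(max(abs(d$S %*% up$net)), 1e-8 * max(abs(up$net)))

  # exchange multipliers act directly
  ex <- make_condition(net, base, exchange_multipliers = c(IDH = 2))
  expect_equal(unname(ex$exchange["IDH"]), 10)

  # removing an essential uptake is infeasible
  expect_error(make_condition(net, base, c(GLYC = 0)), "infeasible")
  expect_error(make_condition(net, base, c(GLYC = -1)), "positive")
})

test_that("generated data are exact at zero noise and reproducible", {
  sc0 <- default_scenario(noise = list(mid_sd_floor = 0, mid_sd_rel = 0,
                                       rate_cv = 0, rate_floor = 0))
  ds0 <- generate_dataset(sc0)
  net <- ds0$network
  em <- emu_decompose(net, lapply(sc0$measured_mids, function(m)
    list(met = m, positions = NULL)))
  clean <- simulate_mids(em, ds0$conditions$control$truth,
                         sc0$experiments$glc)
  m1 <- ds0$conditions$control$replicates[[1]]$mids[[1]]
  expect_identical(m1$mid, mid_of(clean, m1$met))
  r1 <- ds0$conditions$control$replicates[[1]]$rates[[1]]
  expect_identical(r1$value, ds0$conditions$control$truth$net[["GLYC"]])

  # regeneration with the same scenario and seed is bitwise identical
  sc <- default_scenario(replicates = 2, seed = 17)
  a <- generate_dataset(sc)
  b <- generate_dataset(sc)
  expect_identical(a$conditions$kd$replicates, b$conditions$kd$replicates)
  expect_identical(a$manifest$config_hash, b$manifest$config_hash)
})

test_that("channel noise is Gaussian at the reported sd", {
  # standardized residuals of generated channels against the noise-free
  # truth; channels with true fraction >= 0.02 (where the truncation at
  # zero is inactive) are pooled across replicates
  sc <- default_scenario(replicates = 40, seed = 31)
  ds <- generate_dataset(sc)
  net <- ds$network
  em <- emu_decompose(net, lapply(sc$measured_mids, function(m)
    list(met = m, positions = NULL)))
  clean <- list()
  for (e in names(sc$experiments))
    clean[[e]] <- simulate_mids(em, ds$conditions$control$truth,
                                sc$experiments[[e]])
  z <- numeric()
  for (rep in ds$conditions$control$replicates) {
    for (m in rep$mids) {
      truth <- mid_of(clean[[m$experiment]], m$met)
      keep <- truth >= 0.02
      z <- c(z, ((m$mid - truth) / m$sd)[keep])
    }
  }
  expect_gt(length(z), 900)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("measurement CSVs round-trip through the readers", {
  sc <- default_scenario(replicates = 2, seed = 19)
  ds <- generate_dataset(sc)
  dir <- tempfile("csvs_")
  write_measurement_csvs(ds, dir)
  back <- read_measurement_csvs(dir)
  orig <- ds$conditions$kd$replicates[[2]]
  got <- back$kd[[2]]
  expect_equal(length(got$mids), length(orig$mids))
  om <- orig$mids[[3]]; gm <- NULL
  for (m in got$mids)
    if (m$experiment == om$experiment && m$met == om$met && is.null(gm))
      gm <- m
  expect_equal(gm$mid, om$mid, tolerance = 1e-12)
  expect_equal(gm$sd, om$sd, tolerance = 1e-12)
  expect_equal(vapply(got$rates, `[[`, 0, "value"),
               vapply(orig$rates, `[[`, 0, "value"))
  unlink(dir, recursive = TRUE)
})
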