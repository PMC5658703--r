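test_that("EMU decomposition traces targets backward through atom maps", {
  # identity chain: target B{1,2} needs only B, fed from the source
  net <- chain_net()
  em <- emu_decompose(net, list(list(met = "B", positions = c(1, 2))))
  expect_setequal(names(em$balance), c("B#1,2", "A#1,2"))

  # cleavage: target A{1,2} needs no convolution; the C-derived B is size 1
  netc <- cleave_net()
  emc <- emu_decompose(netc, list(list(met = "A", positions = c(1, 2)),
                                  list(met = "B", positions = 1)))
  sizes <- vapply(emc$balance, `[[`, 0L, "size")
  expect_equal(unname(sizes[["B#1"]]), 1L)
  for (bal in emc$balance)
    for (tm in bal$terms)
      expect_lte(length(tm$sources), 1L)

  # citrate in the full fixture: citrate-synthase terms convolve an
  # oxaloacetate EMU with an acetyl-CoA EMU
  neth <- example_network("hct116_central_carbon")
  emh <- emu_decompose(neth, list(list(met = "cit", positions = NULL)))
  cs_terms <- Filter(function(t) t$rxn == "CS",
                     emh$balance[["cit#1,2,3,4,5,6"]]$terms)
  expect_gt(length(cs_terms), 0)
  for (tm in cs_terms) {
    mets <- sort(vapply(tm$sources, `[[`, "", "met"))
    expect_equal(mets, c("accoa", "oaa"))
  }

  # a target on a source metabolite is tracer-determined, not an unknown
  ems <- emu_decompose(net, list(list(met = "in.x", positions = NULL)))
  expect_true("in.x#1,2" %in% names(ems$determined))
})

test_that("convolution is the MID joining operation", {
  a <- c(0.2, 0.5, 0.3)
  expect_equal(convolve_mid(a, 1), a)
  expect_equal(convolve_mid(c(.5, .5), c(.5, .5)), c(.25, .5, .25))
  set.seed(1)
  for (i in 1:20) {
    x <- stats::runif(4); x <- x / sum(x)
    y <- stats::runif(3); y <- y / sum(y)
    z <- convolve_mid(x, y)
    expect_equal(sum(z), 1)
    expect_equal(mean_mass(z), mean_mass(x) + mean_mass(y))
  }
})

test_that("unlabeled feeds give unlabeled MIDs everywhere", {
  net <- example_network("tca_reduced")
  v <- random_flux(net)
  em <- emu_decompose(net, whole_molecule_targets(net))
  mids <- simulate_mids(em, v, list())
  for (id in names(em$balance)) {
    m <- mids[[id]]
    expect_equal(m[1], 1, tolerance = 1e-12)
    expect_equal(sum(m), 1, tolerance = 1e-9)
  }
})

test_that("single-turn oxidative TCA from uniformly labeled glutamine", {
  net <- example_network("tca_first_turn_oxidative")
  v <- flux_vector(c(GLS = 1, GDH = 1, AKGDH = 1, SDH = 1, MDH = 1,
                     CS = 0.5, CITOUT = 0.5, AST = 0.5, ASPOUT = 0.5),
                   network = net)
  em <- emu_decompose(net, whole_molecule_targets(
    net, c("glu", "akg", "mal", "oaa", "cit", "asp")))
  mids <- simulate_mids(em, v, list(tracer_spec("gln.x", "11111")))
  shift <- function(m) which.max(mid_of(mids, m)) - 1L
  # glutaminolysis carries all five carbons to glutamate and aKG
  expect_equal(shift("glu"), 5)
  expect_equal(shift("akg"), 5)
  # one decarboxylation leaves four labeled carbons downstream
  expect_equal(shift("mal"), 4)
  expect_equal(shift("asp"), 4)
  # citrate = labeled OAA + unlabeled acetyl
  expect_equal(shift("cit"), 4)
})

test_that("reductive carboxylation gives m5 citrate and m3 aspartate", {
  net <- example_network("tca_first_turn_reductive")
  v <- flux_vector(stats::setNames(rep(1, 7), names(net$reactions)),
                   network = net)
  em <- emu_decompose(net, whole_molecule_targets(
    net, c("cit", "asp", "accoa")))
  mids <- simulate_mids(em, v, list(tracer_spec("gln.x", "11111")))
  expect_equal(which.max(mid_of(mids, "cit")) - 1L, 5)
  expect_equal(which.max(mid_of(mids, "asp")) - 1L, 3)
  # the acetyl fragment carries the remaining two labeled carbons
  expect_equal(which.max(mid_of(mids, "accoa")) - 1L, 2)
})

test_that("positionally labeled glucose yields doubly labeled pyruvate", {
  net <- example_network("glycolysis_only")
  v <- flux_vector(c(GLYC = 1, PYROUT = 2), network = net)
  em <- emu_decompose(net, whole_molecule_targets(net, "pyr"))
  mids <- simulate_mids(em, v, list(tracer_spec("glc.x", "110000")))
  pyr <- mid_of(mids, "pyr")
  expect_equal(pyr, c(0.5, 0, 0.5, 0))
  expect_equal(which.max(pyr[-1]), 2)
})

test_that("MIDs are invariant under uniform flux scaling", {
  net <- example_network("tca_reduced")
  set.seed(7)
  v <- random_flux(net)
  em <- emu_decompose(net, whole_molecule_targets(net))
  tr <- standard_tracers("gln")
  m1 <- simulate_mids(em, v, tr)
  v2 <- structure(list(net = 3.7 * v$net, exchange = 3.7 * v$exchange),
                  class = "flux_vector")
  m2 <- simulate_mids(em, v2, tr)
  for (id in names(em$balance))
    expect_equal(m2[[id]], m1[[id]], tolerance = 1e-12)
})

test_that("label mass is conserved at every balanced pool", {
  net <- example_network("tca_reduced")
  set.seed(11)
  v <- random_flux(net)
  em <- emu_decompose(net, whole_molecule_targets(net))
  tr <- standard_tracers("gln")
  mids <- simulate_mids(em, v, tr)
  dirs <- emuflux:::flux_directions(v)
  carbons <- stats::setNames(net$metabolites$carbons, net$metabolites$id)
  for (id in names(em$balance)) {
    bal <- em$balance[[id]]
    if (bal$size != carbons[[bal$met]]) next  # whole molecules only
    influx <- 0; inmass <- 0
    for (tm in bal$terms) {
      f <- if (tm$dir == "f") dirs$forward[[tm$rxn]] else dirs$backward[[tm$rxn]]
      if (f <= 0) next
      fw <- f * tm$weight
      mm <- 0
      for (src in tm$sources) {
        sm <- if (src$known)
          emuflux:::.source_mid(src$met, src$positions, tr, carbons[[src$met]])
        else mids[[emuflux:::emu_id(src$met, src$positions)]]
        mm <- mm + mean_mass(sm)
      }
      influx <- influx + fw
      inmass <- inmass + fw * mm
    }
    expect_equal(inmass / influx, mean_mass(mids[[id]]), tolerance = 1e-9,
                 label = paste("label balance at", id))
  }
})

test_that("simulator rejects broken inputs by name", {
  net <- example_network("tca_reduced")
  em <- emu_decompose(net, whole_molecule_targets(net, "glu"))
  # zero influx to the glutamate pool
  v0 <- flux_vector(stats::setNames(rep(0, 12), names(net$reactions)),
                    network = net)
  expect_error(simulate_mids(em, v0, list()), "zero total influx")
  # backward flux on an irreversible reaction violates the split contract
  vneg <- random_flux(net)
  vneg$net[["GLYC"]] <- -5
  expect_error(simulate_mids(em, vneg, list()), "irreversible")
})
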