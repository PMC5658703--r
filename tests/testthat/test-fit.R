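# noise-free measurement set for the reduced fixture, with nominal sds
noise_free_data <- function(condition = "control") {
  sc <- default_scenario(replicates = 1, seed = 5,
                         noise = list(mid_sd_floor = 0, mid_sd_rel = 0,
                                      rate_cv = 0, rate_floor = 0))
  ds <- generate_dataset(sc)
  data <- ds$conditions[[condition]]$replicates[[1]]
  for (i in seq_along(data$mids))
    data$mids[[i]]$sd <- pmax(0.003, 0.01 * data$mids[[i]]$mid)
  for (i in seq_along(data$rates))
    data$rates[[i]]$sd <- max(0.05 * abs(data$rates[[i]]$value), 1)
  list(net = ds$network, data = data, experiments = ds$experiments,
       truth = ds$conditions[[condition]]$truth)
}

truth_par <- function(obj, truth) {
  stats::setNames(c(truth$net[obj$free_reactions],
                    truth$exchange[obj$rev_ids]), obj$par_names)
}

test_that("objective is zero at the generating point and quadratic nearby", {
  nf <- noise_free_data()
  obj <- make_objective(nf$net, nf$data, nf$experiments, fit_config())
  par0 <- truth_par(obj, nf$truth)
  expect_lt(objective_ssr(obj, par0), 1e-6)

  # perturbing one rate measurement by +2 sd raises the SSR at the same
  # point by 2^2 = 4
  data2 <- nf$data
  data2$rates[[3]]$value <- data2$rates[[3]]$value + 2 * data2$rates[[3]]$sd
  obj2 <- make_objective(nf$net, data2, nf$experiments, fit_config())
  expect_equal(objective_ssr(obj2, par0), 4, tolerance = 1e-6)

  # doubling every sd quarters the SSR
  data3 <- data2
  for (i in seq_along(data3$mids)) data3$mids[[i]]$sd <- 2 * data3$mids[[i]]$sd
  for (i in seq_along(data3$rates)) data3$rates[[i]]$sd <- 2 * data3$rates[[i]]$sd
  obj3 <- make_objective(nf$net, data3, nf$experiments, fit_config())
  expect_equal(objective_ssr(obj3, par0), 1, tolerance = 1e-6)
})

test_that("a rate-determined toy is fitted to its algebraic solution", {
  net <- chain_net()
  data <- measurement_set(rates = list(
    rate_measurement("uptake", 10, 0.5, coef = c(UP = 1))))
  fit <- fit_fluxes(net, data, experiments = list(),
                    config = fit_config(n_starts = 3, seed = 1, vmax = 100))
  expect_equal(unname(fit$flux$net), rep(10, 3), tolerance = 1e-6)
})

test_that("multistart fitting is deterministic given the seed", {
  nf <- noise_free_data()
  cfg <- fit_config(n_starts = 3, seed = 9)
  f1 <- fit_fluxes(nf$net, nf$data, nf$experiments, cfg)
  f2 <- fit_fluxes(nf$net, nf$data, nf$experiments, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$par, f2$par)
})

test_that("goodness of fit is a chi-square tail with guarded dof", {
  expect_equal(goodness_of_fit(list(ssr = 0, dof = 10)), 1)
  expect_error(goodness_of_fit(list(ssr = 1, dof = 0)),
               "over-parameterized")
})

test_that("profile intervals are nested across confidence levels", {
  sc <- default_scenario(replicates = 1, seed = 23)
  ds <- generate_dataset(sc)
  fit <- fit_fluxes(ds$network, ds$conditions$control$replicates[[1]],
                    ds$experiments, fit_config(n_starts = 3, seed = 4))
  for (spec in list(list(rxn = "GDH", type = "net"),
                    list(rxn = "IDH", type = "exchange"))) {
    ci <- profile_ci(fit, spec$rxn, levels = c(0.80, 0.90, 0.95),
                     type = spec$type)
    ci <- ci[order(ci$level), ]
    expect_true(all(diff(ci$lower) <= 1e-6))
    expect_true(all(diff(ci$upper) >= -1e-6))
    best <- if (spec$type == "net") fit$flux$net[[spec$rxn]]
            else fit$flux$exchange[[spec$rxn]]
    expect_true(all(ci$lower <= best + 1e-9 & best <= ci$upper + 1e-9))
  }
})

test_that("interval width shrinks as measurement error shrinks", {
  nf <- noise_free_data()
  widths <- sapply(c(0.02, 0.01, 0.005), function(sigma) {
    data <- nf$data
    for (i in seq_along(data$mids))
      data$mids[[i]]$sd <- rep(sigma, length(data$mids[[i]]$sd))
    fit <- fit_fluxes(nf$net, data, nf$experiments,
                      fit_config(n_starts = 2, seed = 3))
    ci <- profile_ci(fit, "GDH", levels = 0.95)
    ci$upper - ci$lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("an unidentifiable parallel pathway spans its whole range", {
  net <- parse_network(c(
    "METABOLITE\tA.x\t1\tsource",
    "METABOLITE\tB\t1\tbalanced",
    "METABOLITE\tB.x\t1\tsink",
    "REACTION\tR1\tirr\tA.x (a) -> B (a)",
    "REACTION\tR2\tirr\tA.x (a) -> B (a)",
    "REACTION\tOUT\tirr\tB (a) -> B.x (a)"))
  data <- measurement_set(rates = list(
    rate_measurement("out", 10, 0.5, coef = c(OUT = 1))))
  fit <- fit_fluxes(net, data, experiments = list(),
                    config = fit_config(n_starts = 2, seed = 1, vmax = 50))
  ci <- profile_ci(fit, "R1", levels = 0.95)
  # only the sum R1 + R2 is constrained; R1 roams from 0 to about the
  # total output before the positivity of R2 bites
  expect_lt(ci$lower, 0.5)
  expect_gt(ci$upper, 9)
})

test_that("condition comparison classifies by interval overlap", {
  fake_fit <- function(val) list(flux = list(net = c(R = val),
                                             exchange = numeric()))
  ci_tab <- function(lo, hi) do.call(rbind, lapply(c(.8, .9, .95),
    function(l) data.frame(reaction = "R", type = "net", level = l,
                           lower = lo, upper = hi,
                           lower_open = FALSE, upper_open = FALSE)))
  # identical fits: fold 1, overlapping
  cmp <- compare_conditions(fake_fit(1.5), ci_tab(1, 2),
                            fake_fit(1.5), ci_tab(1, 2))
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$classification, "overlapping")
  expect_equal(cmp$direction, "unchanged")
  # disjoint at every level: separated at 95
  cmp2 <- compare_conditions(fake_fit(1.5), ci_tab(1, 2),
                             fake_fit(3.5), ci_tab(3, 4))
  expect_equal(cmp2$classification, "separated_95")
  expect_equal(cmp2$direction, "up")
  expect_equal(cmp2$fold_change, 3.5 / 1.5)
  # near-zero denominator: fold change undefined, direction from values
  cmp3 <- compare_conditions(fake_fit(1e-9), ci_tab(-1, 1),
                             fake_fit(2), ci_tab(1.5, 2.5))
  expect_true(is.na(cmp3$fold_change))
  # mismatched reaction sets are rejected
  bad <- ci_tab(1, 2); bad$reaction <- "S"
  expect_error(compare_conditions(fake_fit(1), ci_tab(1, 2),
                                  fake_fit(1), bad), "mismatched")
})
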