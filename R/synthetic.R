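#' Synthetic two-condition, two-tracer datasets
#'
#' Generates measurement sets with the statistical structure the fit
#' assumes: steady-state ground-truth fluxes per condition, MIDs simulated
#' per tracer experiment with truncated-Gaussian channel noise
#' (renormalized to keep valid MIDs), and Gaussian noise on extracellular
#' rates. Ground truth is retained so recovery and coverage can be scored.
#'
#' @name synthetic_data
NULL

#' Sample a steady-state base flux vector matching anchors
#'
#' Anchored net fluxes are matched exactly; the remaining null-space freedom
#' is drawn by proposing uniform values for the free fluxes and projecting
#' onto the anchor constraints (closest point), retrying until all bounds
#' hold.
#'
#' @param net a validated `flux_network`
#' @param anchors named numeric of net-flux values to hold
#' @param seed RNG seed
#' @param bounds named list of `c(lo, hi)` overrides
#' @param exchange named numeric of exchange fluxes for reversible
#'   reactions (defaults to 0)
#' @param vmax default bound magnitude
#' @param max_tries proposal cap
#' @return a `flux_vector`
#' @export
sample_base_fluxes <- function(net, anchors, seed = 1, bounds = list(),
                               exchange = NULL, vmax = 2000,
                               max_tries = 500) {
  decomp <- build_stoichiometry(net)
  B <- decomp$free_basis
  rids <- rownames(B)
  bnds <- default_bounds(net, vmax = vmax)
  for (nm in names(bounds)) bnds[[nm]] <- bounds[[nm]]
  lo <- vapply(rids, function(r) bnds[[r]][1], 0)
  hi <- vapply(rids, function(r) bnds[[r]][2], 0)
  bad <- setdiff(names(anchors), rids)
  if (length(bad)) stop("anchors on unknown reactions: ", paste(bad, collapse = ", "))
  C <- B[names(anchors), , drop = FALSE]
  a <- unname(anchors)
  set.seed(seed)
  frees <- decomp$free_reactions
  k <- length(frees)
  # pseudo-inverse handles redundant (consistent) anchor sets
  sv <- svd(C)
  pos <- sv$d > 1e-10 * max(sv$d, 1)
  Cpinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  theta0 <- drop(Cpinv %*% a)
  if (max(abs(drop(C %*% theta0) - a)) > 1e-6 * max(1, max(abs(a))))
    stop("anchors are infeasible: inconsistent with steady state; ",
         "closest achievable values: ",
         paste(sprintf("%s=%.3g", names(anchors), drop(C %*% theta0)),
               collapse = ", "))
  for (try in seq_len(max_tries)) {
    u <- stats::runif(k, lo[frees], hi[frees])
    theta <- u + drop(Cpinv %*% (a - drop(C %*% u)))
    v <- drop(B %*% theta)
    names(v) <- rids
    tol <- 1e-9 * max(1, max(abs(v)))
    if (all(v >= lo - tol & v <= hi + tol)) {
      rev_ids <- rids[vapply(net$reactions, `[[`, TRUE, "reversible")]
      exch <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
      if (!is.null(exchange)) exch[names(exchange)] <- exchange
      return(structure(list(net = v, exchange = exch), class = "flux_vector"))
    }
  }
  rep <- apply_bounds(decomp, bounds = c(
    stats::setNames(lapply(names(anchors), function(n)
      c(anchors[[n]], anchors[[n]])), names(anchors)), bounds), net = net)
  if (!rep$feasible)
    stop("anchors are infeasible; violated constraints:\n",
         paste(utils::capture.output(print(rep$violations)), collapse = "\n"))
  rev_ids <- rids[vapply(net$reactions, `[[`, TRUE, "reversible")]
  exch <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
  if (!is.null(exchange)) exch[names(exchange)] <- exchange
  structure(list(net = rep$flux, exchange = exch), class = "flux_vector")
}

#' Derive a perturbed condition from a base flux vector
#'
#' Multiplies the selected net fluxes, then re-projects onto the
#' steady-state manifold holding the multiplied fluxes fixed (the remaining
#' coordinates move as little as possible from the base, in least squares).
#' Exchange multipliers act directly on the exchange fluxes.
#'
#' @param net a validated `flux_network`
#' @param base a `flux_vector`
#' @param multipliers named positive factors on net fluxes
#' @param exchange_multipliers named positive factors on exchange fluxes
#' @param bounds named list of `c(lo, hi)` overrides
#' @param vmax default bound magnitude
#' @return a `flux_vector`
#' @export
make_condition <- function(net, base, multipliers = NULL,
                           exchange_multipliers = NULL, bounds = list(),
                           vmax = 2000) {
  if (!is.null(multipliers) && any(multipliers < 0))
    stop("multipliers must be positive")
  decomp <- build_stoichiometry(net)
  B <- decomp$free_basis
  rids <- rownames(B)
  vnew <- base$net
  if (length(multipliers)) {
    targets <- base$net[names(multipliers)] * multipliers
    C <- B[names(multipliers), , drop = FALSE]
    # minimize |B theta - base| s.t. C theta = targets (KKT system)
    BtB <- crossprod(B)
    K <- rbind(cbind(BtB, t(C)),
               cbind(C, matrix(0, nrow(C), nrow(C))))
    rhs <- c(crossprod(B, base$net), unname(targets))
    sol <- tryCatch(solve(K, rhs), error = function(e)
      stop("projection infeasible: singular constraint system"))
    theta <- sol[seq_len(ncol(B))]
    vnew <- drop(B %*% theta)
    names(vnew) <- rids
  }
  bnds <- default_bounds(net, vmax = vmax)
  for (nm in names(bounds)) bnds[[nm]] <- bounds[[nm]]
  lo <- vapply(rids, function(r) bnds[[r]][1], 0)
  hi <- vapply(rids, function(r) bnds[[r]][2], 0)
  tol <- 1e-6 * max(1, max(abs(vnew)))
  viol <- which(vnew < lo - tol | vnew > hi + tol)
  if (length(viol))
    stop("projection infeasible; bound violations: ",
         paste(sprintf("%s=%.3g", rids[viol], vnew[viol]), collapse = ", "))
  exch <- base$exchange
  if (length(exchange_multipliers)) {
    if (any(exchange_multipliers < 0)) stop("multipliers must be positive")
    exch[names(exchange_multipliers)] <-
      exch[names(exchange_multipliers)] * exchange_multipliers
  }
  structure(list(net = vnew, exchange = exch), class = "flux_vector")
}

#' The packaged control-vs-knockdown scenario
#'
#' Two conditions on the reduced network: a control condition with
#' literature-scale uptake and secretion rates for a proliferating
#' colorectal carcinoma line, and a knockdown condition shifted toward
#' higher glutamine uptake and oxidation (glutamine uptake and glutamate
#' dehydrogenase x1.5, reductive IDH exchange x2, glucose uptake and
#' lactate output x1.3). Both tracer experiments (positionally labeled
#' glucose; uniformly labeled glutamine) are measured on citrate,
#' alpha-ketoglutarate, malate, secreted lactate and aspartate, plus five
#' extracellular rates.
#'
#' @param replicates replicate measurement sets per condition
#' @param seed root seed for all generator randomness
#' @param noise list: `mid_sd_floor`, `mid_sd_rel`, `rate_cv`, `rate_floor`
#'   (set all to zero for noise-free data)
#' @return scenario list consumed by [generate_dataset()]
#' @export
default_scenario <- function(replicates = 1, seed = 17,
                             noise = list(mid_sd_floor = 0.003,
                                          mid_sd_rel = 0.01,
                                          rate_cv = 0.05,
                                          rate_floor = 1)) {
  control <- list(
    net = c(GLYC = 150, LDH = 240, PDH = 50, PC = 10, CS = 50, IDH = 50,
            AKGDH = 75, MDH = 75, GLNUP = 40, GDH = 25, GLUOUT = 15,
            ASPOUT = 35),
    exchange = c(IDH = 5, MDH = 100))
  list(network = "tca_reduced",
       base_flux = control,
       conditions = list(
         control = list(),
         kd = list(multipliers = c(GLNUP = 1.5, GDH = 1.5, GLYC = 1.3,
                                   LDH = 1.3),
                   exchange_multipliers = c(IDH = 2))),
       experiments = list(glc = standard_tracers("glc"),
                          gln = standard_tracers("gln")),
       measured_mids = c("cit", "akg", "mal", "lac.x", "asp.x"),
       measured_rates = c(glucose_uptake = "GLYC",
                          lactate_production = "LDH",
                          glutamine_uptake = "GLNUP",
                          glutamate_production = "GLUOUT",
                          aspartate_production = "ASPOUT"),
       noise = noise,
       replicates = replicates,
       seed = seed)
}

#' Generate a synthetic dataset from a scenario
#'
#' @param scenario list as produced by [default_scenario()]; `network` may
#'   be a fixture name or a `flux_network`
#' @return a `synthetic_dataset`: per condition the ground-truth
#'   `flux_vector` (`$truth`) and a list of replicate `measurement_set`s
#'   (`$replicates`); plus `$network`, `$experiments` and a `$manifest`
#'   (seed, config hash). Regeneration with the same scenario is
#'   deterministic.
#' @export
generate_dataset <- function(scenario) {
  net <- scenario$network
  if (is.character(net)) net <- example_network(net)
  base <- flux_vector(scenario$base_flux$net,
                      exchange = scenario$base_flux$exchange, network = net)
  noise <- scenario$noise
  truths <- list()
  for (cn in names(scenario$conditions)) {
    cc <- scenario$conditions[[cn]]
    truths[[cn]] <- if (length(cc$multipliers) || length(cc$exchange_multipliers))
      make_condition(net, base, cc$multipliers, cc$exchange_multipliers)
    else base
  }
  targets <- lapply(scenario$measured_mids, function(m)
    list(met = m, positions = NULL))
  emunets <- lapply(scenario$experiments, function(tr)
    emu_decompose(net, targets))
  set.seed(scenario$seed)
  out <- list()
  for (cn in names(truths)) {
    truth <- truths[[cn]]
    clean_mids <- list()
    for (e in names(emunets))
      clean_mids[[e]] <- simulate_mids(emunets[[e]], truth,
                                       scenario$experiments[[e]])
    reps <- list()
    for (rep in seq_len(scenario$replicates)) {
      mids <- list()
      for (e in names(emunets)) {
        for (m in scenario$measured_mids) {
          truemid <- mid_of(clean_mids[[e]], m)
          sd <- pmax(noise$mid_sd_floor, noise$mid_sd_rel * truemid)
          renorm <- !isFALSE(noise$renormalize)
          if (noise$mid_sd_floor > 0 || noise$mid_sd_rel > 0) {
            noisy <- truemid + stats::rnorm(length(truemid), 0, sd)
            if (renorm) {
              noisy <- pmax(0, noisy)
              noisy <- noisy / sum(noisy)
            }
          } else noisy <- truemid
          # reported sd of a renormalized channel: first-order propagation
          # of r_i = e_i - m_i * sum(e) through the unit-sum normalization
          sdrep <- if (renorm)
            sqrt(sd^2 * (1 - truemid)^2 +
                 truemid^2 * (sum(sd^2) - sd^2)) else sd
          mids[[length(mids) + 1L]] <-
            mid_measurement(e, m, noisy, pmax(sdrep, 1e-6),
                            renormalized = renorm)
        }
      }
      rates <- list()
      for (nm in names(scenario$measured_rates)) {
        rxn <- scenario$measured_rates[[nm]]
        truev <- truth$net[[rxn]]
        sd <- max(noise$rate_cv * abs(truev), noise$rate_floor)
        val <- if (noise$rate_cv > 0 || noise$rate_floor > 0)
          truev + stats::rnorm(1, 0, sd) else truev
        rates[[length(rates) + 1L]] <-
          rate_measurement(nm, val, max(sd, 1e-6),
                           coef = stats::setNames(1, rxn))
      }
      reps[[rep]] <- measurement_set(mids, rates)
    }
    out[[cn]] <- list(truth = truth, replicates = reps)
  }
  structure(list(conditions = out, network = net,
                 experiments = scenario$experiments,
                 manifest = list(seed = scenario$seed,
                                 config_hash = .hash_object(scenario),
                                 replicates = scenario$replicates)),
            class = "synthetic_dataset")
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write a synthetic dataset to tidy CSV files
#'
#' Emits `mids.csv` (condition, replicate, experiment, metabolite, channel,
#' value, sd) and `rates.csv` (condition, replicate, name, reaction, value,
#' sd) — the same schemas the pipeline ingests.
#'
#' @param dataset a `synthetic_dataset`
#' @param dir output directory (created if needed)
#' @return invisible character vector of the written paths
#' @export
write_measurement_csvs <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  midrows <- list(); raterows <- list()
  for (cn in names(dataset$conditions)) {
    reps <- dataset$conditions[[cn]]$replicates
    for (ri in seq_along(reps)) {
      ms <- reps[[ri]]
      for (m in ms$mids)
        midrows[[length(midrows) + 1L]] <- data.frame(
          condition = cn, replicate = ri, experiment = m$experiment,
          metabolite = m$met, channel = seq_along(m$mid) - 1L,
          value = m$mid, sd = m$sd, stringsAsFactors = FALSE)
      for (r in ms$rates)
        raterows[[length(raterows) + 1L]] <- data.frame(
          condition = cn, replicate = ri, name = r$name,
          reaction = names(r$coef)[1], value = r$value, sd = r$sd,
          stringsAsFactors = FALSE)
    }
  }
  p1 <- file.path(dir, "mids.csv"); p2 <- file.path(dir, "rates.csv")
  utils::write.csv(do.call(rbind, midrows), p1, row.names = FALSE)
  utils::write.csv(do.call(rbind, raterows), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read measurement CSVs back into measurement sets
#' @param dir directory containing `mids.csv` and `rates.csv`
#' @return nested list: condition -> replicate -> `measurement_set`
#' @export
read_measurement_csvs <- function(dir) {
  mids <- utils::read.csv(file.path(dir, "mids.csv"), stringsAsFactors = FALSE)
  rates <- utils::read.csv(file.path(dir, "rates.csv"), stringsAsFactors = FALSE)
  out <- list()
  for (cn in unique(mids$condition)) {
    out[[cn]] <- list()
    for (ri in sort(unique(mids$replicate[mids$condition == cn]))) {
      mm <- mids[mids$condition == cn & mids$replicate == ri, ]
      rr <- rates[rates$condition == cn & rates$replicate == ri, ]
      midlist <- list()
      for (key in unique(paste(mm$experiment, mm$metabolite))) {
        sub <- mm[paste(mm$experiment, mm$metabolite) == key, ]
        sub <- sub[order(sub$channel), ]
        midlist[[length(midlist) + 1L]] <-
          mid_measurement(sub$experiment[1], sub$metabolite[1],
                          sub$value, sub$sd)
      }
      ratelist <- lapply(seq_len(nrow(rr)), function(i)
        rate_measurement(rr$name[i], rr$value[i], rr$sd[i],
                         coef = stats::setNames(1, rr$reaction[i])))
      out[[cn]][[ri]] <- measurement_set(midlist, ratelist)
    }
  }
  out
}
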