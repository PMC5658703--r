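#' Orchestrated analysis runs
#'
#' `run_analysis()` executes the full pipeline on a validated configuration:
#' obtain data (generate a synthetic scenario or read measurement CSVs),
#' compute descriptive label statistics, fit each condition, derive profile
#' confidence intervals, compare conditions, and write the result tables
#' with a reproducibility manifest. Every stage draws its randomness from a
#' seed derived from the root seed, so a rerun with the same configuration
#' produces identical files.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param scenario a scenario list ([default_scenario()]) for synthetic
#'   input, or NULL when reading measurements
#' @param measurements_dir directory with `mids.csv`/`rates.csv` (used when
#'   `scenario` is NULL; the network and tracers must then be given)
#' @param network fixture name or `flux_network` (defaults to the
#'   scenario's)
#' @param experiments named list of tracer lists (defaults to the
#'   scenario's)
#' @param out_dir output directory
#' @param seed root seed
#' @param n_starts multistart count per condition fit
#' @param ci_levels confidence levels (subset of 0.80/0.90/0.95)
#' @param ci_reactions reactions to profile (default: free net fluxes plus
#'   all exchange fluxes)
#' @param sigma_floor MID standard-deviation floor used in validation
#' @return a `run_config` list
#' @export
run_config <- function(scenario = NULL, measurements_dir = NULL,
                       network = NULL, experiments = NULL,
                       out_dir = tempfile("emuflux_run_"), seed = 1,
                       n_starts = 8, ci_levels = c(0.80, 0.90, 0.95),
                       ci_reactions = NULL, sigma_floor = 0.003) {
  structure(list(scenario = scenario, measurements_dir = measurements_dir,
                 network = network, experiments = experiments,
                 out_dir = out_dir, seed = seed, n_starts = n_starts,
                 ci_levels = ci_levels, ci_reactions = ci_reactions,
                 sigma_floor = sigma_floor),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror [run_config()]; `scenario: default` loads the
#' packaged control-vs-knockdown scenario, with optional `replicates` and
#' `scenario_seed` overrides.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (identical(y$scenario, "default")) {
    scenario <- default_scenario(
      replicates = if (!is.null(y$replicates)) y$replicates else 1,
      seed = if (!is.null(y$scenario_seed)) y$scenario_seed else 17)
  }
  run_config(scenario = scenario,
             measurements_dir = y$measurements_dir,
             network = y$network,
             out_dir = if (!is.null(y$out_dir)) y$out_dir else tempfile("emuflux_run_"),
             seed = if (!is.null(y$seed)) y$seed else 1,
             n_starts = if (!is.null(y$n_starts)) y$n_starts else 8,
             ci_levels = if (!is.null(y$ci_levels)) as.numeric(y$ci_levels)
                         else c(0.80, 0.90, 0.95))
}

#' Validate a run configuration
#'
#' @param config a `run_config`
#' @return character vector of issues; empty when runnable
#' @export
validate_config <- function(config) {
  issues <- character()
  allowed <- c(0.80, 0.90, 0.95)
  if (length(config$ci_levels) == 0 ||
      any(!vapply(config$ci_levels, function(l)
        any(abs(l - allowed) < 1e-9), TRUE)))
    issues <- c(issues, paste("ci_levels must be a subset of",
                              paste(allowed, collapse = "/")))
  if (is.null(config$scenario) && is.null(config$measurements_dir))
    issues <- c(issues, "either a scenario or a measurements_dir is required")
  if (!is.null(config$measurements_dir) && is.null(config$scenario)) {
    if (!dir.exists(config$measurements_dir))
      issues <- c(issues, paste("measurements_dir does not exist:",
                                config$measurements_dir))
    if (is.null(config$network))
      issues <- c(issues, "network required when reading measurements")
    if (is.null(config$experiments))
      issues <- c(issues, "experiments (tracers) required when reading measurements")
  }
  if (!is.null(config$sigma_floor) && config$sigma_floor <= 0)
    issues <- c(issues, "sigma_floor must be positive")
  sc <- config$scenario
  if (!is.null(sc)) {
    net <- sc$network
    if (is.character(net))
      net <- tryCatch(example_network(net), error = function(e) NULL)
    if (is.null(net)) issues <- c(issues, "scenario network not found")
    else {
      for (e in names(sc$experiments)) for (tr in sc$experiments[[e]]) {
        nc <- tryCatch(met_carbons(net, tr$substrate), error = function(e) NA)
        if (is.na(nc))
          issues <- c(issues, paste("tracer substrate not in network:",
                                    tr$substrate))
        else for (p in tr$pattern) if (nchar(p) != nc)
          issues <- c(issues, sprintf(
            "tracer pattern length %d != %d carbons of %s",
            nchar(p), nc, tr$substrate))
      }
    }
    if (!is.null(sc$noise$mid_sd_floor) && sc$noise$mid_sd_floor < 0)
      issues <- c(issues, "noise sd floor must be >= 0")
  }
  issues
}

#' Run the full analysis pipeline
#'
#' Stages (each aborts the run with a stage-named error on failure):
#' `load`, `data`, `descriptives`, `fit`, `ci`, `compare`, `report`.
#'
#' @param config a `run_config`
#' @return a `run_report`: list of result tables (`fluxes`, `cis`,
#'   `comparison`, `descriptives`) and the `manifest`; tables are also
#'   written to `config$out_dir` as TSV plus `manifest.json`
#' @export
run_analysis <- function(config) {
  issues <- validate_config(config)
  if (length(issues))
    stop("stage [validate]: ", paste(issues, collapse = "; "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  net <- stage("load", {
    n <- if (!is.null(config$network)) config$network else config$scenario$network
    if (is.character(n)) n <- example_network(n)
    stopifnot(nrow(validate_atom_balance(n)) == 0)
    n
  })
  dat <- stage("data", {
    if (!is.null(config$scenario)) {
      ds <- generate_dataset(config$scenario)
      list(sets = lapply(ds$conditions, function(cc) cc$replicates[[1]]),
           experiments = ds$experiments, dataset = ds)
    } else {
      sets <- read_measurement_csvs(config$measurements_dir)
      list(sets = lapply(sets, function(reps) reps[[1]]),
           experiments = config$experiments, dataset = NULL)
    }
  })
  for (cn in names(dat$sets)) {
    exps_needed <- unique(vapply(dat$sets[[cn]]$mids, `[[`, "", "experiment"))
    if (!all(exps_needed %in% names(dat$experiments)))
      stop("stage [data]: missing tracer specification for condition ", cn)
  }

  desc <- stage("descriptives", {
    rows <- list()
    for (cn in names(dat$sets)) {
      ms <- dat$sets[[cn]]
      for (m in ms$mids) {
        tle <- total_label_enrichment(m$mid)
        for (k in seq_along(tle$normalized))
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cn, experiment = m$experiment, metabolite = m$met,
            statistic = paste0("sigma_m_norm_m", k),
            value = unname(tle$normalized[k]), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, experiment = m$experiment, metabolite = m$met,
          statistic = "sigma_m", value = tle$sigma_m,
          stringsAsFactors = FALSE)
      }
      for (r in ms$rates)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, experiment = "", metabolite = r$name,
          statistic = "rate", value = r$value, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  fits <- stage("fit", {
    out <- list()
    i <- 0
    for (cn in names(dat$sets)) {
      i <- i + 1
      cfg <- fit_config(n_starts = config$n_starts,
                        seed = config$seed * 1000L + i)
      out[[cn]] <- fit_fluxes(net, dat$sets[[cn]], dat$experiments, cfg)
    }
    out
  })

  cis <- stage("ci", {
    out <- list()
    for (cn in names(fits)) {
      fit <- fits[[cn]]
      rxns <- config$ci_reactions
      if (is.null(rxns)) {
        rxns <- c(fit$objective$free_reactions, fit$objective$rev_ids)
        types <- c(rep("net", length(fit$objective$free_reactions)),
                   rep("exchange", length(fit$objective$rev_ids)))
      } else types <- rep("net", length(rxns))
      ci <- profile_ci_all(fit, rxns = rxns, types = types,
                           levels = config$ci_levels)
      ci$condition <- cn
      out[[cn]] <- ci
    }
    out
  })

  comparison <- NULL
  if (length(fits) == 2) {
    comparison <- stage("compare", {
      cns <- names(fits)
      compare_conditions(fits[[cns[1]]], cis[[cns[1]]],
                         fits[[cns[2]]], cis[[cns[2]]])
    })
  }

  report <- stage("report", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fluxtab <- do.call(rbind, lapply(names(fits), function(cn) {
      f <- fits[[cn]]$flux
      data.frame(condition = cn, reaction = names(f$net),
                 net = unname(f$net),
                 exchange = unname(f$exchange[names(f$net)]),
                 stringsAsFactors = FALSE)
    }))
    citab <- do.call(rbind, cis)
    paths <- c(fluxes = file.path(config$out_dir, "fluxes.tsv"),
               cis = file.path(config$out_dir, "confidence_intervals.tsv"),
               descriptives = file.path(config$out_dir, "descriptives.tsv"))
    utils::write.table(fluxtab, paths["fluxes"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(citab, paths["cis"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(desc, paths["descriptives"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(comparison)) {
      paths["comparison"] <- file.path(config$out_dir, "comparison.tsv")
      utils::write.table(comparison, paths["comparison"], sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    manifest <- list(
      seed = config$seed,
      config_hash = .hash_object(unclass(config)),
      package_version = as.character(utils::packageVersion("emuflux")),
      fit = lapply(fits, function(f)
        list(ssr = f$ssr, dof = f$dof, p_value = f$p_value)),
      files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))))
    mpath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(tables = list(fluxes = fluxtab, cis = citab,
                       comparison = comparison, descriptives = desc),
         manifest = manifest, paths = c(paths, manifest = mpath))
  })

  structure(list(fluxes = report$tables$fluxes, cis = report$tables$cis,
                 comparison = report$tables$comparison,
                 descriptives = report$tables$descriptives,
                 fits = fits, manifest = report$manifest,
                 paths = report$paths),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", length(x$fits), "condition(s) fitted; outputs:\n")
  for (p in x$paths) cat("  ", p, "\n")
  invisible(x)
}
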