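#' Flux estimation by variance-weighted least squares
#'
#' Free fluxes (null-space coordinates of the stoichiometric matrix, plus
#' one exchange flux per reversible reaction) are fitted to MID and rate
#' measurements by minimizing the weighted sum of squared residuals
#' SSR = sum(((predicted - measured) / sd)^2) with bounded
#' Levenberg-Marquardt from multiple Latin-hypercube starts. Confidence
#' intervals come from the profile likelihood: a flux is stepped away from
#' its optimum, all other parameters re-optimized, and the interval bounded
#' where SSR crosses SSR_min + qchisq(level, 1).
#'
#' @name flux_estimation
NULL

#' Default fitting configuration
#' @param n_starts multistart count
#' @param seed RNG seed (all randomness in the fit flows from it)
#' @param bounds named list of `c(lo, hi)` overrides per reaction
#' @param exch_max upper bound for exchange fluxes
#' @param vmax default net-flux magnitude cap
#' @param maxiter Levenberg-Marquardt iteration cap
#' @param penalty_weight weight of the hinge residuals keeping dependent
#'   fluxes inside their bounds
#' @return config list
#' @export
fit_config <- function(n_starts = 20, seed = 1, bounds = list(),
                       exch_max = 500, vmax = 2000, maxiter = 120,
                       penalty_weight = 100) {
  list(n_starts = n_starts, seed = seed, bounds = bounds,
       exch_max = exch_max, vmax = vmax, maxiter = maxiter,
       penalty_weight = penalty_weight)
}

#' Build the fit objective for a network and data set
#'
#' Precomputes the stoichiometric decomposition, one EMU decomposition per
#' tracer experiment (covering the measured fragments), and returns closures
#' evaluating the residual vector and SSR. Exposed mainly for testing; the
#' fitting entry point is [fit_fluxes()].
#'
#' @param net a validated `flux_network`
#' @param data a `measurement_set`
#' @param experiments named list: experiment label -> list of
#'   [tracer_spec()]
#' @param config from [fit_config()]
#' @return a `flux_objective` (list of closures and metadata)
#' @export
make_objective <- function(net, data, experiments, config = fit_config()) {
  decomp <- build_stoichiometry(net)
  rids <- rownames(decomp$free_basis)
  B <- decomp$free_basis
  bnds <- default_bounds(net, vmax = config$vmax)
  for (nm in names(config$bounds)) bnds[[nm]] <- config$bounds[[nm]]
  lo <- vapply(rids, function(r) bnds[[r]][1], 0)
  hi <- vapply(rids, function(r) bnds[[r]][2], 0)
  rev_ids <- rids[vapply(net$reactions, `[[`, TRUE, "reversible")]
  frees <- decomp$free_reactions
  npar <- length(frees) + length(rev_ids)
  par_names <- c(frees, if (length(rev_ids)) paste0(rev_ids, ".exch"))
  par_lo <- c(lo[frees], rep(0, length(rev_ids)))
  par_hi <- c(hi[frees], rep(config$exch_max, length(rev_ids)))
  names(par_lo) <- names(par_hi) <- par_names

  exps <- unique(vapply(data$mids, `[[`, "", "experiment"))
  missing <- setdiff(exps, names(experiments))
  if (length(missing))
    stop("no tracer specification for experiment(s): ",
         paste(missing, collapse = ", "))
  emunets <- list()
  for (e in exps) {
    tg <- list()
    for (m in data$mids) if (m$experiment == e)
      tg[[length(tg) + 1L]] <- list(met = m$met, positions = m$positions)
    emunets[[e]] <- emu_decompose(net, tg)
  }
  mid_keys <- lapply(data$mids, function(m) {
    pos <- if (is.null(m$positions)) seq_len(met_carbons(net, m$met))
           else sort(m$positions)
    emu_id(m$met, pos)
  })

  n_mid_ch <- sum(vapply(data$mids, function(m) length(m$mid), 0L))
  n_rate <- length(data$rates)
  n_data <- n_mid_ch + n_rate
  idx_data <- seq_len(n_data)

  unpack <- function(par) {
    theta <- par[seq_along(frees)]
    exch <- par[length(frees) + seq_along(rev_ids)]
    names(exch) <- rev_ids
    vnet <- drop(B %*% theta)
    names(vnet) <- rids
    list(vnet = vnet, exch = exch)
  }

  resid_fun <- function(par, fix = NULL) {
    p <- unpack(par)
    vnet <- p$vnet
    # clamp for simulation only: irreversible nets floored at 0
    irr <- setdiff(rids, rev_ids)
    vsim <- vnet
    vsim[irr] <- pmax(vsim[irr], 0)
    v <- structure(list(net = vsim, exchange = p$exch), class = "flux_vector")
    out <- numeric(0)
    ok <- TRUE
    mids_by_exp <- list()
    for (e in names(emunets)) {
      mids_by_exp[[e]] <- tryCatch(
        simulate_mids(emunets[[e]], v, experiments[[e]]),
        error = function(err) NULL)
      if (is.null(mids_by_exp[[e]])) { ok <- FALSE; break }
    }
    if (!ok) {
      out <- rep(1e4, n_data)
    } else {
      for (i in seq_along(data$mids)) {
        m <- data$mids[[i]]
        pred <- mids_by_exp[[m$experiment]][[mid_keys[[i]]]]
        out <- c(out, (pred - m$mid) / m$sd)
      }
      for (r in data$rates) {
        pred <- sum(r$coef * vnet[names(r$coef)])
        out <- c(out, (pred - r$value) / r$sd)
      }
    }
    scale <- pmax(1, pmax(abs(lo), abs(hi)))
    pen <- config$penalty_weight *
      (pmax(lo - vnet, 0) + pmax(vnet - hi, 0)) / scale
    out <- c(out, pen)
    if (!is.null(fix)) {
      val <- if (fix$type == "net") vnet[[fix$rxn]] else p$exch[[fix$rxn]]
      sd_fix <- 1e-6 * max(1, abs(fix$value))
      out <- c(out, (val - fix$value) / sd_fix)
    }
    out
  }

  ssr_fun <- function(par) sum(resid_fun(par)[idx_data]^2)

  structure(list(net = net, data = data, experiments = experiments,
                 config = config, decomp = decomp,
                 free_reactions = frees, rev_ids = rev_ids,
                 par_names = par_names, par_lo = par_lo, par_hi = par_hi,
                 npar = npar, idx_data = idx_data,
                 n_meas = n_independent_measurements(data),
                 resid_fun = resid_fun, ssr_fun = ssr_fun,
                 unpack = unpack, lo = lo, hi = hi),
            class = "flux_objective")
}

#' Weighted SSR of a candidate flux parameterization
#' @param obj a `flux_objective`
#' @param par parameter vector (free net fluxes then exchange fluxes)
#' @return SSR over the data residuals
#' @export
objective_ssr <- function(obj, par) obj$ssr_fun(par)

.lm_optimize <- function(obj, start, fix = NULL, maxiter = NULL) {
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = if (is.null(maxiter)) obj$config$maxiter else maxiter,
    ftol = 1e-12, ptol = 1e-12)
  # iteration-cap warnings are expected while profiling flat directions;
  # convergence state is retained in `info`
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = start, lower = obj$par_lo,
                       upper = obj$par_hi,
                       fn = function(p) obj$resid_fun(p, fix = fix),
                       control = ctrl))
  list(par = fit$par, ssr = sum(obj$resid_fun(fit$par, fix = fix)[obj$idx_data]^2),
       info = fit$info)
}

# deterministic start from the linear rate equations: solve
# min |W (A theta - y)|^2 + ridge toward the interior point, clip to bounds
.rate_preconditioned_start <- function(obj, theta_int) {
  rates <- obj$data$rates
  frees <- obj$free_reactions
  B <- obj$decomp$free_basis
  if (length(rates)) {
    A <- do.call(rbind, lapply(rates, function(r)
      drop(r$coef %*% B[names(r$coef), , drop = FALSE]) / r$sd))
    y <- vapply(rates, function(r) r$value / r$sd, 0)
    lam <- 1e-6 * max(1, sum(A^2))
    theta <- tryCatch(
      drop(solve(crossprod(A) + lam * diag(ncol(A)),
                 crossprod(A, y) + lam * theta_int)),
      error = function(e) theta_int)
  } else theta <- theta_int
  k <- length(frees)
  theta <- pmin(pmax(theta, obj$par_lo[seq_len(k)]), obj$par_hi[seq_len(k)])
  exch0 <- pmin(0.05 * max(1, max(abs(theta))), obj$par_hi[-seq_len(k)])
  stats::setNames(c(theta, exch0), obj$par_names)
}

# deterministic Latin-hypercube starts blended toward an interior point;
# the first start is rate-preconditioned
.multistart_points <- function(obj, n_starts, seed) {
  set.seed(seed)
  k <- obj$npar
  H <- lhs::randomLHS(n_starts, k)
  ip <- apply_bounds(obj$decomp, bounds = stats::setNames(
    lapply(seq_along(obj$lo), function(i) c(obj$lo[i], obj$hi[i])),
    names(obj$lo)))
  theta_int <- if (ip$feasible) ip$flux[obj$free_reactions]
               else (obj$par_lo[seq_along(obj$free_reactions)] +
                     obj$par_hi[seq_along(obj$free_reactions)]) / 2
  int_pt <- c(theta_int, rep(1, obj$npar - length(theta_int)))
  starts <- vector("list", n_starts)
  starts[[1]] <- .rate_preconditioned_start(obj, theta_int)
  for (s in seq_len(n_starts)[-1]) {
    raw <- obj$par_lo + H[s, ] * (obj$par_hi - obj$par_lo)
    # pull toward the interior point until dependent fluxes are near-feasible
    alpha <- 1
    repeat {
      cand <- alpha * raw + (1 - alpha) * int_pt
      v <- obj$unpack(cand)$vnet
      viol <- max(c(obj$lo - v, v - obj$hi, 0))
      if (viol <= 1e-6 * max(1, max(abs(v))) || alpha < 1e-3) break
      alpha <- alpha / 2
    }
    starts[[s]] <- cand
  }
  starts
}

#' Fit free fluxes to measurements
#'
#' @inheritParams make_objective
#' @param config from [fit_config()]
#' @return a `fit_result`: best-fit `flux_vector` (`$flux`), parameter
#'   vector (`$par`), `$ssr`, `$dof`, `$p_value`, per-measurement residual
#'   table (`$residuals`), multistart trace (`$trace`), and the objective
#'   (`$objective`) for downstream profiling
#' @export
fit_fluxes <- function(net, data, experiments, config = fit_config()) {
  obj <- make_objective(net, data, experiments, config)
  starts <- .multistart_points(obj, config$n_starts, config$seed)
  trace <- data.frame(start = integer(), ssr = numeric(), info = integer())
  best <- NULL
  for (s in seq_along(starts)) {
    r <- tryCatch(.lm_optimize(obj, starts[[s]]), error = function(e) NULL)
    if (is.null(r)) {
      trace <- rbind(trace, data.frame(start = s, ssr = NA_real_, info = -1L))
      next
    }
    trace <- rbind(trace, data.frame(start = s, ssr = r$ssr, info = r$info))
    if (is.null(best) || r$ssr < best$ssr) best <- r
  }
  if (is.null(best))
    stop("all multistart fits failed; per-start diagnostics:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))
  p <- obj$unpack(best$par)
  flux <- structure(list(net = p$vnet, exchange = p$exch),
                    class = "flux_vector")
  dof <- obj$n_meas - obj$npar
  res <- obj$resid_fun(best$par)[obj$idx_data]
  labels <- c(unlist(lapply(obj$data$mids, function(m)
    paste0(m$experiment, ":", m$met, ":m", seq_along(m$mid) - 1L))),
    vapply(obj$data$rates, `[[`, "", "name"))
  structure(list(flux = flux, par = best$par, ssr = best$ssr, dof = dof,
                 p_value = if (dof >= 1)
                   stats::pchisq(best$ssr, dof, lower.tail = FALSE)
                 else NA_real_,
                 residuals = data.frame(measurement = labels,
                                        weighted_residual = res),
                 trace = trace, objective = obj, config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> SSR = %.4g, dof = %d, chi-square p = %.3g\n",
              x$ssr, x$dof, x$p_value))
  invisible(x)
}

#' Chi-square goodness of fit
#'
#' Upper-tail probability of the best-fit SSR under the chi-square
#' distribution with `dof` degrees of freedom; small p indicates the model
#' cannot reproduce the data at the stated measurement error.
#'
#' @param fit a `fit_result` (or a list with `ssr` and `dof`)
#' @return p-value
#' @export
goodness_of_fit <- function(fit) {
  if (fit$dof < 1) stop("over-parameterized fit: dof = ", fit$dof)
  stats::pchisq(fit$ssr, fit$dof, lower.tail = FALSE)
}

#' Profile-likelihood ratio statistic at a fixed flux value
#'
#' Re-optimizes all other parameters with the target flux held at `value`
#' and returns SSR(value) - SSR_min. The value lies inside the profile
#' confidence interval at `level` iff the statistic is below
#' `qchisq(level, 1)`.
#'
#' @param fit a `fit_result`
#' @param rxn reaction id
#' @param value flux value at which to evaluate the profile
#' @param type `"net"` or `"exchange"`
#' @param start optional warm-start parameter vector
#' @return list: `stat`, `ssr`, `par` (re-optimized parameters)
#' @export
profile_lr_stat <- function(fit, rxn, value, type = "net", start = NULL) {
  obj <- fit$objective
  fix <- list(type = type, rxn = rxn, value = value)
  st <- if (is.null(start)) fit$par else start
  r <- .lm_optimize(obj, st, fix = fix, maxiter = 60)
  ssr <- sum(obj$resid_fun(r$par)[obj$idx_data]^2)
  list(stat = ssr - fit$ssr, ssr = ssr, par = r$par)
}

#' Profile-likelihood confidence interval for one flux
#'
#' Parameter continuation: the target flux is stepped away from its best-fit
#' value with geometric step growth, re-optimizing all other parameters at
#' each step (warm-started), until the profile SSR exceeds the largest
#' requested threshold or the search range is exhausted. Each crossing is
#' then refined by monotone interpolation/bisection to a tolerance of
#' `1e-3 * |flux| + 1e-3`. Intervals at lower levels are nested inside
#' higher ones by construction of the thresholds.
#'
#' @param fit a `fit_result`
#' @param rxn reaction id
#' @param levels confidence levels (subset of 0.80/0.90/0.95 by convention,
#'   any value in (0,1) accepted)
#' @param type `"net"` or `"exchange"`
#' @param init_step initial continuation step (default 5% of the flux
#'   magnitude)
#' @param max_steps continuation step cap per direction
#' @return data.frame (reaction, type, level, lower, upper, lower_open,
#'   upper_open); open flags mark bounds truncated at the search range
#' @export
profile_ci <- function(fit, rxn, levels = c(0.80, 0.90, 0.95), type = "net",
                       init_step = NULL, max_steps = 40) {
  obj <- fit$objective
  levels <- sort(levels)
  thr <- stats::qchisq(levels, 1)
  if (type == "net") {
    best_val <- fit$flux$net[[rxn]]
    range <- c(obj$lo[[rxn]], obj$hi[[rxn]])
  } else {
    if (!rxn %in% obj$rev_ids) stop(rxn, " has no exchange flux")
    best_val <- fit$flux$exchange[[rxn]]
    range <- c(0, obj$config$exch_max)
  }
  scale <- max(abs(best_val), 1)
  step0 <- if (is.null(init_step)) 0.05 * scale else init_step
  tol <- 1e-3 * abs(best_val) + 1e-3

  profile_one <- function(target, start) {
    r <- profile_lr_stat(fit, rxn, target, type = type, start = start)
    r
  }

  trace_dir <- function(sgn) {
    lim <- if (sgn > 0) range[2] else range[1]
    vals <- best_val; stats <- 0
    par <- fit$par
    step <- step0
    repeat {
      nxt <- vals[length(vals)] + sgn * step
      hit_lim <- (sgn > 0 && nxt >= lim) || (sgn < 0 && nxt <= lim)
      if (hit_lim) nxt <- lim
      r <- profile_one(nxt, par)
      par <- r$par
      vals <- c(vals, nxt); stats <- c(stats, max(r$stat, 0))
      if (r$stat > max(thr) || hit_lim || length(vals) > max_steps) break
      step <- step * 1.7
    }
    list(vals = vals, stats = stats, par = par,
         exhausted = stats[length(stats)] <= max(thr))
  }

  refine <- function(tr, sgn, th) {
    # first index where the profile exceeds th
    i <- which(tr$stats > th)[1]
    if (is.na(i)) return(list(bound = tr$vals[length(tr$vals)], open = TRUE))
    a <- tr$vals[i - 1]; fa <- tr$stats[i - 1]
    b <- tr$vals[i];     fb <- tr$stats[i]
    par <- tr$par
    for (it in 1:12) {
      if (abs(b - a) <= tol) break
      # secant estimate clipped to the bracket middle half
      m <- a + (th - fa) / (fb - fa) * (b - a)
      lo_m <- a + 0.25 * (b - a); hi_m <- a + 0.75 * (b - a)
      m <- min(max(m, lo_m), hi_m)
      r <- profile_one(m, par)
      par <- r$par
      if (r$stat > th) { b <- m; fb <- r$stat } else { a <- m; fa <- r$stat }
    }
    list(bound = (a + b) / 2, open = FALSE)
  }

  up <- trace_dir(+1)
  dn <- trace_dir(-1)
  out <- list()
  for (k in seq_along(levels)) {
    u <- refine(up, +1, thr[k])
    l <- refine(dn, -1, thr[k])
    out[[k]] <- data.frame(reaction = rxn, type = type, level = levels[k],
                           lower = min(l$bound, best_val),
                           upper = max(u$bound, best_val),
                           lower_open = l$open, upper_open = u$open)
  }
  do.call(rbind, out)
}

#' Profile CIs for many fluxes
#' @inheritParams profile_ci
#' @param rxns reaction ids (default: the free net fluxes)
#' @param types parallel vector of `"net"`/`"exchange"` (recycled)
#' @return row-bound data.frame of [profile_ci()] results
#' @export
profile_ci_all <- function(fit, rxns = NULL, types = "net",
                           levels = c(0.80, 0.90, 0.95), ...) {
  if (is.null(rxns)) rxns <- fit$objective$free_reactions
  types <- rep_len(types, length(rxns))
  do.call(rbind, lapply(seq_along(rxns), function(i)
    profile_ci(fit, rxns[i], levels = levels, type = types[i], ...)))
}

#' Compare fitted fluxes between two conditions
#'
#' Fold changes are ratios of best-fit values (condition B over condition
#' A); each reaction is classified by the highest confidence level in
#' (0.95, 0.90, 0.80) at which the two conditions' profile intervals are
#' disjoint, else `"overlapping"`. Net-flux fold changes carry a sign
#' guard: when the denominator is near zero or the signs differ the fold
#' change is NA and the direction comes from the flux values. Exchange
#' fluxes are compared on their (non-negative) magnitudes.
#'
#' @param fitA,fitB `fit_result`s for the two conditions (A = reference)
#' @param cisA,cisB data.frames from [profile_ci_all()] with matching
#'   reactions/types/levels
#' @param eps denominator threshold for the fold-change sign guard
#' @return a `comparison_result` data.frame: reaction, type, fold_change,
#'   classification, direction
#' @export
compare_conditions <- function(fitA, cisA, fitB, cisB, eps = 1e-6) {
  keyA <- unique(cisA[, c("reaction", "type")])
  keyB <- unique(cisB[, c("reaction", "type")])
  if (!identical(keyA[order(keyA$reaction, keyA$type), ],
                 keyB[order(keyB$reaction, keyB$type), ]))
    stop("mismatched reaction sets between conditions")
  if (!setequal(names(fitA$flux$net), names(fitB$flux$net)))
    stop("mismatched reaction sets between fits")
  out <- list()
  for (i in seq_len(nrow(keyA))) {
    rxn <- keyA$reaction[i]; tp <- keyA$type[i]
    a <- if (tp == "net") fitA$flux$net[[rxn]] else fitA$flux$exchange[[rxn]]
    b <- if (tp == "net") fitB$flux$net[[rxn]] else fitB$flux$exchange[[rxn]]
    fold <- if (abs(a) < eps || (tp == "net" && sign(a) != sign(b) && abs(b) >= eps))
      NA_real_ else b / a
    cls <- "overlapping"
    for (lv in c(0.95, 0.90, 0.80)) {
      ia <- cisA[cisA$reaction == rxn & cisA$type == tp & cisA$level == lv, ]
      ib <- cisB[cisB$reaction == rxn & cisB$type == tp & cisB$level == lv, ]
      if (!nrow(ia) || !nrow(ib)) next
      disjoint <- ia$upper < ib$lower || ib$upper < ia$lower
      if (disjoint) { cls <- sprintf("separated_%02d", round(lv * 100)); break }
    }
    direction <- if (cls == "overlapping") "unchanged"
                 else if (b > a) "up" else "down"
    out[[i]] <- data.frame(reaction = rxn, type = tp, fold_change = fold,
                           classification = cls, direction = direction,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("comparison_result", class(res))
  res
}
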