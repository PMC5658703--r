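#' Brute-force positional-isotopomer steady state
#'
#' Independent oracle for the EMU simulator. Maintains the full positional
#' isotopomer distribution (2^n states for an n-carbon metabolite) of every
#' balanced and atom-mapped sink metabolite and iterates the flux-weighted
#' balance x_M = sum_r f_r w_r (induced isotopomer distribution) / F_M with
#' Gauss-Seidel sweeps until stationary, then marginalizes to MIDs by
#' labeled-carbon count. Deliberately shares no code with the EMU path.
#'
#' @param net a validated `flux_network`
#' @param v a `flux_vector`
#' @param tracers list of [tracer_spec()] objects
#' @param max_joint cap on the joint substrate state space per reaction
#'   instance (refuses larger enumerations)
#' @param tol convergence tolerance on the max absolute change per sweep
#' @param maxit maximum sweeps
#' @return named list metabolite -> MID vector
#' @export
brute_force_isotopomers <- function(net, v, tracers, max_joint = 2^16,
                                    tol = 1e-13, maxit = 50000) {
  fwd <- pmax(v$net, 0); bwd <- pmax(-v$net, 0)
  if (length(v$exchange)) {
    fwd[names(v$exchange)] <- fwd[names(v$exchange)] + v$exchange
    bwd[names(v$exchange)] <- bwd[names(v$exchange)] + v$exchange
  }
  carbons <- stats::setNames(net$metabolites$carbons, net$metabolites$id)
  roles <- stats::setNames(net$metabolites$role, net$metabolites$id)

  # source isotopomer distributions
  src_dist <- function(met) {
    n <- carbons[[met]]
    d <- numeric(2^n); d[1] <- 1
    for (tr in tracers) {
      if (tr$substrate != met) next
      d[] <- 0
      for (comp in .tracer_components(tr)) {
        idx <- sum(2^(comp$positions - 1)) + 1L
        d[idx] <- d[idx] + comp$fraction
      }
    }
    d
  }

  tracked <- net$metabolites$id[roles %in% c("balanced", "sink") & carbons > 0]
  # a sink is tracked only if some producing map covers it
  state <- list()
  for (m in tracked) state[[m]] <- c(1, numeric(2^carbons[[m]] - 1))

  # precompute producing terms: per tracked metabolite a list of
  # (flux id, dir, weight, substrate mets, per-product-position source)
  terms <- stats::setNames(vector("list", length(tracked)), tracked)
  for (r in net$reactions) {
    dirs <- if (r$reversible) c("f", "b") else "f"
    for (d in dirs) {
      for (tr in r$transitions) {
        subs <- if (d == "f") tr$subs else tr$prods
        prods <- if (d == "f") tr$prods else tr$subs
        submets <- vapply(subs, `[[`, "", "met")
        for (pt in prods) {
          if (!pt$met %in% tracked || is.null(pt$letters)) next
          np <- length(pt$letters)
          src_inst <- integer(np); src_pos <- integer(np)
          ok <- TRUE
          for (p in seq_len(np)) {
            found <- FALSE
            for (si in seq_along(subs)) {
              q <- match(pt$letters[p], subs[[si]]$letters)
              if (!is.na(q)) { src_inst[p] <- si; src_pos[p] <- q; found <- TRUE; break }
            }
            if (!found) { ok <- FALSE; break }
          }
          if (!ok) next
          involved <- sort(unique(src_inst))
          ns <- vapply(involved, function(si) length(subs[[si]]$letters), 0L)
          if (prod(2^ns) > max_joint)
            stop("isotopomer state-space cap exceeded for reaction ", r$id)
          # joint index: involved[1] varies fastest
          offs <- cumprod(c(1, 2^ns))[seq_along(involved)]
          joint <- seq_len(prod(2^ns)) - 1L
          pstate <- integer(length(joint))
          for (p in seq_len(np)) {
            k <- match(src_inst[p], involved)
            local <- (joint %/% offs[k]) %% (2^ns[k])
            bit <- (local %/% 2^(src_pos[p] - 1L)) %% 2L
            pstate <- pstate + bit * 2L^(p - 1L)
          }
          terms[[pt$met]][[length(terms[[pt$met]]) + 1L]] <- list(
            rxn = r$id, dir = d, weight = tr$weight,
            sub_mets = submets[involved], idx = pstate + 1L,
            nstates = 2L^np)
        }
      }
    }
  }

  get_dist <- function(met) {
    if (roles[[met]] == "source") src_dist(met) else state[[met]]
  }

  order_mets <- tracked[order(vapply(tracked, function(m) carbons[[m]], 0L))]
  for (it in seq_len(maxit)) {
    delta <- 0
    for (m in order_mets) {
      if (is.null(terms[[m]])) next
      acc <- numeric(2^carbons[[m]])
      influx <- 0
      for (tm in terms[[m]]) {
        f <- if (tm$dir == "f") fwd[[tm$rxn]] else bwd[[tm$rxn]]
        if (f <= 0) next
        fw <- f * tm$weight
        influx <- influx + fw
        joint <- get_dist(tm$sub_mets[1])
        for (sm in tm$sub_mets[-1])
          joint <- as.vector(outer(joint, get_dist(sm)))
        induced <- numeric(tm$nstates)
        agg <- rowsum(joint, tm$idx)
        induced[as.integer(rownames(agg))] <- agg[, 1]
        acc <- acc + fw * induced
      }
      if (influx <= 1e-12) next
      newd <- acc / influx
      delta <- max(delta, max(abs(newd - state[[m]])))
      state[[m]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("brute-force isotopomer iteration did not converge (delta = ",
            signif(delta, 3), ")")

  out <- list()
  for (m in tracked) {
    if (is.null(terms[[m]])) next
    n <- carbons[[m]]
    pop <- vapply(0:(2^n - 1), function(s) sum((s %/% 2^(0:(n - 1))) %% 2), 0)
    mid <- vapply(0:n, function(k) sum(state[[m]][pop == k]), 0)
    out[[m]] <- mid
  }
  out
}
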