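#' Steady-state stoichiometric machinery
#'
#' `build_stoichiometry()` assembles the stoichiometric matrix S over
#' balanced metabolites and computes, by exact rational Gauss-Jordan
#' elimination, a basis of its null space whose coordinates are actual
#' reaction fluxes (the non-pivot "free" reactions). Any steady-state net
#' flux vector is `v = free_basis %*% theta` with `theta = v[free_reactions]`.
#'
#' @name stoichiometry
NULL

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# exact rational reduced row echelon form; num/den are integer-valued
# double matrices. Entries stay exact while magnitudes < 2^53 (tiny here).
.rat_rref <- function(num, den) {
  nr <- nrow(num); nc <- ncol(num)
  reduce <- function(n, d) {
    if (n == 0) return(c(0, 1))
    g <- .gcd(n, d)
    s <- if (d < 0) -1 else 1
    c(s * n / g, s * d / g)
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    p <- which(num[row:nr, col] != 0)
    if (!length(p)) next
    p <- p[1] + row - 1L
    if (p != row) {
      tmp <- num[row, ]; num[row, ] <- num[p, ]; num[p, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[p, ]; den[p, ] <- tmp
    }
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(nc)) {   # row <- row / pivot
      r <- reduce(num[row, j] * pd, den[row, j] * pn)
      num[row, j] <- r[1]; den[row, j] <- r[2]
    }
    for (i in seq_len(nr)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(nc)) {
        # a_ij <- a_ij - f * row_j
        n1 <- num[i, j] * fd * den[row, j] - fn * num[row, j] * den[i, j]
        d1 <- den[i, j] * fd * den[row, j]
        r <- reduce(n1, d1)
        num[i, j] <- r[1]; den[i, j] <- r[2]
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

#' Rank of an integer matrix by exact rational elimination
#'
#' Independent oracle for the floating-point decomposition.
#'
#' @param m integer-valued matrix
#' @return integer rank
#' @export
rational_rank <- function(m) {
  if (any(m != round(m))) stop("rational_rank expects an integer-valued matrix")
  .rat_rref(m, matrix(1, nrow(m), ncol(m)))$rank
}

#' Build the stoichiometric decomposition of a network
#'
#' @param net a validated `flux_network`
#' @return a `stoich_decomp`: list with `S` (balanced metabolites x reactions),
#'   `free_basis` (reactions x free fluxes; unit rows at the free reactions),
#'   `free_basis_exact` (integer-scaled columns, `S %*% free_basis_exact`
#'   exactly zero), `free_reactions`, `free_count`, `rank`
#' @export
build_stoichiometry <- function(net) {
  rids <- reaction_ids(net)
  balanced <- net$metabolites$id[net$metabolites$role == "balanced"]
  S <- matrix(0, length(balanced), length(rids),
              dimnames = list(balanced, rids))
  for (r in net$reactions) {
    tr <- r$transitions[[1]]
    for (t in tr$subs) if (t$met %in% balanced)
      S[t$met, r$id] <- S[t$met, r$id] - 1
    for (t in tr$prods) if (t$met %in% balanced)
      S[t$met, r$id] <- S[t$met, r$id] + 1
  }
  # structurally dead pools: no possible producing direction
  for (m in balanced) {
    has_prod <- FALSE
    for (r in net$reactions) {
      tr <- r$transitions[[1]]
      inprod <- any(vapply(tr$prods, `[[`, "", "met") == m)
      insub <- any(vapply(tr$subs, `[[`, "", "met") == m)
      if (inprod || (insub && r$reversible)) { has_prod <- TRUE; break }
    }
    if (!has_prod) stop("structurally dead network: balanced metabolite '",
                        m, "' has no producer")
  }
  rr <- .rat_rref(S, matrix(1, nrow(S), ncol(S)))
  free_cols <- setdiff(seq_len(ncol(S)), rr$pivots)
  nf <- length(free_cols)
  B <- matrix(0, ncol(S), nf, dimnames = list(rids, rids[free_cols]))
  Bex <- B
  for (k in seq_len(nf)) {
    j <- free_cols[k]
    numv <- rep(0, ncol(S)); denv <- rep(1, ncol(S))
    numv[j] <- 1
    for (i in seq_along(rr$pivots)) {
      pc <- rr$pivots[i]
      numv[pc] <- -rr$num[i, j]
      denv[pc] <- rr$den[i, j]
    }
    B[, k] <- numv / denv
    scale <- Reduce(function(a, b) a * b / .gcd(a, b), unique(denv))
    Bex[, k] <- numv * (scale / denv)
  }
  structure(list(S = S, free_basis = B, free_basis_exact = Bex,
                 free_reactions = rids[free_cols],
                 free_count = nf, rank = rr$rank),
            class = "stoich_decomp")
}

#' @export
print.stoich_decomp <- function(x, ...) {
  cat(sprintf("<stoich_decomp> S: %d x %d, rank %d, %d free fluxes (%s)\n",
              nrow(x$S), ncol(x$S), x$rank, x$free_count,
              paste(x$free_reactions, collapse = ", ")))
  invisible(x)
}

#' Default net-flux bounds for a network
#' @param net a `flux_network`
#' @param vmax magnitude cap, nmol/1e6 cells/h
#' @return named list of `c(lo, hi)` per reaction
#' @export
default_bounds <- function(net, vmax = 2000) {
  out <- list()
  for (r in net$reactions)
    out[[r$id]] <- if (r$reversible) c(-vmax, vmax) else c(0, vmax)
  out
}

#' Find a strictly interior steady-state flux vector under bounds
#'
#' Searches the null-space coordinates for a point with `S v = 0` whose
#' fluxes sit strictly inside the given bounds (up to a margin; bounds with
#' `hi == lo` are matched exactly). The search minimizes a hinged quadratic
#' penalty on bound violations from several deterministic starts; the
#' returned point is verified against every constraint, so a `feasible = TRUE`
#' report is a certificate. When no feasible point is found the violated
#' constraints at the best point reached are reported.
#'
#' @param decomp a `stoich_decomp`
#' @param bounds named list of `c(lo, hi)` per reaction; missing reactions
#'   get `default_bounds()` entries
#' @param net optional `flux_network` supplying default bounds
#' @param margin requested strict clearance as a fraction of each bound width
#' @return list: `feasible` flag, `flux` (named net-flux vector or NULL),
#'   `theta` free coordinates, `violations` data.frame
#' @export
apply_bounds <- function(decomp, bounds = list(), net = NULL, margin = 0.01) {
  rids <- rownames(decomp$free_basis)
  full <- if (!is.null(net)) default_bounds(net) else
    setNames(rep(list(c(-2000, 2000)), length(rids)), rids)
  for (nm in names(bounds)) {
    if (!nm %in% rids) stop("bounds given for unknown reaction: ", nm)
    full[[nm]] <- bounds[[nm]]
  }
  lo <- vapply(rids, function(r) full[[r]][1], 0)
  hi <- vapply(rids, function(r) full[[r]][2], 0)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo > hi))
    stop("bounds must be finite with lo <= hi")
  B <- decomp$free_basis
  width <- hi - lo
  eps <- ifelse(width > 1e-9, margin * width, 0)
  # hard bound violations dominate; the margin term only nudges the point
  # toward the interior where the hard constraints leave room
  W <- 1e8
  pen <- function(theta) {
    v <- drop(B %*% theta)
    W * sum(pmax(lo - v, 0)^2 + pmax(v - hi, 0)^2) +
      sum(pmax(lo + eps - v, 0)^2 + pmax(v - hi + eps, 0)^2)
  }
  gr <- function(theta) {
    v <- drop(B %*% theta)
    g <- W * (-2 * pmax(lo - v, 0) + 2 * pmax(v - hi, 0)) +
      (-2 * pmax(lo + eps - v, 0) + 2 * pmax(v - hi + eps, 0))
    drop(crossprod(B, g))
  }
  frees <- decomp$free_reactions
  mid <- (lo[frees] + hi[frees]) / 2
  starts <- list(mid,
                 lo[frees] + 0.25 * width[frees],
                 lo[frees] + 0.75 * width[frees],
                 lo[frees] + 0.1 * width[frees])
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, pen, gr, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value <= 1e-18) break
  }
  v <- drop(B %*% best$par)
  names(v) <- rids
  tol <- 1e-6 * max(1, max(abs(v)))
  viol <- which(v < lo - tol | v > hi + tol)
  if (length(viol) == 0L) {
    return(list(feasible = TRUE, flux = v, theta = best$par,
                violations = data.frame(reaction = character(),
                                        lo = numeric(), hi = numeric(),
                                        value = numeric())))
  }
  list(feasible = FALSE, flux = NULL, theta = best$par,
       violations = data.frame(reaction = rids[viol], lo = lo[viol],
                               hi = hi[viol], value = v[viol],
                               row.names = NULL))
}
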