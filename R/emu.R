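#' EMU decomposition and simulation of label propagation
#'
#' An elementary metabolite unit (EMU) is a subset of a metabolite's carbon
#' positions whose mass isotopologue distribution can be balanced
#' independently of the rest of the molecule. Backward tracing from the
#' target EMUs through the atom-transition maps yields, per EMU size, a
#' linear balance system; condensation reactions couple sizes through
#' convolutions of smaller EMUs. Solving sizes in ascending order gives
#' every target MID at isotopic steady state.
#'
#' @name emu_simulation
NULL

emu_id <- function(met, positions)
  paste0(met, "#", paste(positions, collapse = ","))

#' Decompose a network into the EMU systems needed for given targets
#'
#' @param net a validated `flux_network`
#' @param targets list of `list(met = , positions = )`; `positions = NULL`
#'   means the whole molecule. Targets on source-role metabolites are
#'   returned under `determined` (their MIDs follow from the tracers alone).
#' @return an `emu_network`: balance relations stratified by EMU size,
#'   reachable backward from the targets only
#' @export
emu_decompose <- function(net, targets) {
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    nc <- met_carbons(net, tg$met)
    if (is.null(tg$positions)) targets[[i]]$positions <- seq_len(nc)
    else if (any(tg$positions < 1 | tg$positions > nc))
      stop("target positions out of range for ", tg$met)
    targets[[i]]$positions <- sort(unique(targets[[i]]$positions))
  }
  determined <- list()
  queue <- list()
  for (tg in targets) {
    if (met_role(net, tg$met) == "source")
      determined[[emu_id(tg$met, tg$positions)]] <-
        list(met = tg$met, positions = tg$positions)
    else queue[[length(queue) + 1L]] <- tg
  }
  balance <- list()
  revflags <- vapply(net$reactions, `[[`, TRUE, "reversible")
  names(revflags) <- reaction_ids(net)
  while (length(queue)) {
    tg <- queue[[1]]; queue <- queue[-1]
    id <- emu_id(tg$met, tg$positions)
    if (!is.null(balance[[id]])) next
    terms <- list()
    for (r in net$reactions) {
      dirs <- if (r$reversible) c("f", "b") else "f"
      for (d in dirs) {
        for (tr in r$transitions) {
          subs <- if (d == "f") tr$subs else tr$prods
          prods <- if (d == "f") tr$prods else tr$subs
          for (pi in seq_along(prods)) {
            pt <- prods[[pi]]
            if (pt$met != tg$met || is.null(pt$letters)) next
            want <- pt$letters[tg$positions]
            sources <- list()
            ok <- TRUE
            for (st in subs) {
              if (is.null(st$letters)) next
              pos <- which(st$letters %in% want)
              if (!length(pos)) next
              role <- met_role(net, st$met)
              sources[[length(sources) + 1L]] <-
                list(met = st$met, positions = sort(pos),
                     known = (role == "source"))
            }
            got <- sum(vapply(sources, function(s) length(s$positions), 0L))
            if (got != length(want)) ok <- FALSE  # letters lost to unmapped side
            if (!ok) next
            terms[[length(terms) + 1L]] <-
              list(rxn = r$id, dir = d, weight = tr$weight, sources = sources)
            for (s in sources) {
              if (!s$known) {
                sid <- emu_id(s$met, s$positions)
                if (is.null(balance[[sid]]))
                  queue[[length(queue) + 1L]] <-
                    list(met = s$met, positions = s$positions)
              }
            }
          }
        }
      }
    }
    if (!length(terms))
      stop("EMU ", id, " has no producing atom-mapped reaction")
    balance[[id]] <- list(met = tg$met, positions = tg$positions,
                          size = length(tg$positions), terms = terms)
  }
  sizes <- sort(unique(vapply(balance, `[[`, 0L, "size")))
  by_size <- lapply(sizes, function(s)
    names(balance)[vapply(balance, `[[`, 0L, "size") == s])
  names(by_size) <- as.character(sizes)
  structure(list(balance = balance, by_size = by_size, sizes = sizes,
                 targets = targets, determined = determined,
                 reversible = revflags,
                 carbons = stats::setNames(net$metabolites$carbons,
                                           net$metabolites$id)),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat("<emu_network>", length(x$balance), "unknown EMUs; sizes:",
      paste(sprintf("%s(%d)", names(x$by_size),
                    lengths(x$by_size)), collapse = " "), "\n")
  invisible(x)
}

#' Simulate mass isotopologue distributions
#'
#' Solves the EMU balance systems size by size for the flux vector and
#' tracers, returning the steady-state MID of every EMU in the
#' decomposition.
#'
#' @param emunet an `emu_network` from [emu_decompose()]
#' @param v a `flux_vector` (steady-state feasible)
#' @param tracers list of [tracer_spec()] objects
#' @return an `emu_mids` object: named list of MID vectors keyed by EMU id;
#'   use [mid_of()] for convenient access
#' @export
simulate_mids <- function(emunet, v, tracers) {
  dirs <- flux_directions(v)
  irr <- names(emunet$reversible)[!emunet$reversible]
  if (any(dirs$backward[irr] > 1e-9))
    stop("negative net flux into the forward/backward split of an irreversible reaction: ",
         paste(irr[dirs$backward[irr] > 1e-9], collapse = ", "))
  solved <- new.env(parent = emptyenv())
  get_mid <- function(src) {
    if (src$known)
      .source_mid(src$met, src$positions, tracers,
                  emunet$carbons[[src$met]])
    else get(emu_id(src$met, src$positions), envir = solved)
  }
  target_ids <- vapply(emunet$targets, function(t)
    emu_id(t$met, t$positions), "")
  for (s in emunet$sizes) {
    ids <- emunet$by_size[[as.character(s)]]
    n <- length(ids)
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    R <- matrix(0, n, s + 1L)
    for (i in seq_len(n)) {
      bal <- emunet$balance[[ids[i]]]
      influx <- 0
      for (tm in bal$terms) {
        f <- if (tm$dir == "f") dirs$forward[[tm$rxn]] else dirs$backward[[tm$rxn]]
        if (f <= 0) next
        fw <- f * tm$weight
        influx <- influx + fw
        same_size_unknown <- length(tm$sources) == 1L &&
          !tm$sources[[1]]$known &&
          length(tm$sources[[1]]$positions) == s &&
          emu_id(tm$sources[[1]]$met, tm$sources[[1]]$positions) %in% ids
        if (same_size_unknown) {
          j <- emu_id(tm$sources[[1]]$met, tm$sources[[1]]$positions)
          A[i, j] <- A[i, j] - fw
        } else {
          m <- NULL
          for (src in tm$sources) {
            sm <- get_mid(src)
            m <- if (is.null(m)) sm else convolve_mid(m, sm)
          }
          R[i, ] <- R[i, ] + fw * m
        }
      }
      if (influx <= 1e-12) {
        # a flux-dead branch: only an error when its MID was asked for;
        # otherwise it carries no material and gets an unlabeled placeholder
        if (ids[i] %in% target_ids)
          stop("singular EMU balance: zero total influx to ", ids[i])
        A[i, ] <- 0
        A[i, i] <- 1
        R[i, ] <- c(1, numeric(s))
        next
      }
      A[i, i] <- A[i, i] + influx
    }
    X <- solve(A, R)
    for (i in seq_len(n)) {
      mi <- pmax(X[i, ], 0)
      mi <- mi / sum(mi)
      assign(ids[i], mi, envir = solved)
    }
  }
  out <- as.list(solved)
  for (id in names(emunet$determined)) {
    d <- emunet$determined[[id]]
    out[[id]] <- .source_mid(d$met, d$positions, tracers,
                             emunet$carbons[[d$met]])
  }
  structure(out, class = "emu_mids")
}

#' Extract one MID from simulation output
#' @param mids an `emu_mids` object
#' @param met metabolite id
#' @param positions carbon position set; `NULL` for the whole molecule (the
#'   whole-molecule EMU must have been among the decomposition targets)
#' @return numeric MID vector
#' @export
mid_of <- function(mids, met, positions = NULL) {
  keys <- names(mids)
  if (is.null(positions)) {
    hit <- grep(paste0("^", met, "#"), keys, value = TRUE)
    if (!length(hit)) stop("no simulated EMU for metabolite ", met)
    sizes <- nchar(gsub("[^,]", "", hit))
    key <- hit[which.max(sizes)]
  } else key <- emu_id(met, sort(positions))
  m <- mids[[key]]
  if (is.null(m)) stop("EMU not simulated: ", key)
  m
}

#' Whole-molecule EMU targets for a set of metabolites
#' @param net a `flux_network`
#' @param mets metabolite ids (default: all balanced metabolites)
#' @return list suitable for [emu_decompose()]
#' @export
whole_molecule_targets <- function(net, mets = NULL) {
  if (is.null(mets))
    mets <- net$metabolites$id[net$metabolites$role == "balanced" &
                                 net$metabolites$carbons > 0]
  lapply(mets, function(m) list(met = m, positions = NULL))
}
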