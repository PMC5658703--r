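#' Metabolic network models with carbon atom transitions
#'
#' A `flux_network` holds metabolites (with carbon counts and a role),
#' reactions (stoichiometry implied by the equation, reversibility, and one
#' or more weighted atom-transition maps), and free-text annotations.
#'
#' Roles:
#' \describe{
#'   \item{balanced}{intracellular pool at isotopic and metabolic steady
#'     state; subject to mass balance.}
#'   \item{source}{extracellular substrate or untracked pool (e.g. CO2);
#'     supplies carbon with a known labeling state (unlabeled unless a tracer
#'     is declared) and absorbs carbon without balance.}
#'   \item{sink}{secreted or drained pool; its labeling is the flux-weighted
#'     mixture of its inflows but it is exempt from mass balance.}
#' }
#'
#' @name flux_network
NULL

.valid_roles <- c("balanced", "source", "sink")

new_flux_network <- function(metabolites, reactions, annotations = character()) {
  structure(list(metabolites = metabolites,
                 reactions = reactions,
                 annotations = annotations),
            class = "flux_network")
}

#' Look up carbon count of a metabolite
#' @param net a `flux_network`
#' @param id metabolite id
#' @return integer carbon count
#' @keywords internal
met_carbons <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", id)
  net$metabolites$carbons[i]
}

met_role <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", id)
  net$metabolites$role[i]
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

#' Parse a metabolic network model file
#'
#' The file is UTF-8 text with tab-separated directives:
#' \preformatted{
#' METABOLITE <tab> id <tab> carbons <tab> role
#' REACTION   <tab> id <tab> rev|irr <tab> A (ab) + B (c) -> C (abc)
#' MAP2       <tab> A (ab) + B (c) -> C (bac)
#' ANNOTATION <tab> key <tab> value
#' }
#' `#` starts a comment. A `MAP2` line attaches a second atom-transition map
#' to the preceding reaction (the two maps are weighted 0.5 each; used for
#' molecular symmetry, e.g. succinate/fumarate). Atom maps are lower-case
#' letter strings, one letter per carbon position. Maps are mandatory on the
#' substrate side for carbon-bearing metabolites and on the product side for
#' balanced products; a map-free source/sink product absorbs any substrate
#' carbons not mapped to a product.
#'
#' @param text character scalar (file content) or character vector of lines
#' @return a `flux_network`
#' @seealso [write_network()], [validate_atom_balance()]
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text) == 0L || all(!nzchar(trimws(text))))
    stop("empty network file")
  perr <- function(lineno, msg) stop(sprintf("network parse error at line %d: %s", lineno, msg),
                                     call. = FALSE)
  mets <- list()
  rxns <- list()
  ann <- character()
  last_rxn <- NULL
  for (lineno in seq_along(text)) {
    line <- sub("#.*$", "", text[lineno])
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    kw <- fields[1]
    if (kw == "METABOLITE") {
      if (length(fields) < 4L) perr(lineno, "METABOLITE needs id, carbons, role")
      id <- fields[2]; carbons <- suppressWarnings(as.integer(fields[3])); role <- fields[4]
      if (is.na(carbons) || carbons < 0) perr(lineno, "bad carbon count")
      if (!role %in% .valid_roles) perr(lineno, paste("bad role:", role))
      if (id %in% names(mets)) perr(lineno, paste("duplicate metabolite id:", id))
      mets[[id]] <- list(id = id, carbons = carbons, role = role)
    } else if (kw == "REACTION") {
      if (length(fields) < 4L) perr(lineno, "REACTION needs id, rev|irr, equation")
      id <- fields[2]; revflag <- fields[3]; eq <- fields[4]
      if (!revflag %in% c("rev", "irr")) perr(lineno, "reversibility must be rev or irr")
      if (id %in% names(rxns)) perr(lineno, paste("duplicate reaction id:", id))
      tr <- .parse_equation(eq, mets, lineno, perr)
      rxns[[id]] <- list(id = id, reversible = (revflag == "rev"),
                         transitions = list(tr))
      last_rxn <- id
    } else if (kw == "MAP2") {
      if (is.null(last_rxn)) perr(lineno, "MAP2 with no preceding REACTION")
      if (length(fields) < 2L) perr(lineno, "MAP2 needs an equation")
      tr <- .parse_equation(fields[2], mets, lineno, perr)
      rxns[[last_rxn]]$transitions <- c(rxns[[last_rxn]]$transitions, list(tr))
    } else if (kw == "ANNOTATION") {
      if (length(fields) < 3L) perr(lineno, "ANNOTATION needs key and value")
      ann[fields[2]] <- paste(fields[-(1:2)], collapse = "\t")
    } else {
      perr(lineno, paste("unknown directive:", kw))
    }
  }
  metdf <- data.frame(id = vapply(mets, `[[`, "", "id"),
                      carbons = vapply(mets, `[[`, 0L, "carbons"),
                      role = vapply(mets, `[[`, "", "role"),
                      stringsAsFactors = FALSE, row.names = NULL)
  # equalize weights across maps of one reaction
  for (id in names(rxns)) {
    k <- length(rxns[[id]]$transitions)
    for (j in seq_len(k)) rxns[[id]]$transitions[[j]]$weight <- 1 / k
  }
  new_flux_network(metdf, rxns, ann)
}

# parse "A (ab) + B (c) -> C (abc)" into a transition record
.parse_equation <- function(eq, mets, lineno, perr) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) perr(lineno, "equation must contain exactly one ->")
  parse_side <- function(s, side) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    out <- list()
    for (term in terms) {
      term <- trimws(term)
      if (!nzchar(term)) perr(lineno, "empty term in equation")
      m <- regmatches(term, regexec("^([^[:space:]()]+)[[:space:]]*(\\(([a-z]+)\\))?$", term))[[1]]
      if (length(m) == 0L || !nzchar(m[2])) perr(lineno, paste("cannot parse term:", term))
      id <- m[2]
      letters <- if (nzchar(m[4])) strsplit(m[4], "")[[1]] else NULL
      if (!id %in% names(mets)) perr(lineno, paste("unknown metabolite:", id))
      carbons <- mets[[id]]$carbons
      role <- mets[[id]]$role
      if (!is.null(letters) && length(letters) != carbons)
        perr(lineno, sprintf("atom map '%s' has %d letters but %s is declared with %d carbons",
                             m[4], length(letters), id, carbons))
      if (is.null(letters) && carbons > 0) {
        needs_map <- (side == "sub") || role == "balanced"
        if (needs_map)
          perr(lineno, sprintf("missing atom map for %s (%s side)", id, side))
      }
      out[[length(out) + 1L]] <- list(met = id, letters = letters)
    }
    out
  }
  list(weight = 1,
       subs = parse_side(sides[1], "sub"),
       prods = parse_side(sides[2], "prod"))
}

#' Read a network model from a file
#' @param path file path
#' @return a `flux_network`
#' @export
read_network <- function(path) parse_network(readLines(path, warn = FALSE))

#' Write a network model in canonical form
#'
#' Emits metabolites in declaration order, then reactions with their atom
#' maps, then annotations. `parse_network(write_network(net))` reproduces
#' `net`.
#'
#' @param net a `flux_network`
#' @param path optional file path; if `NULL` the text is returned
#' @return character vector of lines (invisibly when writing to a file)
#' @export
write_network <- function(net, path = NULL) {
  fmt_term <- function(t) {
    if (is.null(t$letters)) t$met
    else sprintf("%s (%s)", t$met, paste(t$letters, collapse = ""))
  }
  fmt_eq <- function(tr) {
    paste(paste(vapply(tr$subs, fmt_term, ""), collapse = " + "),
          "->",
          paste(vapply(tr$prods, fmt_term, ""), collapse = " + "))
  }
  lines <- character()
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    lines <- c(lines, paste("METABOLITE", m$id, m$carbons, m$role, sep = "\t"))
  }
  for (r in net$reactions) {
    lines <- c(lines, paste("REACTION", r$id,
                            if (r$reversible) "rev" else "irr",
                            fmt_eq(r$transitions[[1]]), sep = "\t"))
    for (tr in r$transitions[-1])
      lines <- c(lines, paste("MAP2", fmt_eq(tr), sep = "\t"))
  }
  for (k in names(net$annotations))
    lines <- c(lines, paste("ANNOTATION", k, net$annotations[[k]], sep = "\t"))
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(lines)
  } else lines
}

#' Validate carbon-atom balance of every reaction
#'
#' Checks, per reaction and transition: atom maps present where required;
#' letters used exactly once on each side; every product carbon traced to a
#' substrate carbon; substrate carbons not mapped to a product only permitted
#' when the reaction has a map-free source/sink product to absorb them; map
#' weights positive and summing to 1 within 1e-12; identical molecule counts
#' across the maps of one reaction. Network-level: every balanced metabolite
#' has at least one producing and one consuming reaction.
#'
#' Violations are returned as data, not raised.
#'
#' @param net a `flux_network`
#' @return data.frame with columns `reaction`, `problem` (zero rows when valid)
#' @export
validate_atom_balance <- function(net) {
  bad <- list()
  note <- function(rxn, msg) bad[[length(bad) + 1L]] <<- data.frame(
    reaction = rxn, problem = msg, stringsAsFactors = FALSE)
  produced <- character(); consumed <- character()
  for (r in net$reactions) {
    w <- vapply(r$transitions, `[[`, 0, "weight")
    if (any(w <= 0)) note(r$id, "non-positive atom-map weight")
    if (abs(sum(w) - 1) > 1e-12)
      note(r$id, sprintf("atom-map weights sum to %.6f, not 1", sum(w)))
    counts0 <- NULL
    for (tr in r$transitions) {
      sub_letters <- unlist(lapply(tr$subs, `[[`, "letters"))
      prod_letters <- unlist(lapply(tr$prods, `[[`, "letters"))
      if (anyDuplicated(sub_letters))
        note(r$id, "duplicate letter on substrate side")
      if (anyDuplicated(prod_letters))
        note(r$id, "duplicate letter on product side")
      orphan <- setdiff(prod_letters, sub_letters)
      if (length(orphan))
        note(r$id, paste("product carbons from nowhere:", paste(orphan, collapse = ",")))
      lost <- setdiff(sub_letters, prod_letters)
      if (length(lost)) {
        absorber <- any(vapply(tr$prods, function(t)
          is.null(t$letters) && met_role(net, t$met) != "balanced", TRUE))
        if (!absorber)
          note(r$id, paste("substrate carbons unaccounted for:", paste(lost, collapse = ",")))
      }
      counts <- table(c(vapply(tr$subs, `[[`, "", "met"), vapply(tr$prods, `[[`, "", "met")))
      if (is.null(counts0)) counts0 <- counts
      else if (!identical(counts0, counts))
        note(r$id, "molecule counts differ between atom maps")
    }
    tr <- r$transitions[[1]]
    for (t in tr$subs) consumed <- c(consumed, t$met)
    for (t in tr$prods) produced <- c(produced, t$met)
    if (r$reversible) {
      for (t in tr$subs) produced <- c(produced, t$met)
      for (t in tr$prods) consumed <- c(consumed, t$met)
    }
  }
  balanced <- net$metabolites$id[net$metabolites$role == "balanced"]
  for (m in setdiff(balanced, produced))
    note("(network)", paste("balanced metabolite never produced:", m))
  for (m in setdiff(balanced, consumed))
    note("(network)", paste("balanced metabolite never consumed:", m))
  if (length(bad)) do.call(rbind, bad)
  else data.frame(reaction = character(), problem = character(), stringsAsFactors = FALSE)
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d metabolites (%d balanced), %d reactions (%d reversible)\n",
              nrow(x$metabolites), sum(x$metabolites$role == "balanced"),
              length(x$reactions),
              sum(vapply(x$reactions, `[[`, TRUE, "reversible"))))
  invisible(x)
}

#' Construct a flux vector
#'
#' Net fluxes are in nmol per 1e6 cells per hour. Reversible reactions carry
#' an additional non-negative exchange flux: forward = max(net, 0) + exchange,
#' backward = max(-net, 0) + exchange.
#'
#' @param net_flux named numeric, one entry per reaction
#' @param exchange named numeric over reversible reactions (defaults to 0)
#' @param network optional `flux_network` used to check names and signs
#' @return a `flux_vector`
#' @export
flux_vector <- function(net_flux, exchange = NULL, network = NULL) {
  if (!is.null(network)) {
    rids <- reaction_ids(network)
    if (!setequal(names(net_flux), rids))
      stop("net_flux names must match the network's reaction ids")
    net_flux <- net_flux[rids]
    rev <- rids[vapply(network$reactions, `[[`, TRUE, "reversible")]
    if (is.null(exchange)) exchange <- setNames(numeric(length(rev)), rev)
    exchange <- exchange[rev]
    names(exchange) <- rev
    exchange[is.na(exchange)] <- 0
    irrev <- setdiff(rids, rev)
    if (any(net_flux[irrev] < -1e-9))
      stop("negative net flux on irreversible reaction: ",
           paste(irrev[net_flux[irrev] < -1e-9], collapse = ", "))
  } else if (is.null(exchange)) exchange <- numeric()
  if (any(exchange < 0)) stop("exchange fluxes must be non-negative")
  structure(list(net = net_flux, exchange = exchange), class = "flux_vector")
}

#' Forward/backward split of a flux vector
#' @param v a `flux_vector`
#' @return list with named numerics `forward` and `backward`
#' @keywords internal
flux_directions <- function(v) {
  fwd <- pmax(v$net, 0)
  bwd <- pmax(-v$net, 0)
  if (length(v$exchange)) {
    fwd[names(v$exchange)] <- fwd[names(v$exchange)] + v$exchange
    bwd[names(v$exchange)] <- bwd[names(v$exchange)] + v$exchange
  }
  list(forward = fwd, backward = bwd)
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector>", length(x$net), "net fluxes,",
      length(x$exchange), "exchange fluxes\n")
  print(utils::head(round(x$net, 4), 10))
  invisible(x)
}
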