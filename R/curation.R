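# Rebuild a network without the given reactions (metabolite universe and S
# are recomputed; orphaned metabolites drop out).
drop_reactions <- function(network, ids) {
  keep <- !(network$reactions$id %in% ids)
  metabolic_network(network$reactions[keep, ], network$biomass)
}

# Canonical duplicate-detection key: sorted (metabolite, coefficient) list.
# A reversible reaction is orientation-free (the key is the lexicographic
# minimum of the as-written and sign-flipped forms); an irreversible
# reaction keeps its orientation, so A -> B and B -> A are distinct.
reaction_key <- function(equation) {
  p <- parse_equation(equation)
  o <- order(p$metabolites)
  fmt <- function(coefs) paste(p$metabolites[o],
                               format(coefs[o], digits = 12, trim = TRUE),
                               sep = ":", collapse = ";")
  if (p$reversible) {
    paste0("rev|", min(fmt(p$coefficients), fmt(-p$coefficients)))
  } else {
    paste0("irr|", fmt(p$coefficients))
  }
}

#' Merge a host network with a universal reaction pool
#'
#' Produces the union network: host reactions keep `origin = "host"`, pool
#' reactions are tagged `origin = "universal"`. A pool reaction identical to
#' a host reaction (same stoichiometry and directionality; a reversible
#' reaction also matches its sign-flipped form) is dropped as a duplicate
#' and recorded in the `"duplicates"` attribute of the result. Metabolite
#' namespaces must already be shared; an optional two-column synonym table
#' (`from`, `to`) renames pool metabolites first.
#'
#' @param host host `metabolic_network` (supplies the biomass reaction).
#' @param pool pool `metabolic_network` (its biomass, if any, is ignored).
#' @param synonyms optional data frame with columns `from`, `to` mapping
#'   pool metabolite ids onto the host namespace; a `from` entry mapping to
#'   `NA` or `""` is an input error.
#' @return merged `metabolic_network` with attribute `"duplicates"` (tibble:
#'   `pool_id`, `kept_id`).
#' @export
merge_networks <- function(host, pool, synonyms = NULL) {
  pool_rx <- pool$reactions
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    if (any(is.na(synonyms$to) | synonyms$to == ""))
      stop("synonym table maps metabolite(s) to nothing: ",
           paste(synonyms$from[is.na(synonyms$to) | synonyms$to == ""],
                 collapse = ", "), call. = FALSE)
    map <- stats::setNames(synonyms$to, synonyms$from)
    pool_rx$equation <- vapply(pool_rx$equation, function(eq) {
      p <- parse_equation(eq)
      hit <- p$metabolites %in% names(map)
      p$metabolites[hit] <- unname(map[p$metabolites[hit]])
      make_equation(p$metabolites, p$coefficients, p$reversible)
    }, character(1))
  }
  pool_rx$origin <- "universal"

  host_keys <- vapply(host$reactions$equation, reaction_key, character(1))
  pool_keys <- vapply(pool_rx$equation, reaction_key, character(1))
  dup_host <- match(pool_keys, host_keys)
  dup_pool <- match(pool_keys, pool_keys)  # first occurrence within pool
  is_dup <- !is.na(dup_host) | dup_pool < seq_along(pool_keys)
  duplicates <- tibble::tibble(
    pool_id = pool_rx$id[is_dup],
    kept_id = ifelse(!is.na(dup_host[is_dup]),
                     host$reactions$id[dup_host[is_dup]],
                     pool_rx$id[dup_pool[is_dup]]))
  pool_rx <- pool_rx[!is_dup, ]
  # pool reaction ids clashing with host ids (but different chemistry) are
  # made unique to preserve the id-uniqueness invariant
  clash <- pool_rx$id %in% host$reactions$id
  pool_rx$id[clash] <- paste0(pool_rx$id[clash], "_pool")

  merged <- metabolic_network(dplyr::bind_rows(host$reactions, pool_rx),
                              host$biomass)
  attr(merged, "duplicates") <- duplicates
  merged
}

#' Detect energy-generating ("perpetuum mobile") cycles
#'
#' With every exchange reaction closed in both directions, maximises the
#' flux through each energy-dissipation reaction (for example ATP
#' hydrolysis). A positive optimum means the network contains a flux
#' distribution that generates energy without consuming any nutrient. For
#' each such dissipation reaction, the minimal sets of universal-origin
#' reactions that must be active to sustain the dissipation flux are found
#' by the gap-fill machinery run in "minimise active universal reactions
#' subject to dissipation flux >= epsilon" mode and enumerated exhaustively.
#'
#' @param network merged `metabolic_network`.
#' @param energy_dissipation_reactions character vector of dissipation
#'   reaction ids present in the network.
#' @param epsilon minimal dissipation flux qualifying as a cycle in the
#'   minimisation (default `1e-8`).
#' @param tol flux tolerance above which the closed-exchange maximum counts
#'   as a cycle (default `1e-6`).
#' @param max_sets cap on enumerated minimal supports per dissipation
#'   reaction.
#' @return tibble with one row per minimal flux-carrying support:
#'   `dissipation`, `support` (list: all reactions carrying flux in the
#'   verifying distribution), `removable` (list: its universal-origin
#'   members; empty for a cycle running entirely on host reactions, which
#'   triggers a warning since host reactions are never removed). Zero rows
#'   iff no cycle exists.
#' @export
detect_energy_cycles <- function(network, energy_dissipation_reactions,
                                 epsilon = 1e-8, tol = VIABILITY_TOL,
                                 max_sets = 50L) {
  rx <- network$reactions
  if (missing(energy_dissipation_reactions) ||
      length(energy_dissipation_reactions) == 0)
    stop("supply at least one energy-dissipation reaction", call. = FALSE)
  bad <- setdiff(energy_dissipation_reactions, rx$id)
  if (length(bad) > 0)
    stop("dissipation reaction(s) not in network: ",
         paste(bad, collapse = ", "), call. = FALSE)

  lb <- rx$lower; ub <- rx$upper
  lb[rx$is_exchange] <- 0; ub[rx$is_exchange] <- 0
  b0 <- rep(0, length(network$metabolites))
  candidates <- rx$id[rx$origin == "universal" & !rx$is_exchange]

  out <- list()
  for (d in energy_dissipation_reactions) {
    obj <- as.numeric(rx$id == d)
    mx <- lp_solve(obj, network$S, b0, lb, ub, maximize = TRUE)
    if (mx$status != "optimal" || mx$objective <= tol) next
    # the constraint system with closed exchanges is homogeneous, so any
    # flux distribution with dissipation >= epsilon scales to dissipation
    # >= 1 within the caps; detecting at 1 keeps the LP well-conditioned
    sys <- make_milp_system(network, lb, ub, candidates,
                            target_id = d, floor = max(epsilon, 1))
    parts <- milp_parts(sys)
    exclusions <- list()
    repeat {
      sol <- milp_search(sys, exclusions)
      if (sol$status != "optimal") break
      if (length(exclusions) > 0 &&
          sol$size > length(exclusions[[1]])) break
      ver <- milp_verify(sys, parts, sol$set, epsilon)
      carriers <- names(ver$fluxes)[abs(ver$fluxes) > tol]
      out[[length(out) + 1]] <- tibble::tibble(
        dissipation = d, support = list(sort(carriers)),
        removable = list(sol$set))
      if (length(sol$set) == 0) break  # cycle needs no universal reaction
      exclusions[[length(exclusions) + 1]] <- sol$set
      if (length(exclusions) >= max_sets) break
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    return(tibble::tibble(dissipation = character(), support = list(),
                          removable = list()))
  if (any(lengths(res$removable) == 0))
    warning("energy cycle(s) using only host reactions detected; ",
            "host reactions are never removed", call. = FALSE)
  res
}

# Smallest hitting set over a list of non-empty id sets, ties broken
# lexicographically; brute force over the union (curation-scale inputs).
min_hitting_set <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  for (k in seq_along(universe)) {
    combs <- utils::combn(universe, k, simplify = FALSE)
    for (h in combs) {
      if (all(vapply(sets, function(s) any(s %in% h), logical(1)))) return(h)
    }
  }
  universe
}

#' Remove unconditionally blocked reactions
#'
#' Opens every exchange in both directions (the most permissive medium
#' expressible in the model) and removes universal-origin reactions whose
#' flux-variability range is `(0, 0)` — reactions unable to carry flux under
#' any condition. Iterates to a fixed point. Host-origin reactions are never
#' removed; blocked host reactions are reported separately.
#'
#' @param network merged `metabolic_network`.
#' @param tol flux tolerance.
#' @return list with `network` (pruned), `removed` (universal ids removed)
#'   and `blocked_host` (blocked but retained host ids).
#' @export
remove_blocked <- function(network, tol = VIABILITY_TOL) {
  removed <- character()
  repeat {
    fva <- flux_variability(network, open_all_exchanges = TRUE)
    blocked <- fva$id[fva$max < tol & fva$min > -tol]
    rx <- network$reactions
    drop <- blocked[rx$origin[match(blocked, rx$id)] == "universal"]
    if (length(drop) == 0) {
      blocked_host <- blocked[rx$origin[match(blocked, rx$id)] == "host"]
      return(list(network = network, removed = removed,
                  blocked_host = blocked_host))
    }
    network <- drop_reactions(network, drop)
    removed <- c(removed, drop)
  }
}

#' Curate a merged universal network
#'
#' Full curation pipeline: merge the host network with the reaction pool,
#' drop duplicate pool reactions, excise energy-generating cycles by
#' removing a minimum-cardinality set of universal-origin reactions
#' (smallest hitting set over the enumerated minimal cycle supports,
#' lexicographic tie-break, re-detecting until no dissipation flux is
#' possible with all exchanges closed), then remove unconditionally blocked
#' universal reactions. The pipeline is idempotent.
#'
#' @inheritParams merge_networks
#' @param energy_dissipation_reactions dissipation reaction ids (in the host
#'   or pool) used to probe for energy-generating cycles.
#' @param tol flux tolerance.
#' @return list with `network` (curated `metabolic_network`) and `report`
#'   (a `curation_report`).
#' @export
curate_universal <- function(host, pool, energy_dissipation_reactions,
                             synonyms = NULL, tol = VIABILITY_TOL) {
  merged <- merge_networks(host, pool, synonyms)
  duplicates <- attr(merged, "duplicates")
  current <- merged

  cycle_removed <- character()
  repeat {
    cyc <- detect_energy_cycles(current, energy_dissipation_reactions, tol = tol)
    if (nrow(cyc) == 0) break
    breakable <- cyc$removable[lengths(cyc$removable) > 0]
    if (length(breakable) == 0) break  # host-only cycles; warned already
    hit <- min_hitting_set(breakable)
    current <- drop_reactions(current, hit)
    cycle_removed <- c(cycle_removed, hit)
  }

  rb <- remove_blocked(current, tol = tol)
  current <- rb$network

  report <- structure(list(
    duplicates_removed = duplicates,
    energy_cycle_reactions_removed = cycle_removed,
    blocked_removed = rb$removed,
    blocked_host_retained = rb$blocked_host,
    final_counts = c(
      metabolic = sum(!current$reactions$is_exchange),
      uptake = sum(current$reactions$is_exchange))),
    class = "curation_report")
  list(network = current, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> duplicates removed: ", nrow(x$duplicates_removed),
      "; energy-cycle reactions removed: ",
      length(x$energy_cycle_reactions_removed),
      "; blocked removed: ", length(x$blocked_removed),
      "; final counts: ", x$final_counts[["metabolic"]], " metabolic + ",
      x$final_counts[["uptake"]], " uptake\n", sep = "")
  invisible(x)
}

#' Serialise a curation report as JSON
#'
#' @param report a `curation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(list(
    duplicates_removed = report$duplicates_removed,
    energy_cycle_reactions_removed = report$energy_cycle_reactions_removed,
    blocked_removed = report$blocked_removed,
    blocked_host_retained = report$blocked_host_retained,
    final_counts = as.list(report$final_counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
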