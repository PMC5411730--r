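# Flux bounds for a network placed in an environment: every exchange not
# opened by the environment has uptake closed (lower bound 0); opened
# exchanges get lower bound -uptake; secretion (positive exchange flux) is
# always permitted. Non-exchange reactions keep their stored bounds.
fba_bounds <- function(network, env) {
  rx <- network$reactions
  up <- env_uptakes(env)
  unknown <- setdiff(names(up), rx$id[rx$is_exchange])
  if (length(unknown) > 0)
    stop("environment opens unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lb <- rx$lower
  ub <- rx$upper
  ex <- rx$is_exchange
  lb[ex] <- 0
  ub[ex] <- pmax(ub[ex], 0)
  hit <- match(names(up), rx$id)
  lb[hit] <- -abs(unname(up))
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximises biomass flux subject to steady-state mass balance `S v = 0` and
#' flux bounds, with uptake limits taken from the environment. Exchanges not
#' opened by the environment are closed for uptake; secretion is always
#' allowed.
#'
#' @param network a [metabolic_network()].
#' @param env an environment (one row of an environment tibble, or a named
#'   numeric vector of uptake bounds keyed by exchange id).
#' @return a `flux_solution`: list with `objective_value` (maximum biomass
#'   flux), `fluxes` (named vector), and `status` (`"optimal"` or
#'   `"infeasible"`).
#' @export
solve_fba <- function(network, env) {
  bb <- fba_bounds(network, env)
  obj <- as.numeric(network$reactions$id == network$biomass)
  res <- lp_solve(obj, network$S, rep(0, length(network$metabolites)),
                  bb$lb, bb$ub, maximize = TRUE)
  if (res$status == "failed")
    stop("LP solver failure in FBA (model defect?)", call. = FALSE)
  structure(list(objective_value = if (res$status == "optimal") res$objective else 0,
                 fluxes = if (res$status == "optimal")
                   stats::setNames(res$x, network$reactions$id) else NULL,
                 status = res$status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      ", biomass flux: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Viability of a network in an environment
#'
#' A network is viable when its maximum biomass flux exceeds `tol`; the
#' tolerance absorbs LP numerics in the "maximum biomass production was
#' zero" criterion.
#'
#' @inheritParams solve_fba
#' @param tol viability threshold on biomass flux (default `1e-6`).
#' @return `TRUE`/`FALSE`.
#' @export
is_viable <- function(network, env, tol = VIABILITY_TOL) {
  sol <- solve_fba(network, env)
  sol$status == "optimal" && sol$objective_value > tol
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum steady-state flux under the
#' environment's bounds, with the biomass reaction either left free or
#' pinned to zero.
#'
#' @inheritParams solve_fba
#' @param reactions reaction ids to analyse (default: all).
#' @param biomass `"free"` (default) or `"zero"` (biomass flux forced to 0).
#' @param open_all_exchanges if `TRUE`, ignore `env` and open every exchange
#'   in both directions at the flux cap (the most permissive medium; used
#'   for unconditional-blockage testing).
#' @return tibble with columns `id`, `min`, `max`.
#' @export
flux_variability <- function(network, env = NULL, reactions = NULL,
                             biomass = c("free", "zero"),
                             open_all_exchanges = FALSE) {
  biomass <- match.arg(biomass)
  rx <- network$reactions
  if (open_all_exchanges) {
    lb <- rx$lower; ub <- rx$upper
    lb[rx$is_exchange] <- -FLUX_CAP
    ub[rx$is_exchange] <- FLUX_CAP
  } else {
    if (is.null(env)) stop("supply env or open_all_exchanges = TRUE", call. = FALSE)
    bb <- fba_bounds(network, env)
    lb <- bb$lb; ub <- bb$ub
  }
  if (biomass == "zero") {
    bi <- match(network$biomass, rx$id)
    lb[bi] <- 0; ub[bi] <- 0
  }
  ids <- reactions %||% rx$id
  idx <- match(ids, rx$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  b0 <- rep(0, length(network$metabolites))
  rng <- purrr::map(idx, function(j) {
    obj <- numeric(nrow(rx)); obj[j] <- 1
    lo <- lp_solve(obj, network$S, b0, lb, ub, maximize = FALSE)
    hi <- lp_solve(obj, network$S, b0, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for ", rx$id[j], call. = FALSE)
    c(lo$objective, hi$objective)
  })
  tibble::tibble(id = ids,
                 min = vapply(rng, `[`, numeric(1), 1),
                 max = vapply(rng, `[`, numeric(1), 2))
}
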