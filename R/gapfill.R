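#' Define a gap-filling problem
#'
#' Bundles a merged (host + universal) network, an environment, the growth
#' floor and the minimal-activity flux `epsilon` into the optimisation
#' problem: find the minimum number of universal-origin reactions whose
#' addition lets the host grow (biomass flux at or above the growth floor)
#' in the environment.
#'
#' @param network merged, curated `metabolic_network` with `origin` tags.
#' @param env environment (one-row tibble or named uptake vector).
#' @param growth_floor minimum biomass flux counted as growth (default
#'   `1e-4`).
#' @param epsilon minimal flux through an active added reaction (default
#'   `1e-8`); must satisfy `growth_floor > epsilon > 0`.
#' @param candidates candidate reaction ids; defaults to all
#'   universal-origin, non-exchange reactions. Host-origin candidates are an
#'   error.
#' @return object of class `gapfill_problem`.
#' @export
gapfill_problem <- function(network, env, growth_floor = 1e-4,
                            epsilon = 1e-8, candidates = NULL) {
  stopifnot(growth_floor > epsilon, epsilon > 0)
  rx <- network$reactions
  if (is.null(candidates)) {
    candidates <- rx$id[rx$origin == "universal" & !rx$is_exchange]
  } else {
    bad <- setdiff(candidates, rx$id)
    if (length(bad) > 0) stop("unknown candidate(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    if (any(rx$origin[match(candidates, rx$id)] != "universal"))
      stop("candidates must be universal-origin reactions", call. = FALSE)
  }
  structure(list(network = network, env = env,
                 growth_floor = growth_floor, epsilon = epsilon,
                 candidates = sort(candidates)),
            class = "gapfill_problem")
}

#' @export
print.gapfill_problem <- function(x, ...) {
  cat("<gapfill_problem> env: ", env_name(x$env), ", ",
      length(x$candidates), " candidate reactions, growth floor ",
      format(x$growth_floor), ", epsilon ", format(x$epsilon), "\n", sep = "")
  invisible(x)
}

#' Build the mixed-integer model for a gap-filling problem
#'
#' Constructs the explicit optimisation model: steady-state mass balance
#' `S v = 0`, host flux bounds, environment uptakes, a biomass lower bound
#' at the growth floor; every reversible candidate decomposed into two
#' opposing irreversible reactions so candidate fluxes are non-negative; a
#' binary indicator `b_i` per candidate direction with linking constraints
#' `b_i * epsilon <= v'_i <= b_i * u'_i`; an anti-parallel constraint
#' `b_fwd + b_rev <= 1` per split pair; objective `min sum(b_i)`. Candidate
#' directions with non-positive maximal flux `u'_i` are dropped with a
#' warning (they can never be active).
#'
#' @param problem a [gapfill_problem()].
#' @return object of class `gapfill_milp` with elements `indicators`
#'   (tibble: `var`, `parent`, `direction`, `u_prime`), `antiparallel`
#'   (list of indicator index pairs), `n_indicators`, plus the internal
#'   split-column LP system used by the solver.
#' @export
build_milp <- function(problem) {
  net <- problem$network
  bb <- fba_bounds(net, problem$env)
  sys <- make_milp_system(net, bb$lb, bb$ub, problem$candidates,
                          target_id = net$biomass,
                          floor = problem$growth_floor)
  sys$problem <- problem
  sys
}

# Shared builder for "minimise the number of open candidate reactions subject
# to flux through `target_id` >= floor" models; used by the gap-filler (target
# = biomass) and by energy-cycle detection (target = a dissipation reaction,
# all exchanges closed).
make_milp_system <- function(network, lb, ub, candidates, target_id, floor) {
  rx <- network$reactions
  cand_idx <- match(sort(candidates), rx$id)

  S <- as.matrix(network$S)
  n <- ncol(S)

  bi <- match(target_id, rx$id)
  lb[bi] <- max(lb[bi], floor)

  # split candidate columns: forward part reuses the original column with
  # bounds [0, ub]; a reverse part column -S[, j] with bounds [0, -lb] is
  # appended for candidates that admit negative flux
  ind <- list(); extra_cols <- list(); extra_lb <- numeric(); extra_ub <- numeric()
  for (j in cand_idx) {
    id <- rx$id[j]
    if (ub[j] > 0) {
      ind[[length(ind) + 1]] <- tibble::tibble(
        var = paste0(id, "..fwd"), parent = id, direction = "fwd",
        u_prime = ub[j], col = j)
    } else {
      warning("candidate direction ", id, "..fwd dropped (u' <= 0)", call. = FALSE)
    }
    if (lb[j] < 0) {
      extra_cols[[length(extra_cols) + 1]] <- -S[, j]
      extra_lb <- c(extra_lb, 0); extra_ub <- c(extra_ub, -lb[j])
      ind[[length(ind) + 1]] <- tibble::tibble(
        var = paste0(id, "..rev"), parent = id, direction = "rev",
        u_prime = -lb[j], col = n + length(extra_cols))
    }
    lb[j] <- max(lb[j], 0)  # forward part is non-negative
  }
  indicators <- dplyr::bind_rows(ind)
  if (nrow(indicators) == 0)
    indicators <- tibble::tibble(var = character(), parent = character(),
                                 direction = character(), u_prime = numeric(),
                                 col = integer())
  Se <- if (length(extra_cols) > 0) cbind(S, do.call(cbind, extra_cols)) else S
  lbe <- c(lb, extra_lb); ube <- c(ub, extra_ub)

  antiparallel <- indicators |>
    dplyr::group_by(.data$parent) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(pair = list(.data$var), .groups = "drop")

  structure(list(indicators = indicators,
                 n_indicators = nrow(indicators),
                 antiparallel = antiparallel$pair,
                 S = Se, lb = lbe, ub = ube,
                 n_orig = n,
                 reaction_ids = rx$id,
                 biomass_col = bi),
            class = "gapfill_milp")
}

#' @export
print.gapfill_milp <- function(x, ...) {
  cat("<gapfill_milp> ", x$n_indicators, " binary indicators, ",
      length(x$antiparallel), " anti-parallel constraints, ",
      nrow(x$S), " mass-balance rows\n", sep = "")
  invisible(x)
}

# ---- branch-and-bound core -------------------------------------------------
#
# Minimise the number of open candidate (merged) reactions subject to the LP
# system in `milp` being feasible. A candidate is "open" when its split part
# columns keep their bounds and "closed" when they are pinned to zero; the
# relaxation objective sum(v'_part / u'_part) over undecided candidates is a
# valid lower bound on the number of additional active candidates. Exclusion
# constraints are sets of parent ids that must not all be open (integer cuts
# sum_{i in B} b_i <= |B| - 1 at the merged level).

milp_parts <- function(milp) {
  split(seq_len(nrow(milp$indicators)), milp$indicators$parent)
}

# bounds with the given candidate parents closed
milp_node_bounds <- function(milp, parts, closed) {
  lb <- milp$lb; ub <- milp$ub
  for (p in closed) {
    cols <- milp$indicators$col[parts[[p]]]
    lb[cols] <- 0; ub[cols] <- 0
  }
  list(lb = lb, ub = ub)
}

milp_feasible_set <- function(milp, parts, open_set) {
  closed <- setdiff(names(parts), open_set)
  bb <- milp_node_bounds(milp, parts, closed)
  res <- lp_solve(numeric(ncol(milp$S)), milp$S, rep(0, nrow(milp$S)),
                  bb$lb, bb$ub)
  res$status == "optimal"
}

milp_minimalise <- function(milp, parts, set) {
  for (p in sort(set)) {
    if (p %in% set && milp_feasible_set(milp, parts, setdiff(set, p)))
      set <- setdiff(set, p)
  }
  sort(set)
}

milp_search <- function(milp, exclusions = list(), node_cap = 100000L) {
  parts <- milp_parts(milp)
  parents <- sort(names(parts))
  m <- nrow(milp$S); nv <- ncol(milp$S)
  b0 <- rep(0, m)
  weight_all <- numeric(nv)
  weight_all[milp$indicators$col] <- 1 / pmax(milp$indicators$u_prime, 1e-12)

  best_size <- Inf; best_set <- NULL
  stack <- list(list(F1 = character(), F0 = character()))
  nodes <- 0L
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_cap) stop("branch-and-bound node cap exceeded", call. = FALSE)
    F1 <- node$F1; F0 <- node$F0

    # unit propagation over exclusion cuts
    pruned <- FALSE
    repeat {
      changed <- FALSE
      for (M in exclusions) {
        rem <- setdiff(M, F1)
        if (length(rem) == 0) { pruned <- TRUE; break }
        if (length(rem) == 1 && !(rem %in% F0)) { F0 <- c(F0, rem); changed <- TRUE }
      }
      if (pruned || !changed) break
    }
    if (pruned || length(F1) >= best_size) next

    bb <- milp_node_bounds(milp, parts, F0)
    free <- setdiff(parents, c(F1, F0))
    obj <- weight_all
    decided_cols <- milp$indicators$col[unlist(parts[F1], use.names = FALSE)]
    obj[decided_cols] <- 0
    relax <- lp_solve(obj, milp$S, b0, bb$lb, bb$ub)
    if (relax$status != "optimal") next
    lbnd <- length(F1) + max(0, ceiling(relax$objective - 1e-7))
    if (lbnd >= best_size) next

    # candidate activity in the relaxation, by parent
    act <- vapply(parents, function(p) {
      sum(relax$x[milp$indicators$col[parts[[p]]]])
    }, numeric(1))
    supp <- parents[!(parents %in% F0) & act > 1e-9]
    T0 <- sort(union(F1, supp))
    clean <- function(s) !any(vapply(exclusions, function(M) all(M %in% s),
                                     logical(1)))
    if (milp_feasible_set(milp, parts, T0)) {
      Tmin <- milp_minimalise(milp, parts, T0)
      for (Tc in list(Tmin, T0)) {  # fall back to T0 if Tmin hits a cut
        if (length(Tc) < best_size && clean(Tc)) {
          best_size <- length(Tc); best_set <- Tc; break
        }
      }
    }
    free_active <- intersect(free, supp)
    if (length(free_active) == 0) next
    jb <- free_active[order(-act[free_active], free_active)][1]
    # closed child explored first (LIFO)
    stack[[length(stack) + 1]] <- list(F1 = c(F1, jb), F0 = F0)
    stack[[length(stack) + 1]] <- list(F1 = F1, F0 = c(F0, jb))
  }
  if (is.null(best_set) && !is.finite(best_size))
    return(list(status = "infeasible", set = NULL, size = NA_integer_))
  list(status = "optimal", set = best_set, size = length(best_set))
}

# Verify a solution set by plain LP: open exactly `set`, force each member to
# carry at least epsilon flux in its observed direction, maximise biomass.
milp_verify <- function(milp, parts, set, epsilon) {
  closed <- setdiff(names(parts), set)
  bb <- milp_node_bounds(milp, parts, closed)
  obj <- numeric(ncol(milp$S)); obj[milp$biomass_col] <- 1
  res <- lp_solve(obj, milp$S, rep(0, nrow(milp$S)), bb$lb, bb$ub, maximize = TRUE)
  if (res$status != "optimal") return(NULL)
  ind <- milp$indicators
  indicator_values <- stats::setNames(integer(nrow(ind)), ind$var)
  lb <- bb$lb; ub <- bb$ub
  for (p in set) {
    rows <- parts[[p]]
    vals <- res$x[ind$col[rows]]
    k <- rows[which.max(vals)]   # active direction: the one carrying flux
    lb[ind$col[k]] <- max(lb[ind$col[k]], epsilon)
    other <- setdiff(rows, k)
    if (length(other) > 0) ub[ind$col[other]] <- 0  # anti-parallel
    indicator_values[k] <- 1L
  }
  res2 <- lp_solve(obj, milp$S, rep(0, nrow(milp$S)), lb, ub, maximize = TRUE)
  if (res2$status != "optimal") res2 <- res  # epsilon forcing degenerate; keep LP optimum
  list(biomass = res2$objective,
       fluxes = stats::setNames(res2$x[seq_len(milp$n_orig)], milp$reaction_ids),
       indicator_values = indicator_values)
}

new_gapfill_solution <- function(set, verification, env) {
  structure(list(active_set = set, size = length(set),
                 indicator_values = verification$indicator_values,
                 biomass_flux = verification$biomass,
                 fluxes = verification$fluxes,
                 env = env_name(env)),
            class = "gapfill_solution")
}

#' @export
print.gapfill_solution <- function(x, ...) {
  cat("<gapfill_solution> env: ", x$env, ", size ", x$size,
      if (x$size > 0) paste0(" {", paste(x$active_set, collapse = ", "), "}"),
      ", biomass ", format(x$biomass_flux), "\n", sep = "")
  invisible(x)
}

#' Minimum reaction additions enabling growth
#'
#' Solves the gap-filling model exactly by LP-based branch-and-bound over
#' the candidate indicator variables: the minimum number of universal
#' reactions whose addition gives biomass flux at or above the growth
#' floor, together with one optimal added-reaction set.
#'
#' @param problem a [gapfill_problem()] (or a prebuilt [build_milp()] model).
#' @return a `gapfill_solution` (fields `active_set`, `size`,
#'   `indicator_values`, `biomass_flux`), or an object of class
#'   `gapfill_infeasible` when even the full pool cannot support growth
#'   ("environment unreachable from pool", distinct from solver failure).
#' @export
solve_min_additions <- function(problem) {
  milp <- if (inherits(problem, "gapfill_milp")) problem else build_milp(problem)
  prob <- milp$problem
  parts <- milp_parts(milp)
  res <- milp_search(milp)
  if (res$status == "infeasible") {
    return(structure(list(env = env_name(prob$env),
                          reason = "environment unreachable from pool"),
                     class = "gapfill_infeasible"))
  }
  ver <- milp_verify(milp, parts, res$set, prob$epsilon)
  new_gapfill_solution(res$set, ver, prob$env)
}

#' Enumerate all minimal growth-enabling reaction sets
#'
#' Repeatedly re-solves the gap-filling model, after each solution adding an
#' integer-cut exclusion constraint (`sum_{i: B_i = 1} b_i <= sum(B) - 1`)
#' that forbids rediscovering any already-found set; collection stops when
#' the next optimum is larger than the minimal size or the model becomes
#' infeasible, at which point the enumeration is exhaustive.
#'
#' @param problem a [gapfill_problem()].
#' @param max_iter cap on the number of enumerated sets (default 10000); if
#'   reached, the enumeration is returned with `exhausted = FALSE`.
#' @return object of class `minimal_set_enumeration`: fields `env`,
#'   `minimal_size`, `sets` (list of `gapfill_solution`), `exhausted`.
#' @export
enumerate_minimal_sets <- function(problem, max_iter = 10000L) {
  milp <- if (inherits(problem, "gapfill_milp")) problem else build_milp(problem)
  prob <- milp$problem
  parts <- milp_parts(milp)
  first <- milp_search(milp)
  if (first$status == "infeasible")
    stop("gap-filling infeasible: environment unreachable from pool", call. = FALSE)
  s0 <- first$size
  sets <- list(first$set)
  exhausted <- FALSE
  if (s0 == 0L) {
    exhausted <- TRUE  # the empty set is the unique minimal solution
  } else {
    exclusions <- list(first$set)
    repeat {
      if (length(sets) >= max_iter) break
      nxt <- milp_search(milp, exclusions)
      if (nxt$status == "infeasible" || nxt$size > s0) { exhausted <- TRUE; break }
      sets[[length(sets) + 1]] <- nxt$set
      exclusions[[length(exclusions) + 1]] <- nxt$set
    }
  }
  solutions <- purrr::map(sets, function(s) {
    new_gapfill_solution(s, milp_verify(milp, parts, s, prob$epsilon), prob$env)
  })
  structure(list(env = env_name(prob$env), minimal_size = s0,
                 sets = solutions, exhausted = exhausted),
            class = "minimal_set_enumeration")
}

#' @export
print.gapfill_infeasible <- function(x, ...) {
  cat("<gapfill_infeasible> env: ", x$env, " (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' @export
print.minimal_set_enumeration <- function(x, ...) {
  cat("<minimal_set_enumeration> env: ", x$env, ", minimal size ",
      x$minimal_size, ", ", length(x$sets), " set(s), exhausted: ",
      x$exhausted, "\n", sep = "")
  invisible(x)
}
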