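# Toy networks used across tests, built in code.

# Linear chain: uptake of A (bounded), conversion to B, biomass drain of B.
chain_toy <- function() {
  metabolic_network(tibble::tibble(
    id = c("EX_A", "R_AB", "BIOMASS"),
    equation = c("A <->", "A -> B", "B ->")), "BIOMASS")
}

# Branched toy: route 1 yields 1 biomass per A, route 2 yields 2 per A.
branched_toy <- function() {
  metabolic_network(tibble::tibble(
    id = c("EX_A", "R1", "R2", "BIOMASS"),
    equation = c("A <->", "1 A -> 1 B", "1 A -> 2 B", "B ->")), "BIOMASS")
}

env_A <- function(bound = 10) growth_env("envA", c(EX_A = bound))
env_empty <- function() growth_env("empty", stats::setNames(numeric(0), character(0)))

# Host + pool with planted one-step (P needs rP) and two-step (Q needs
# {rQ1, rQ2} or {rQ3, rQ4}) innovations, plus a dead-end decoy.
planted_universal <- function() {
  host <- metabolic_network(tibble::tibble(
    id = c("EX_C", "R_CX", "BIOMASS"),
    equation = c("C <->", "C -> X", "X ->")), "BIOMASS")
  pool <- metabolic_network(tibble::tibble(
    id = c("EX_P", "rP", "EX_Q", "rQ1", "rQ2", "rQ3", "rQ4", "dead"),
    equation = c("P <->", "P -> X", "Q <->", "Q -> Y", "Y -> X",
                 "Q -> Z", "Z -> X", "W -> V")))
  list(host = host, pool = pool, universal = merge_networks(host, pool),
       envP = growth_env("C:P", c(EX_P = 10), element = "C", nutrient = "P"),
       envQ = growth_env("C:Q", c(EX_Q = 10), element = "C", nutrient = "Q"),
       envC = growth_env("base", c(EX_C = 10)))
}

# Independent LP cross-check via pracma::linprog with equalities and bounds
# rewritten as inequality rows (its native lb/ub path is unusable).
pracma_fba_max <- function(network, env) {
  bb <- stepstone:::fba_bounds(network, env)
  S <- as.matrix(network$S)
  n <- ncol(S)
  obj <- as.numeric(network$reactions$id == network$biomass)
  # shift x = v - lb so variables are non-negative
  A <- diag(n); b <- bb$ub - bb$lb
  beq <- -as.vector(S %*% bb$lb)
  res <- pracma::linprog(cc = obj, A = A, b = b, Aeq = S, beq = beq,
                         maximize = TRUE, maxiter = 1000)
  if (res$errno != 1) return(NA_real_)
  res$fval + sum(obj * bb$lb)
}

# Brute-force gap-fill oracle: exhaustive FBA over candidate subsets of
# size <= max_size; returns the minimal size and all minimal sets.
subset_gapfill_oracle <- function(network, env, candidates, max_size,
                                  floor = 1e-4) {
  rx <- network$reactions
  cand_idx <- match(candidates, rx$id)
  grows <- function(set_ids) {
    stepstone:::activate_and_grow(network, env, cand_idx,
                                  match(set_ids, rx$id)) >= floor
  }
  if (grows(character())) return(list(size = 0L, sets = list(character())))
  for (k in seq_len(max_size)) {
    hits <- Filter(grows, utils::combn(sort(candidates), k, simplify = FALSE))
    if (length(hits) > 0) return(list(size = k, sets = hits))
  }
  list(size = NA_integer_, sets = list())
}

set_of_sets_equal <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(s) paste(sort(s), collapse = ";"),
                                  character(1)))
  identical(norm(a), norm(b))
}
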