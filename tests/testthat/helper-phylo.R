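# Exhaustive-minimisation oracle for ancestral reconstruction: enumerates
# all 2^Nnode internal labelings, scoring gains/losses on edges plus the
# stem convention (presence at the root costs one gain). Returns the
# minimum cost and all labelings attaining it.
exhaustive_parsimony <- function(tree, tip_states, gain_cost = 2,
                                 loss_cost = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tip_states <- tip_states[tree$tip.label]
  edge <- tree$edge
  best <- Inf; labelings <- list()
  for (code in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(nint)]
    full <- c(unname(tip_states), lab)
    from <- full[edge[, 1]]; to <- full[edge[, 2]]
    cost <- sum((from == 0 & to == 1) * gain_cost +
                  (from == 1 & to == 0) * loss_cost) +
      gain_cost * (full[ntip + 1] == 1)
    if (cost < best - 1e-9) { best <- cost; labelings <- list(lab) }
    else if (cost < best + 1e-9) labelings <- c(labelings, list(lab))
  }
  list(cost = best, labelings = labelings)
}

# Exact one-sided signed-rank null by direct enumeration of all 2^n sign
# vectors (independent of the package's DP implementation).
enumerate_signed_rank_p <- function(d) {
  d <- d[abs(d) > 1e-12]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  count <- 0L
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code))[seq_len(n)]
    if (sum(r[signs == 1]) >= w_obs - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# Exact one-sided rank-sum null by enumerating all subsets of the combined
# sample assigned to group a.
enumerate_rank_sum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  subs <- utils::combn(n, length(a), simplify = FALSE)
  mean(vapply(subs, function(s) sum(r[s]) >= w_obs - 1e-9, logical(1)))
}

# Hand-set profile from explicit node states (bypasses reconstruction).
manual_profile <- function(tree, states_matrix) {
  structure(list(tree = tree, states = states_matrix),
            class = "phylo_profile")
}
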