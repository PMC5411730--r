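# ---- GPR (gene-protein-reaction) boolean rules -----------------------------

gpr_tokenise <- function(text) {
  pat <- "\\(|\\)|[Aa][Nn][Dd]\\b|[Oo][Rr]\\b|&&?|\\|\\|?|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty GPR expression", call. = FALSE)
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  # anything not matched by the token pattern (other than whitespace) is an error
  rest <- gsub(pat, "", text, perl = TRUE)
  if (grepl("\\S", rest)) {
    bad <- regexpr("\\S", rest)
    stop("malformed GPR expression near position ", bad, ": '", text, "'",
         call. = FALSE)
  }
  list(tokens = toks, pos = as.integer(m))
}

#' Parse a GPR boolean expression
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := '(' expr ')' | gene`. `AND`/`OR` are case-insensitive;
#' `&`/`|` forms are accepted. AND encodes an enzyme complex (all subunits
#' required), OR encodes isoenzymes (any one suffices).
#'
#' @param text GPR string, e.g. `"(g1 AND g2) OR g3"`.
#' @return parse tree: a gene id (character) or a list
#'   `list(op = "and"/"or", args = list(...))`.
#' @export
parse_gpr <- function(text) {
  tk <- gpr_tokenise(text)
  toks <- tk$tokens; pos <- tk$pos; i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  advance <- function() { i <<- i + 1L }
  fail <- function(msg) {
    p <- if (i <= length(pos)) pos[i] else nchar(text) + 1L
    stop("GPR parse error at position ", p, ": ", msg, call. = FALSE)
  }
  is_op <- function(t, op) !is.na(t) && grepl(
    if (op == "and") "^([Aa][Nn][Dd]|&&?)$" else "^([Oo][Rr]|\\|\\|?)$", t)
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(e)
    }
    if (t == ")" || is_op(t, "and") || is_op(t, "or"))
      fail(paste0("unexpected '", t, "'"))
    advance()
    t
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) { advance(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) { advance(); args <- c(args, list(parse_term())) }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  out <- parse_expr()
  if (!is.na(peek())) fail(paste0("unexpected trailing '", peek(), "'"))
  out
}

gpr_genes <- function(node) {
  if (is.character(node)) return(node)
  unique(unlist(lapply(node$args, gpr_genes)))
}

eval_gpr_tree <- function(node, presence) {
  if (is.character(node)) return(presence[[node]])
  vals <- vapply(node$args, eval_gpr_tree, numeric(1), presence = presence)
  if (node$op == "and") as.numeric(all(vals == 1)) else as.numeric(any(vals == 1))
}

#' Evaluate a GPR rule against gene presence
#'
#' A reaction backed by an enzyme complex (`AND`) is present only when all
#' complex genes are present; isoenzymes (`OR`) require at least one.
#' Genes missing from `gene_presence` default to absent and are reported
#' via a message.
#'
#' @param gpr GPR string or a [parse_gpr()] tree.
#' @param gene_presence named vector of 0/1 gene presence values.
#' @return 0 or 1.
#' @export
eval_gpr <- function(gpr, gene_presence) {
  tree <- if (is.character(gpr) && length(gpr) == 1 && !is.list(gpr))
    parse_gpr(gpr) else gpr
  genes <- gpr_genes(tree)
  missing <- setdiff(genes, names(gene_presence))
  if (length(missing) > 0) {
    message("gene(s) without presence data treated as absent: ",
            paste(missing, collapse = ", "))
    gene_presence <- c(gene_presence,
                       stats::setNames(rep(0, length(missing)), missing))
  }
  if (!all(gene_presence[genes] %in% c(0, 1)))
    stop("gene presence values must be 0/1", call. = FALSE)
  eval_gpr_tree(tree, gene_presence)
}

#' Map gene presence profiles to reaction presence profiles
#'
#' Evaluates each reaction's GPR rule in every species (tip), turning a
#' genes-by-species 0/1 matrix into a reactions-by-species 0/1 matrix.
#'
#' @param gpr_table data frame with columns `reaction`, `gpr`.
#' @param gene_presence genes-by-species 0/1 matrix (rownames = gene ids).
#' @return reactions-by-species 0/1 matrix.
#' @export
map_genes_to_reactions <- function(gpr_table, gene_presence) {
  stopifnot(all(c("reaction", "gpr") %in% names(gpr_table)))
  trees <- lapply(gpr_table$gpr, parse_gpr)
  out <- t(vapply(trees, function(tr) {
    apply(gene_presence, 2, function(col) eval_gpr(tr, col))
  }, numeric(ncol(gene_presence))))
  # single-species edge case: vapply returns a vector
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(gpr_table))
  dimnames(out) <- list(gpr_table$reaction, colnames(gene_presence))
  out
}

# ---- ancestral state reconstruction ----------------------------------------

#' Ancestral presence/absence by weighted parsimony with DELTRAN
#'
#' Sankoff minimum-cost reconstruction of binary presence/absence states on
#' a rooted bifurcating tree with asymmetric transition costs
#' (`cost(0 -> 1) = gain_cost`, `cost(1 -> 0) = loss_cost`, default 2:1 so
#' gains are penalised over losses). Among minimum-cost labelings,
#' ambiguities are resolved by delayed transformation (DELTRAN): in the
#' root-to-tip pass an ambiguous node adopts its parent's state, pushing
#' state changes toward the tips.
#'
#' Presence at the root is itself penalised as one gain, as if the tree
#' hung from a virtual stem edge leading out of an all-absent origin, and a
#' root tie resolves to absence. Gains are the events under study here;
#' without the stem convention an asymmetric cost scheme would place free
#' presence at the root and so manufacture spurious ancestral presence and
#' losses. The reported `cost` includes the stem gain when the root is
#' reconstructed as present.
#'
#' @param tree rooted, strictly bifurcating `ape::phylo`; polytomies are
#'   rejected.
#' @param tip_states binary matrix (characters x tips, colnames = tip
#'   labels) or a named 0/1 vector for a single character.
#' @param gain_cost,loss_cost positive transition penalties.
#' @return object of class `phylo_profile`: `tree`, `tip_states`, `states`
#'   (characters x all nodes, tips first then internals in ape numbering),
#'   `ancestral_states` (internal nodes only), `cost` (per-character
#'   reconstruction cost).
#' @export
reconstruct_ancestral <- function(tree, tip_states, gain_cost = 2,
                                  loss_cost = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("polytomies are not supported; resolve multifurcations first",
         call. = FALSE)
  stopifnot(gain_cost > 0, loss_cost > 0)
  if (is.vector(tip_states) && !is.matrix(tip_states))
    tip_states <- matrix(tip_states, nrow = 1,
                         dimnames = list("char1", names(tip_states)))
  if (!all(tip_states %in% c(0, 1)))
    stop("tip states must be binary 0/1", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% colnames(tip_states)))
    stop("tip_states missing tree tip(s): ",
         paste(setdiff(tree$tip.label, colnames(tip_states)), collapse = ", "),
         call. = FALSE)
  tip_states <- tip_states[, tree$tip.label, drop = FALSE]
  nch <- nrow(tip_states)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  post <- ape::reorder.phylo(tree, "postorder")$edge

  # Sankoff down-pass, vectorised over characters:
  # c0/c1[v, ] = min cost of the subtree at v given v is absent/present
  c0 <- matrix(0, nnode, nch); c1 <- matrix(0, nnode, nch)
  c0[seq_len(ntip), ] <- t(ifelse(tip_states == 0, 0, Inf))
  c1[seq_len(ntip), ] <- t(ifelse(tip_states == 1, 0, Inf))
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1]; ch <- post[k, 2]
    c0[p, ] <- c0[p, ] + pmin(c0[ch, ], gain_cost + c1[ch, ])
    c1[p, ] <- c1[p, ] + pmin(loss_cost + c0[ch, ], c1[ch, ])
  }

  states <- matrix(NA_real_, nnode, nch)
  states[seq_len(ntip), ] <- t(tip_states)
  # presence at the root itself counts as a gain (a virtual stem edge from
  # an all-absent origin); ties resolve to absence
  states[root, ] <- ifelse(c0[root, ] <= c1[root, ] + gain_cost, 0, 1)
  # preorder traceback with DELTRAN tie-breaking (adopt the parent's state)
  for (k in rev(seq_len(nrow(post)))) {
    p <- post[k, 1]; ch <- post[k, 2]
    if (ch <= ntip) next
    sp <- states[p, ]
    t0 <- ifelse(sp == 0, c0[ch, ], loss_cost + c0[ch, ])
    t1 <- ifelse(sp == 0, gain_cost + c1[ch, ], c1[ch, ])
    states[ch, ] <- ifelse(t0 < t1, 0, ifelse(t1 < t0, 1, sp))
  }

  st <- t(states)
  rownames(st) <- rownames(tip_states)
  colnames(st) <- as.character(seq_len(nnode))
  edge <- tree$edge
  from <- st[, edge[, 1], drop = FALSE]
  to <- st[, edge[, 2], drop = FALSE]
  cost <- rowSums((from == 0 & to == 1) * gain_cost +
                    (from == 1 & to == 0) * loss_cost) +
    gain_cost * (st[, root] == 1)
  structure(list(tree = tree, tip_states = tip_states, states = st,
                 ancestral_states = st[, (ntip + 1):nnode, drop = FALSE],
                 cost = cost, gain_cost = gain_cost, loss_cost = loss_cost),
            class = "phylo_profile")
}

#' @export
print.phylo_profile <- function(x, ...) {
  cat("<phylo_profile> ", nrow(x$states), " character(s) on ",
      length(x$tree$tip.label), " tips; reconstruction cost ",
      paste(format(x$cost), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tally ancestor/descendant edge patterns for a reaction pair
#'
#' Every tree edge contributes one observation of the ancestor's and
#' descendant's joint presence pattern for reactions A and B. Pattern
#' notation: `a10_d11` is an edge whose ancestor has A present and B absent
#' and whose descendant has both present (a contingent gain of B);
#' `a00_d11` is a co-gain of both on one edge.
#'
#' @param profile a [reconstruct_ancestral()] result (states for both
#'   reactions must be present).
#' @param pair character vector `c(A, B)` of two character (reaction) names.
#' @return object of class `edge_event_table` with counts `a10_d11`,
#'   `a10_dXX_total`, `a00_d01`, `a00_dXX_total`, `a00_d11`,
#'   `a00_d10_or_d01`.
#' @export
tabulate_edge_events <- function(profile, pair) {
  stopifnot(inherits(profile, "phylo_profile"), length(pair) == 2)
  miss <- setdiff(pair, rownames(profile$states))
  if (length(miss) > 0)
    stop("no reconstructed states for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  A <- profile$states[pair[1], ]; B <- profile$states[pair[2], ]
  e <- profile$tree$edge
  aA <- A[e[, 1]]; aB <- B[e[, 1]]; dA <- A[e[, 2]]; dB <- B[e[, 2]]
  a10 <- aA == 1 & aB == 0
  a00 <- aA == 0 & aB == 0
  structure(list(pair = pair,
                 a10_d11 = sum(a10 & dA == 1 & dB == 1),
                 a10_dXX_total = sum(a10),
                 a00_d01 = sum(a00 & dA == 0 & dB == 1),
                 a00_dXX_total = sum(a00),
                 a00_d11 = sum(a00 & dA == 1 & dB == 1),
                 a00_d10_or_d01 = sum(a00 & xor(dA == 1, dB == 1))),
            class = "edge_event_table")
}

#' Contingent-gain fraction of a reaction pair
#'
#' `p1` is the rate at which B is gained on edges where A is already
#' present (and B absent) in the ancestor; `p2` the rate at which B is
#' gained on edges where both are absent in the ancestor. The contingent
#' gain fraction `f = p1 / (p1 + p2)` is 0.5 when a gain of B is
#' independent of the presence of A. `f` is undefined (NA) when a
#' denominator is zero or `p1 + p2 = 0`; undefined fractions are excluded
#' from downstream tests.
#'
#' @param table an [tabulate_edge_events()] result.
#' @return object of class `contingent_gain_result` with `p1`, `p2`, `f`.
#' @export
contingent_gain <- function(table) {
  p1 <- if (table$a10_dXX_total > 0) table$a10_d11 / table$a10_dXX_total else NA_real_
  p2 <- if (table$a00_dXX_total > 0) table$a00_d01 / table$a00_dXX_total else NA_real_
  f <- if (!is.na(p1) && !is.na(p2) && (p1 + p2) > 0) p1 / (p1 + p2) else NA_real_
  structure(list(pair = table$pair, p1 = p1, p2 = p2, f = f),
            class = "contingent_gain_result")
}

#' @export
print.contingent_gain_result <- function(x, ...) {
  cat("<contingent_gain_result> pair (", x$pair[1], ", ", x$pair[2],
      "): p1 = ", format(x$p1), ", p2 = ", format(x$p2),
      ", f = ", format(x$f), "\n", sep = "")
  invisible(x)
}

#' Co-gain fraction of a reaction pair
#'
#' Among edges where both reactions are ancestrally absent, the fraction of
#' gain events acquiring both simultaneously: `f = n1 / (n1 + n2)` with
#' `n1` the co-gains (`a00_d11`) and `n2` the single gains (`a00_d10` or
#' `a00_d01`). Undefined (NA) when no gain event occurred.
#'
#' @param table an [tabulate_edge_events()] result.
#' @return object of class `cogain_result` with `n1`, `n2`, `f`.
#' @export
cogain <- function(table) {
  n1 <- table$a00_d11
  n2 <- table$a00_d10_or_d01
  f <- if (n1 + n2 > 0) n1 / (n1 + n2) else NA_real_
  structure(list(pair = table$pair, n1 = n1, n2 = n2, f = f),
            class = "cogain_result")
}

#' @export
print.cogain_result <- function(x, ...) {
  cat("<cogain_result> pair (", x$pair[1], ", ", x$pair[2],
      "): n1 = ", x$n1, ", n2 = ", x$n2, ", f = ", format(x$f), "\n", sep = "")
  invisible(x)
}

# ---- exact Wilcoxon machinery ----------------------------------------------
#
# stats::wilcox.test switches to a normal approximation in the presence of
# ties or zeros; the analyses here routinely produce tied fractions (e.g.
# many pairs with f = 1), so the exact conditional null distributions are
# computed by generating-function dynamic programming over doubled midranks.
# Cross-checked against stats::wilcox.test on tie-free data in the tests.

# P(W >= w_obs) where W = sum of ranks of positive d under random signs.
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r2 <- round(2 * rank(abs(d)))           # doubled midranks: exact integers
  w_obs2 <- round(2 * sum(rank(abs(d))[d > 0]))
  total <- sum(r2)
  dp <- numeric(total + 1); dp[1] <- 1    # dp[w + 1] = P(W2 = w)
  for (r in r2) {
    shifted <- c(rep(0, r), dp[seq_len(total + 1 - r)])
    dp <- 0.5 * dp + 0.5 * shifted
  }
  sum(dp[(w_obs2 + 1):(total + 1)])
}

# P(W_x >= w_obs) for the rank-sum of group x within the combined ranking,
# over all equally likely subsets of the combined sample.
rank_sum_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r2 <- round(2 * rank(c(x, y)))
  w_obs2 <- sum(r2[seq_len(nx)])
  total <- sum(r2)
  # dp[k + 1, w + 1] = number of k-subsets with doubled rank sum w
  dp <- matrix(0, nx + 1, total + 1); dp[1, 1] <- 1
  for (r in r2) {
    for (k in nx:1) {
      idx <- seq_len(total + 1 - r)
      dp[k + 1, idx + r] <- dp[k + 1, idx + r] + dp[k, idx]
    }
  }
  sum(dp[nx + 1, (w_obs2 + 1):(total + 1)]) / choose(n, nx)
}

#' One-tailed signed-rank test of contingent-gain fractions against 0.5
#'
#' Tests whether the distribution of contingent-gain fractions lies above
#' 0.5 (the independence expectation) by a one-tailed one-sample Wilcoxon
#' signed-rank test. Zero differences are dropped by the standard
#' convention; undefined fractions are excluded (and counted). The exact
#' conditional null distribution is used up to `exact_limit` non-zero
#' differences, beyond that a tie-corrected normal approximation.
#'
#' @param f numeric vector of fractions (possibly with NAs), or a list of
#'   `contingent_gain_result` objects.
#' @param mu null value (default 0.5).
#' @param exact_limit maximum n for the exact null (default 200).
#' @return list of class `contingent_gain_test`: `p_value`, `n_used`,
#'   `n_excluded`, `mean_f`.
#' @export
contingent_gain_test <- function(f, mu = 0.5, exact_limit = 200) {
  if (is.list(f)) f <- vapply(f, `[[`, numeric(1), "f")
  n_excluded <- sum(is.na(f))
  f <- f[!is.na(f)]
  if (length(f) == 0) stop("no defined fractions to test", call. = FALSE)
  d <- f - mu
  mean_f <- mean(f)
  d_nz <- d[abs(d) > .Machine$double.eps^0.5]
  p <- if (length(d_nz) == 0) {
    1
  } else if (length(d_nz) <= exact_limit) {
    signed_rank_exact_p(d_nz)
  } else {
    stats::wilcox.test(d_nz, mu = 0, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  }
  structure(list(p_value = p, n_used = length(d_nz),
                 n_excluded = n_excluded, mean_f = mean_f),
            class = "contingent_gain_test")
}

#' @export
print.contingent_gain_test <- function(x, ...) {
  cat("<contingent_gain_test> mean f = ", format(x$mean_f),
      ", n = ", x$n_used, " (", x$n_excluded, " undefined excluded), ",
      "one-tailed P = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' One-sided rank-sum comparison of co-gain fractions between pair groups
#'
#' Tests whether co-gain fractions in `group_a` are stochastically greater
#' than in `group_b` (one-sided Wilcoxon rank-sum). NAs (undefined
#' fractions) are removed. Exact conditional null up to `exact_limit`
#' combined observations, tie-corrected normal approximation beyond.
#'
#' @param group_a,group_b numeric vectors of co-gain fractions.
#' @param exact_limit maximum combined n for the exact null (default 100).
#' @return list with `p_value`, `n_a`, `n_b`.
#' @export
cogain_group_test <- function(group_a, group_b, exact_limit = 100) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must contain defined fractions", call. = FALSE)
  p <- if (length(a) + length(b) <= exact_limit) {
    rank_sum_exact_p(a, b)
  } else {
    stats::wilcox.test(a, b, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  }
  list(p_value = p, n_a = length(a), n_b = length(b))
}

#' Randomization test for elevated co-gain
#'
#' Breaks the pairing between reactions and reshuffles the pooled members
#' into new random pairs, recomputing the mean co-gain fraction each time.
#' The p-value is `(n1 + 1) / (reps + 1)` where `n1` counts replicates
#' whose shuffled mean is at least the observed mean.
#'
#' @param profile a [reconstruct_ancestral()] result covering all member
#'   reactions.
#' @param pairs two-column data frame (or matrix) of reaction pairs.
#' @param reps number of shuffles (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return list of class `cogain_randomization`: `p_value`, `observed_mean`,
#'   `shuffled_means`, `reps`.
#' @export
cogain_randomization <- function(profile, pairs, reps = 1000, seed = 1) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2)
    stop("randomization needs at least two pairs", call. = FALSE)
  mean_cogain <- function(pm) {
    fs <- vapply(seq_len(nrow(pm)), function(i) {
      cogain(tabulate_edge_events(profile, pm[i, ]))$f
    }, numeric(1))
    mean(fs, na.rm = TRUE)
  }
  observed <- mean_cogain(pairs)
  if (!is.finite(observed))
    stop("no pair has a defined co-gain fraction; nothing to test",
         call. = FALSE)
  members <- as.vector(t(pairs))
  shuffled <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      mean_cogain(matrix(sample(members), ncol = 2, byrow = TRUE))
    }, numeric(1))
  })
  # a replicate whose fractions are all undefined cannot exceed the observed
  n1 <- sum(shuffled >= observed, na.rm = TRUE)
  structure(list(p_value = (n1 + 1) / (reps + 1), observed_mean = observed,
                 shuffled_means = shuffled, reps = reps),
            class = "cogain_randomization")
}

#' @export
print.cogain_randomization <- function(x, ...) {
  cat("<cogain_randomization> observed mean f = ", format(x$observed_mean),
      ", P = ", format(x$p_value), " (", x$reps, " shuffles)\n", sep = "")
  invisible(x)
}

# Run code with a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
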