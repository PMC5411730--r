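# ---- toy metabolic scenarios -----------------------------------------------

#' Generate a toy host/pool scenario with planted innovations
#'
#' Builds a small viable host (uptake of one source per element, a
#' catabolic reaction coupling carbon to energy, a biomass reaction and an
#' ATP-hydrolysis maintenance reaction) plus a universal reaction pool with
#' planted innovation pathways of known ground truth:
#'
#' * `n_one_step` nutrients each utilisable after adding exactly one pool
#'   reaction (minimal set size 1);
#' * `n_two_step` nutrients each requiring a pathway of two pool reactions
#'   (minimal set size 2), with `n_alt_sets` alternative disjoint minimal
#'   pairs per nutrient;
#' * when `share_stepping_stone` is `TRUE`, each two-step nutrient's first
#'   route converts it into the first one-step nutrient, so the pathway's
#'   second reaction is exactly that nutrient's sole reaction — the motif
#'   in which a two-reaction innovation (e.g. chorismate utilisation)
#'   shares a reaction that alone confers growth on another nutrient
#'   (e.g. L-phenylalanine), making the two-step environment accessible by
#'   purely adaptive steps;
#' * decoy pool reactions: a dead end, a jointly-dependent reversible
#'   shuttle pair, and (optionally) a planted energy-generating cycle for
#'   curation tests.
#'
#' Ground truth is verified by direct FBA at generation time: the host is
#' inviable on every planted nutrient, each recorded minimal set restores
#' growth, and every strict subset fails.
#'
#' @param n_one_step,n_two_step,n_alt_sets non-negative counts;
#'   `n_alt_sets >= 1` when `n_two_step > 0`, and `share_stepping_stone`
#'   requires `n_one_step >= 1`.
#' @param share_stepping_stone plant the shared stepping-stone motif.
#' @param seed integer seed; the pool's row order is shuffled under it (the
#'   planted structure itself is deterministic).
#' @param energy_cycle include the perpetuum-mobile decoy pair.
#' @param uptake_bound uptake bound for all environments (default 10).
#' @return object of class `toy_scenario`: `host`, `pool`
#'   (`metabolic_network`s), `base_env`, `candidates` (element/nutrient/
#'   exchange table), `dissipation` (id of the ATP-maintenance reaction),
#'   and `truth` (planted minimal sets, stepping stones, accessible
#'   two-step environments, energy-cycle reactions).
#' @export
make_toy_scenario <- function(n_one_step = 1, n_two_step = 1, n_alt_sets = 1,
                              share_stepping_stone = TRUE, seed = 1,
                              energy_cycle = TRUE, uptake_bound = 10) {
  stopifnot(n_one_step >= 0, n_two_step >= 0, n_alt_sets >= 0)
  if (n_two_step > 0 && n_alt_sets < 1)
    stop("n_alt_sets must be >= 1 when two-step nutrients are planted",
         call. = FALSE)
  if (share_stepping_stone && n_two_step > 0 && n_one_step < 1)
    stop("share_stepping_stone requires at least one one-step nutrient",
         call. = FALSE)

  host <- metabolic_network(tibble::tibble(
    id = c("EX_C0", "EX_N0", "EX_P0", "EX_S0", "R_CAT", "ATPM", "BIOMASS"),
    equation = c("C0 <->", "N0 <->", "P0 <->", "S0 <->",
                 "1 C0 + 1 ADP -> 1 X + 1 ATP",
                 "1 ATP -> 1 ADP",
                 "1 X + 1 ATP + 1 N0 + 1 P0 + 1 S0 -> 1 ADP")),
    biomass_reaction = "BIOMASS")

  pool_rows <- list()
  add <- function(id, eq) pool_rows[[length(pool_rows) + 1]] <<-
    tibble::tibble(id = id, equation = eq)

  one_step <- character(n_one_step)
  for (i in seq_len(n_one_step)) {
    nut <- paste0("P", i)
    add(paste0("EX_", nut), paste0(nut, " <->"))
    one_step[i] <- paste0("rOne_", i)
    add(one_step[i], paste0("1 ", nut, " + 1 ADP -> 1 X + 1 ATP"))
  }

  two_truth <- list()
  for (j in seq_len(n_two_step)) {
    nut <- paste0("Q", j)
    add(paste0("EX_", nut), paste0(nut, " <->"))
    sets <- list()
    for (m in seq_len(n_alt_sets)) {
      if (m == 1 && share_stepping_stone) {
        ra <- paste0("rTwo_", j, "_1a")
        add(ra, paste0("1 ", nut, " -> 1 P1"))
        sets[[m]] <- sort(c(ra, one_step[1]))
      } else {
        inter <- paste0("I_", j, "_", m)
        ra <- paste0("rTwo_", j, "_", m, "a")
        rb <- paste0("rTwo_", j, "_", m, "b")
        add(ra, paste0("1 ", nut, " -> 1 ", inter))
        add(rb, paste0("1 ", inter, " + 1 ADP -> 1 X + 1 ATP"))
        sets[[m]] <- sort(c(ra, rb))
      }
    }
    two_truth[[j]] <- list(nutrient = nut, env = paste0("C:", nut),
                           sets = sets,
                           accessible = share_stepping_stone)
  }

  # decoys: a dead end and a jointly-dependent shuttle pair
  add("rDead", "1 D1 -> 1 D2")
  add("rShuttleA", "1 X -> 1 X2")
  add("rShuttleB", "1 X2 -> 1 X")
  cycle_rxns <- character()
  if (energy_cycle) {
    add("rCycA", "1 W + 1 ADP -> 1 Z + 1 ATP")
    add("rCycB", "1 Z -> 1 W")
    cycle_rxns <- c("rCycA", "rCycB")
  }

  pool_tab <- dplyr::bind_rows(pool_rows)
  pool_tab <- with_seed(seed, pool_tab[sample(nrow(pool_tab)), ])
  pool <- metabolic_network(pool_tab)

  base_env <- growth_env(
    "base", c(EX_C0 = uptake_bound, EX_N0 = uptake_bound,
              EX_P0 = uptake_bound, EX_S0 = uptake_bound),
    sources = c(C = "EX_C0", N = "EX_N0", P = "EX_P0", S = "EX_S0"))

  nutrients <- c(if (n_one_step > 0) paste0("P", seq_len(n_one_step)),
                 if (n_two_step > 0) paste0("Q", seq_len(n_two_step)))
  candidates <- tibble::tibble(
    element = rep("C", length(nutrients)),
    nutrient = nutrients %||% character(),
    exchange = paste0("EX_", nutrients %||% character()))

  truth <- list(
    one_step = if (n_one_step > 0) tibble::tibble(
      nutrient = paste0("P", seq_len(n_one_step)),
      env = paste0("C:P", seq_len(n_one_step)),
      set = as.list(one_step)) else NULL,
    two_step = if (n_two_step > 0) tibble::tibble(
      nutrient = vapply(two_truth, `[[`, character(1), "nutrient"),
      env = vapply(two_truth, `[[`, character(1), "env"),
      sets = lapply(two_truth, `[[`, "sets"),
      accessible = vapply(two_truth, `[[`, logical(1), "accessible")) else NULL,
    stepping_stones = if (share_stepping_stone && n_two_step > 0 &&
                          n_one_step > 0) one_step[1] else character(),
    energy_cycle = cycle_rxns)

  scenario <- structure(list(host = host, pool = pool, base_env = base_env,
                             candidates = candidates, dissipation = "ATPM",
                             truth = truth, seed = seed),
                        class = "toy_scenario")
  verify_toy_truth(scenario, uptake_bound)
  scenario
}

#' @export
print.toy_scenario <- function(x, ...) {
  cat("<toy_scenario> host: ", nrow(x$host$reactions), " reactions; pool: ",
      nrow(x$pool$reactions), " reactions; ",
      NROW(x$truth$one_step), " one-step and ",
      NROW(x$truth$two_step), " two-step planted nutrient(s)\n", sep = "")
  invisible(x)
}

# Generation-time verification of the planted ground truth by direct FBA:
# the host must fail on every planted nutrient, every recorded minimal set
# must restore growth, and every strict subset must fail.
verify_toy_truth <- function(scenario, uptake_bound) {
  uni <- merge_networks(scenario$host, scenario$pool)
  rx <- uni$reactions
  cand_idx <- match(default_candidates(uni), rx$id)
  base_up <- scenario$base_env$uptakes[[1]]
  swap_env <- function(ex) {
    up <- base_up[names(base_up) != "EX_C0"]
    up[ex] <- uptake_bound
    up
  }
  check <- function(env_up, set, expect_grow) {
    g <- activate_and_grow(uni, env_up, cand_idx, match(set, rx$id))
    ok <- if (expect_grow) g > VIABILITY_TOL else g <= VIABILITY_TOL
    if (!ok) stop("planted truth failed FBA verification", call. = FALSE)
  }
  all_sets <- c(
    if (!is.null(scenario$truth$one_step))
      purrr::map2(scenario$truth$one_step$nutrient,
                  scenario$truth$one_step$set,
                  function(n, s) list(ex = paste0("EX_", n), set = s)),
    if (!is.null(scenario$truth$two_step))
      unlist(purrr::map2(scenario$truth$two_step$nutrient,
                         scenario$truth$two_step$sets,
                         function(n, ss) lapply(ss, function(s)
                           list(ex = paste0("EX_", n), set = s))),
             recursive = FALSE))
  for (it in all_sets) {
    env_up <- swap_env(it$ex)
    check(env_up, character(), FALSE)           # host alone fails
    check(env_up, it$set, TRUE)                 # planted set grows
    for (r in it$set)                           # strict subsets fail
      check(env_up, setdiff(it$set, r), FALSE)
  }
  invisible(TRUE)
}

#' Generate a random gap-filling problem with a brute-force-checkable pool
#'
#' Builds a minimal viable host (one carbon source, catabolism, biomass)
#' and a random universal pool of unit-stoichiometry conversion reactions
#' over a small metabolite set, plus one novel-nutrient environment. Pool
#' sizes stay small enough that exhaustive FBA over candidate subsets is an
#' independent oracle for the gap-filler.
#'
#' @param seed integer seed.
#' @param n_intermediates number of intermediate metabolites.
#' @param n_candidates number of pool conversion reactions (at most a few
#'   tens).
#' @param p_reversible probability a pool reaction is reversible.
#' @param p_coupled probability a pool reaction needs a second substrate.
#' @return list with `network` (merged host + pool), `env` (the novel
#'   environment's uptake vector), `candidates` (pool reaction ids).
#' @export
random_gapfill_problem <- function(seed, n_intermediates = 6,
                                   n_candidates = 15, p_reversible = 0.3,
                                   p_coupled = 0.15) {
  host <- metabolic_network(tibble::tibble(
    id = c("EX_C0", "R_CAT", "BIOMASS"),
    equation = c("C0 <->", "1 C0 -> 1 X", "1 X ->")),
    biomass_reaction = "BIOMASS")
  mets <- c("NU", paste0("M", seq_len(n_intermediates)), "X")
  rows <- with_seed(seed, {
    purrr::map(seq_len(n_candidates), function(k) {
      from <- sample(mets[-length(mets)], 1)              # not from X
      to <- sample(setdiff(mets[-1], from), 1)            # not to NU
      coupled <- stats::runif(1) < p_coupled
      second <- if (coupled) sample(setdiff(mets, c(from, to)), 1)
      eq <- if (coupled)
        paste0("1 ", from, " + 1 ", second, " -> 1 ", to)
      else paste0("1 ", from, " ", if (stats::runif(1) < p_reversible)
        "<->" else "->", " 1 ", to)
      tibble::tibble(id = sprintf("u%02d", k), equation = eq)
    })
  })
  pool_tab <- dplyr::bind_rows(
    rows, tibble::tibble(id = "EX_NU", equation = "NU <->"))
  uni <- merge_networks(host, metabolic_network(pool_tab))
  list(network = uni, env = c(EX_NU = 10),
       candidates = setdiff(default_candidates(uni), "EX_NU"))
}

# ---- simulated gene histories ----------------------------------------------

#' Simulate gene gain/loss histories with planted contingency
#'
#' Grows a random rooted bifurcating tree with unit branch lengths and
#' evolves `n_pairs` gene pairs (A, B) along it: on each edge, an absent
#' gene is gained with probability `gain_p` and a present gene lost with
#' probability `loss_p` — except that B's gain probability is multiplied
#' by `kappa` on edges whose ancestor carries A. `kappa = 1` makes A and B
#' independent; `kappa > 1` plants the contingency that B tends to be
#' gained after A (the signature of stepping-stone acquisition), so the
#' expected contingent-gain fraction exceeds 0.5.
#'
#' B always starts absent at the root — B's gains are the events under
#' study. A's root state is drawn present with probability `root_p`
#' (default 0.55, close to an ignorance prior over the partner gene's
#' ancestral presence); `root_p = 0` forces an all-absent root. The
#' defaults (`gain_p = 0.03`, `loss_p = 0.05`, `root_p = 0.55`) describe
#' slow gene gain with somewhat faster loss — presence/absence mosaics on
#' the tree in which both A-present and A-absent branches are well
#' represented, so the contingent-gain tally has events on both sides of
#' its contrast.
#'
#' @param n_tips number of extant species.
#' @param n_pairs number of simulated gene pairs.
#' @param gain_p,loss_p per-edge gain and loss probabilities in `[0, 1]`.
#' @param kappa contingency multiplier (`kappa * gain_p` must be `<= 1`).
#' @param seed integer seed.
#' @param root_p probability that A is present at the root.
#' @return object of class `simulated_history`: `tree` (`ape::phylo`, unit
#'   edge lengths), `tip_states` (genes x tips 0/1 matrix), `true_states`
#'   (genes x all nodes), `pairs` (tibble `pair`, `gene_a`, `gene_b`),
#'   `params`.
#' @export
simulate_history <- function(n_tips, n_pairs, gain_p = 0.03, loss_p = 0.05,
                             kappa = 1, seed = 1, root_p = 0.55) {
  stopifnot(n_tips >= 2, n_pairs >= 1,
            gain_p >= 0, gain_p <= 1, loss_p >= 0, loss_p <= 1, kappa >= 0,
            root_p >= 0, root_p <= 1)
  if (kappa * gain_p > 1)
    stop("kappa * gain_p must not exceed 1", call. = FALSE)
  genes_a <- paste0("A", seq_len(n_pairs))
  genes_b <- paste0("B", seq_len(n_pairs))
  with_seed(seed, {
    tree <- ape::rtree(n_tips, br = 1)
    ntip <- n_tips
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    states <- matrix(0L, 2 * n_pairs, nnode,
                     dimnames = list(c(genes_a, genes_b),
                                     as.character(seq_len(nnode))))
    ia <- seq_len(n_pairs); ib <- n_pairs + seq_len(n_pairs)
    states[ia, root] <- stats::rbinom(n_pairs, 1, root_p)
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in rev(seq_len(nrow(pre)))) {   # root-to-tip order
      p <- pre[k, 1]; ch <- pre[k, 2]
      pa <- states[ia, p]; pb <- states[ib, p]
      gain_b <- ifelse(pa == 1, pmin(1, kappa * gain_p), gain_p)
      ua <- stats::runif(n_pairs); ub <- stats::runif(n_pairs)
      states[ia, ch] <- ifelse(pa == 1, ifelse(ua < loss_p, 0L, 1L),
                               ifelse(ua < gain_p, 1L, 0L))
      states[ib, ch] <- ifelse(pb == 1, ifelse(ub < loss_p, 0L, 1L),
                               ifelse(ub < gain_b, 1L, 0L))
    }
    tips <- states[, seq_len(ntip), drop = FALSE]
    colnames(tips) <- tree$tip.label
    structure(list(tree = tree, tip_states = tips, true_states = states,
                   pairs = tibble::tibble(pair = seq_len(n_pairs),
                                          gene_a = genes_a, gene_b = genes_b),
                   params = list(n_tips = n_tips, n_pairs = n_pairs,
                                 gain_p = gain_p, loss_p = loss_p,
                                 kappa = kappa, seed = seed,
                                 root_p = root_p)),
              class = "simulated_history")
  })
}

#' @export
print.simulated_history <- function(x, ...) {
  cat("<simulated_history> ", x$params$n_pairs, " gene pair(s) on ",
      x$params$n_tips, " tips; gain ", x$params$gain_p, ", loss ",
      x$params$loss_p, ", kappa ", x$params$kappa, "\n", sep = "")
  invisible(x)
}

#' Read / write presence-absence matrices
#'
#' TSV with rows = genes (or reactions) and columns = species; first column
#' holds the row id.
#'
#' @param mat 0/1 matrix with dimnames.
#' @param path file path.
#' @return the matrix ([read_presence_tsv()]) or `path` invisibly.
#' @export
write_presence_tsv <- function(mat, path) {
  out <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}
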