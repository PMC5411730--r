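planted_context <- function() {
  pu <- planted_universal()
  novel <- dplyr::bind_rows(pu$envP, pu$envQ)
  enums <- list(enumerate_minimal_sets(gapfill_problem(pu$universal, pu$envP)),
                enumerate_minimal_sets(gapfill_problem(pu$universal, pu$envQ)))
  c(pu, list(novel = novel, enums = enums))
}

test_that("single-reaction screening finds exactly the solo-beneficial reactions", {
  ctx <- planted_context()
  singles <- screen_singles(ctx$universal, ctx$novel)
  expect_equal(singles, tibble::tibble(reaction = "rP", env = "C:P"),
               ignore_attr = TRUE)
  # host-origin candidate is a contract violation
  expect_error(screen_singles(ctx$universal, ctx$novel, candidates = "R_CX"),
               "host-origin")
})

test_that("pair screening classifies planted pairs and counts all pairs when exhaustive", {
  ctx <- planted_context()
  pairs <- screen_pairs(ctx$universal, ctx$novel, enumerations = ctx$enums)
  td <- tidy(pairs)
  # the minimal pair {rQ1, rQ2} has no solo-beneficial member
  row_noind <- td[td$reaction_a == "rQ1" & td$reaction_b == "rQ2", ]
  expect_equal(row_noind$category, "beneficial_without_individual_effect")
  expect_equal(row_noind$stepping_stone_ids, "")
  # any pair containing rP is with-individual, stepping stone rP
  row_ind <- td[td$reaction_a == "rP", ][1, ]
  expect_equal(row_ind$category, "beneficial_with_combined_and_individual_effect")
  expect_equal(row_ind$stepping_stone_ids, "rP")
  # restricted screening finds every size-2 minimal pair
  min_pairs <- lapply(Filter(function(e) e$minimal_size == 2, ctx$enums),
                      function(e) lapply(e$sets, `[[`, "active_set"))
  for (s in unlist(min_pairs, recursive = FALSE)) {
    hit <- (pairs$reaction_a == s[1] & pairs$reaction_b == s[2]) |
      (pairs$reaction_a == s[2] & pairs$reaction_b == s[1])
    expect_true(any(hit))
  }
  # exhaustive mode tests n(n-1)/2 pairs
  n_cand <- length(stepstone:::default_candidates(ctx$universal))
  pairs_ex <- screen_pairs(ctx$universal, ctx$novel, exhaustive = TRUE)
  expect_lte(nrow(pairs_ex), n_cand * (n_cand - 1) / 2)
  # restricted mode finds a subset of the exhaustive scan's beneficial pairs
  expect_true(all(paste(pairs$reaction_a, pairs$reaction_b) %in%
                    paste(pairs_ex$reaction_a, pairs_ex$reaction_b)))
})

test_that("beneficial pairs are verified by direct LP re-checks", {
  ctx <- planted_context()
  pairs <- screen_pairs(ctx$universal, ctx$novel, enumerations = ctx$enums)
  rx <- ctx$universal$reactions
  cand_idx <- match(stepstone:::default_candidates(ctx$universal), rx$id)
  for (i in seq_len(nrow(pairs))) {
    both <- c(pairs$reaction_a[i], pairs$reaction_b[i])
    for (e in pairs$beneficial_envs[[i]]) {
      env <- ctx$novel[ctx$novel$name == e, ]
      expect_gt(stepstone:::activate_and_grow(ctx$universal, env, cand_idx,
                                              match(both, rx$id)), 1e-6)
    }
    if (pairs$category[i] == "beneficial_without_individual_effect") {
      for (m in both) for (j in seq_len(nrow(ctx$novel))) {
        expect_lte(stepstone:::activate_and_grow(ctx$universal, ctx$novel[j, ],
                                                 cand_idx, match(m, rx$id)), 1e-6)
      }
    }
  }
})

test_that("accessibility follows the stepping-stone structure", {
  ctx <- planted_context()
  pairs <- screen_pairs(ctx$universal, ctx$novel, enumerations = ctx$enums)
  acc <- accessibility(pairs, ctx$enums)
  # Q's sets are {rQ1,rQ2}/{rQ3,rQ4}; none contains the solo-beneficial rP
  expect_equal(acc$two_step_envs, "C:Q")
  expect_length(acc$accessible_envs, 0)
  expect_equal(acc$fraction_accessible, 0)
  # the shared-stepping-stone scenario is accessible
  sc <- make_toy_scenario(1, 1, 2, share_stepping_stone = TRUE, seed = 9)
  cur <- curate_universal(sc$host, sc$pool, sc$dissipation)
  envs <- generate_environments(sc$base_env, sc$candidates, network = cur$network)
  scr <- screen_novel(sc$host, cur$network, envs)
  novel <- scr[scr$novel, ]
  enums <- lapply(seq_len(nrow(novel)), function(i)
    enumerate_minimal_sets(gapfill_problem(cur$network, novel[i, ])))
  prs <- screen_pairs(cur$network, novel, enumerations = enums)
  acc2 <- accessibility(prs, enums)
  expect_equal(acc2$accessible_envs, "C:Q1")
  expect_equal(acc2$fraction_accessible, 1)
  # the planted shared reaction is reported as a stepping stone
  expect_true(sc$truth$stepping_stones %in% unlist(prs$stepping_stones))
})

test_that("exaptation overlap matches hand-computed fractions", {
  ctx <- planted_context()
  # P: {{rP}}; Q: {{rQ1,rQ2},{rQ3,rQ4}} -> P fraction 0 (rP nowhere), Q 0
  ov <- exaptation_overlap(ctx$enums)
  expect_equal(ov$per_env$fraction, c(0, 0))
  # shared-motif scenario: P1 {{r1}} subset of Q1's {r2,r1} -> 1; Q1 -> 0
  sc <- make_toy_scenario(1, 1, 2, share_stepping_stone = TRUE, seed = 9)
  cur <- curate_universal(sc$host, sc$pool, sc$dissipation)
  envs <- generate_environments(sc$base_env, sc$candidates, network = cur$network)
  scr <- screen_novel(sc$host, cur$network, envs)
  novel <- scr[scr$novel, ]
  enums <- lapply(seq_len(nrow(novel)), function(i)
    enumerate_minimal_sets(gapfill_problem(cur$network, novel[i, ])))
  ov2 <- exaptation_overlap(enums)
  expect_equal(sort(ov2$per_env$fraction), c(0, 1))
  expect_equal(ov2$mean, 0.5)
  # duplicated environments cover each other fully
  ov3 <- exaptation_overlap(ctx$enums[c(1, 1, 2, 2)])
  expect_equal(ov3$per_env$fraction, c(1, 1, 1, 1))
  # a single environment is undefined
  expect_error(exaptation_overlap(ctx$enums[1]), "at least two")
})

test_that("environments with singleton minimal sets appear in the single screen", {
  ctx <- planted_context()
  singles <- screen_singles(ctx$universal, ctx$novel)
  for (en in Filter(function(e) e$minimal_size == 1, ctx$enums)) {
    for (s in en$sets) {
      expect_true(any(singles$reaction == s$active_set & singles$env == en$env))
    }
  }
})
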