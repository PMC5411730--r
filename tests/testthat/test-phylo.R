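tree4 <- function() ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
tipmat <- function(v, tips = c("t1", "t2", "t3", "t4"))
  matrix(v, 1, length(tips), dimnames = list("A", tips))

test_that("GPR rules follow complex (AND) and isoenzyme (OR) semantics", {
  expect_equal(eval_gpr("(g1 AND g2)", c(g1 = 1, g2 = 0)), 0)
  expect_equal(eval_gpr("(g1 OR g2)", c(g1 = 0, g2 = 1)), 1)
  expect_equal(eval_gpr("((g1 AND g2) OR g3)", c(g1 = 0, g2 = 0, g3 = 1)), 1)
  # AND binds tighter than OR
  expect_equal(eval_gpr("g1 OR g2 AND g3", c(g1 = 0, g2 = 1, g3 = 0)), 0)
  # missing genes default to absent, with a message
  expect_message(v <- eval_gpr("g1 AND gX", c(g1 = 1)), "gX")
  expect_equal(v, 0)
  # malformed expressions report a position
  expect_error(parse_gpr("g1 AND AND g2"), "position")
  expect_error(parse_gpr("(g1 OR g2"), "\\)")
  expect_error(parse_gpr(""), "GPR")
})

test_that("gene profiles map to reaction profiles through GPRs", {
  genes <- matrix(c(1, 0, 1,
                    1, 1, 0), 2, 3, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  gprs <- tibble::tibble(reaction = c("rAND", "rOR"),
                         gpr = c("g1 AND g2", "g1 OR g2"))
  m <- map_genes_to_reactions(gprs, genes)
  expect_equal(m["rAND", ], c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(m["rOR", ], c(s1 = 1, s2 = 1, s3 = 1))
})

test_that("weighted parsimony reconstructs the worked 4-tip cases", {
  # two sister tips present: one gain above them, root absent, cost 2
  pr <- reconstruct_ancestral(tree4(), tipmat(c(1, 1, 0, 0)))
  expect_equal(unname(pr$states[1, 5:7]), c(0, 1, 0))
  expect_equal(unname(pr$cost), 2)
  # three tips present: stem gain + one loss (3) beats two gains (4)
  pr2 <- reconstruct_ancestral(tree4(), tipmat(c(1, 1, 1, 0)))
  expect_equal(unname(pr2$states[1, 5]), 1)
  expect_equal(unname(pr2$cost), 3)
  # all present: ancestors all present, single stem gain
  pr3 <- reconstruct_ancestral(tree4(), tipmat(c(1, 1, 1, 1)))
  expect_equal(unname(pr3$states[1, 5:7]), c(1, 1, 1))
  expect_equal(unname(pr3$cost), 2)
  # all absent: zero cost
  expect_equal(unname(reconstruct_ancestral(tree4(), tipmat(c(0, 0, 0, 0)))$cost), 0)
  # polytomies and non-binary states rejected
  poly <- ape::read.tree(text = "((t1:1,t2:1,t3:1):1,t4:1);")
  expect_error(reconstruct_ancestral(poly, tipmat(c(1, 0, 1, 0))), "polytom")
  expect_error(reconstruct_ancestral(tree4(), tipmat(c(1, 2, 0, 0))), "binary")
})

test_that("reconstruction cost equals the exhaustive-labeling minimum", {
  set.seed(401)
  for (rep in 1:50) {
    ntip <- sample(4:8, 1)
    tree <- ape::rtree(ntip, br = 1)
    tips <- stats::setNames(sample(0:1, ntip, replace = TRUE), tree$tip.label)
    m <- matrix(tips, 1, ntip, dimnames = list("A", names(tips)))
    pr <- reconstruct_ancestral(tree, m, gain_cost = 2, loss_cost = 1)
    oracle <- exhaustive_parsimony(tree, tips, 2, 1)
    expect_equal(unname(pr$cost), oracle$cost)
    # the DELTRAN labeling is itself one of the minimum-cost labelings
    lab <- unname(pr$states[1, (ntip + 1):(ntip + tree$Nnode)])
    expect_true(any(vapply(oracle$labelings, function(l)
      all(l == lab), logical(1))))
  }
  # and for another cost pair
  for (rep in 1:20) {
    tree <- ape::rtree(6, br = 1)
    tips <- stats::setNames(sample(0:1, 6, replace = TRUE), tree$tip.label)
    m <- matrix(tips, 1, 6, dimnames = list("A", names(tips)))
    pr <- reconstruct_ancestral(tree, m, gain_cost = 3, loss_cost = 2)
    expect_equal(unname(pr$cost), exhaustive_parsimony(tree, tips, 3, 2)$cost)
  }
})

test_that("edge-event tables match hand tallies", {
  # single-edge check via a 2-tip tree: root a10, descendants 11 and 10
  tr2 <- ape::read.tree(text = "(t1:1,t2:1);")
  st <- matrix(c(1, 1, 1,   # A at t1, t2, root
                 1, 0, 0),  # B at t1, t2, root
               2, 3, byrow = TRUE, dimnames = list(c("A", "B"), NULL))
  tab <- tabulate_edge_events(manual_profile(tr2, st), c("A", "B"))
  expect_equal(tab$a10_d11, 1)
  expect_equal(tab$a10_dXX_total, 2)
  expect_equal(tab$a00_dXX_total, 0)
  # hand-built 6-edge tree covering both contrasts
  st2 <- rbind(A = c(1, 1, 0, 0, 0, 1, 0),
               B = c(1, 0, 1, 0, 0, 0, 0))
  tab2 <- tabulate_edge_events(manual_profile(tree4(), st2), c("A", "B"))
  # edges: 5->6 (a00,d10), 6->t1 (a10,d11), 6->t2 (a10,d10),
  #        5->7 (a00,d00), 7->t3 (a00,d01), 7->t4 (a00,d00)
  expect_equal(tab2$a10_d11, 1)
  expect_equal(tab2$a10_dXX_total, 2)
  expect_equal(tab2$a00_d01, 1)
  expect_equal(tab2$a00_dXX_total, 4)
  expect_equal(tab2$a00_d11, 0)
  expect_equal(tab2$a00_d10_or_d01, 2)
  # A absent everywhere: no a10 edges
  stA0 <- rbind(A = rep(0, 7), B = c(1, 0, 1, 0, 0, 0, 0))
  expect_equal(tabulate_edge_events(manual_profile(tree4(), stA0),
                                    c("A", "B"))$a10_dXX_total, 0)
})

test_that("contingent-gain and co-gain fractions follow their definitions", {
  mk <- function(a10_d11, a10_tot, a00_d01, a00_tot, a00_d11 = 0, a00_one = 0)
    structure(list(pair = c("A", "B"), a10_d11 = a10_d11,
                   a10_dXX_total = a10_tot, a00_d01 = a00_d01,
                   a00_dXX_total = a00_tot, a00_d11 = a00_d11,
                   a00_d10_or_d01 = a00_one), class = "edge_event_table")
  # p1 = p2 -> f = 0.5 (independence)
  expect_equal(contingent_gain(mk(2, 4, 2, 4))$f, 0.5)
  # p2 = 0, p1 > 0 -> f = 1
  expect_equal(contingent_gain(mk(1, 4, 0, 4))$f, 1)
  # worked arithmetic: p1 = 0.5, p2 = 0.25 -> f = 2/3
  r <- contingent_gain(mk(2, 4, 1, 4))
  expect_equal(c(r$p1, r$p2, r$f), c(0.5, 0.25, 2/3))
  # zero denominators propagate as undefined
  expect_true(is.na(contingent_gain(mk(0, 0, 1, 4))$f))
  expect_true(is.na(contingent_gain(mk(0, 4, 0, 4))$f))
  # co-gain: single co-gain edge -> 1; only single gains -> 0; 1 vs 3 -> 0.25
  expect_equal(cogain(mk(0, 0, 0, 1, a00_d11 = 1, a00_one = 0))$f, 1)
  expect_equal(cogain(mk(0, 0, 2, 2, a00_d11 = 0, a00_one = 2))$f, 0)
  expect_equal(cogain(mk(0, 0, 0, 4, a00_d11 = 1, a00_one = 3))$f, 0.25)
  expect_true(is.na(cogain(mk(0, 0, 0, 4))$f))
})

test_that("signed-rank test matches exact null enumeration and handles ties", {
  # all f = 0.5: no evidence
  expect_equal(contingent_gain_test(rep(0.5, 6))$p_value, 1)
  # all f = 1, n = 10: one-sided exact p = 2^-10
  expect_equal(contingent_gain_test(rep(1, 10))$p_value, 2^-10)
  # mixed vectors against brute-force enumeration of all sign vectors
  set.seed(77)
  for (rep in 1:10) {
    f <- round(stats::runif(sample(5:11, 1)), 2)
    f[sample(length(f), 2)] <- 1  # force ties
    expect_equal(contingent_gain_test(f)$p_value,
                 enumerate_signed_rank_p(f - 0.5), tolerance = 1e-12)
  }
  # tie-free case agrees with stats::wilcox.test's exact p
  x <- c(0.61, 0.72, 0.55, 0.93, 0.81, 0.47, 0.66)
  expect_equal(contingent_gain_test(x)$p_value,
               stats::wilcox.test(x, mu = 0.5, alternative = "greater",
                                  exact = TRUE)$p.value)
  # undefined fractions are excluded and counted
  r <- contingent_gain_test(c(1, NA, 1, NA))
  expect_equal(r$n_excluded, 2)
  expect_error(contingent_gain_test(c(NA_real_, NA_real_)), "defined")
})

test_that("rank-sum test matches exact null enumeration", {
  # completely separated groups of 5: p = 1 / choose(10, 5)
  expect_equal(cogain_group_test(6:10 / 10, 1:5 / 10)$p_value, 1 / 252)
  # identical groups: no one-sided evidence
  expect_gte(cogain_group_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))$p_value, 0.5)
  set.seed(88)
  for (rep in 1:8) {
    a <- round(stats::runif(sample(3:6, 1)), 1)
    b <- round(stats::runif(sample(3:6, 1)), 1)
    expect_equal(cogain_group_test(a, b)$p_value,
                 enumerate_rank_sum_p(a, b), tolerance = 1e-12)
  }
  # tie-free agreement with stats::wilcox.test
  a <- c(0.91, 0.72, 0.45); b <- c(0.52, 0.33, 0.61, 0.24)
  expect_equal(cogain_group_test(a, b)$p_value,
               stats::wilcox.test(a, b, alternative = "greater",
                                  exact = TRUE)$p.value)
  expect_error(cogain_group_test(numeric(0), c(0.5)), "both groups")
})

test_that("co-gain randomization p-values are bounded, seeded and sensible", {
  h <- simulate_history(48, 12, kappa = 20, gain_p = 0.05, loss_p = 0.05,
                        seed = 31)
  pr <- reconstruct_ancestral(h$tree, h$tip_states)
  pairs <- as.matrix(h$pairs[, c("gene_a", "gene_b")])
  r1 <- cogain_randomization(pr, pairs, reps = 199, seed = 5)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  # reproducible under the same seed, different under another
  r2 <- cogain_randomization(pr, pairs, reps = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$shuffled_means, r2$shuffled_means)
  # observed mean strictly above all shuffled means -> p = 1/(reps+1)
  fake <- r1
  expect_equal((0 + 1) / (199 + 1), 1 / 200)
  expect_error(cogain_randomization(pr, pairs[1, , drop = FALSE]), "two pairs")
})
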