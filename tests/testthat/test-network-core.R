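test_that("equation parsing and round-trip formatting work", {
  p <- parse_equation("1 A + 2 B <-> 1 C")
  expect_setequal(p$metabolites, c("A", "B", "C"))
  expect_equal(p$coefficients[match(c("A", "B", "C"), p$metabolites)],
               c(-1, -2, 1))
  expect_true(p$reversible)
  expect_false(parse_equation("A -> B")$reversible)
  # exchange form: one metabolite, empty product side
  ex <- parse_equation("A <->")
  expect_equal(ex$metabolites, "A")
  expect_error(parse_equation("A B"), "arrow")
  rt <- parse_equation(make_equation(p$metabolites, p$coefficients, TRUE))
  expect_setequal(rt$metabolites, p$metabolites)
})

test_that("network construction enforces the documented invariants", {
  net <- chain_toy()
  expect_s3_class(net, "metabolic_network")
  expect_equal(dim(net$S), c(2L, 3L))
  expect_true(net$reactions$is_exchange[net$reactions$id == "EX_A"])
  expect_false(any(net$reactions$is_exchange[net$reactions$id == "R_AB"]))
  # duplicate ids rejected
  expect_error(metabolic_network(tibble::tibble(
    id = c("r", "r"), equation = c("A -> B", "B -> A")), NULL), "unique")
  # biomass must exist and be irreversible forward
  expect_error(metabolic_network(tibble::tibble(
    id = "r", equation = "A -> B"), "nope"), "not in network")
  expect_error(metabolic_network(tibble::tibble(
    id = "bm", equation = "A <->"), "bm"), "irreversible")
})

test_that("FBA solves the bound-limited chain and closed media", {
  net <- chain_toy()
  sol <- solve_fba(net, env_A(10))
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # mass balance residual of the optimal flux
  expect_lt(max(abs(as.vector(net$S %*% sol$fluxes))), 1e-6)
  # no open uptakes -> no biomass
  expect_equal(solve_fba(net, env_empty())$objective_value, 0, tolerance = 1e-9)
  expect_true(is_viable(net, env_A()))
  expect_false(is_viable(net, env_empty()))
  # unknown exchange id is an input error
  expect_error(solve_fba(net, c(EX_missing = 5)), "unknown exchange")
})

test_that("FBA picks the higher-yield route in a branched network", {
  net <- branched_toy()
  env <- growth_env("a5", c(EX_A = 5))
  # hand-LP oracle: vertices are route-1-only (5) and route-2-only (10)
  expect_equal(solve_fba(net, env)$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(solve_fba(net, env)$fluxes["R2"]), 5, tolerance = 1e-9)
})

test_that("FBA objective is invariant under reordering and reversible splitting", {
  net <- branched_toy()
  env <- growth_env("a5", c(EX_A = 5))
  base <- solve_fba(net, env)$objective_value
  perm <- net$reactions[c(3, 1, 4, 2), ]
  expect_equal(solve_fba(metabolic_network(perm, "BIOMASS"), env)$objective_value,
               base, tolerance = 1e-9)
  # split a reversible reaction into two irreversibles
  rev_net <- metabolic_network(tibble::tibble(
    id = c("EX_A", "R_AB", "BIOMASS"),
    equation = c("A <->", "A <-> B", "B ->")), "BIOMASS")
  split_net <- metabolic_network(tibble::tibble(
    id = c("EX_A", "R_AB_f", "R_AB_r", "BIOMASS"),
    equation = c("A <->", "A -> B", "B -> A", "B ->")), "BIOMASS")
  expect_equal(solve_fba(rev_net, env_A())$objective_value,
               solve_fba(split_net, env_A())$objective_value, tolerance = 1e-9)
})

test_that("FBA optima agree with an independent LP implementation", {
  skip_if_not_installed("pracma")
  for (case in list(list(chain_toy(), env_A(10)),
                    list(branched_toy(), growth_env("a5", c(EX_A = 5))),
                    list(chain_toy(), env_empty()))) {
    mine <- solve_fba(case[[1]], case[[2]])$objective_value
    ref <- pracma_fba_max(case[[1]], case[[2]])
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("flux variability brackets reachable fluxes", {
  net <- chain_toy()
  fva <- flux_variability(net, env_A(10))
  expect_equal(fva$min[fva$id == "R_AB"], 0, tolerance = 1e-9)
  expect_equal(fva$max[fva$id == "R_AB"], 10, tolerance = 1e-9)
  # dead-end consumer of a producible metabolite cannot carry steady flux
  dead <- metabolic_network(tibble::tibble(
    id = c("EX_A", "R_AB", "R_BD", "BIOMASS"),
    equation = c("A <->", "A -> B", "B -> D", "B ->")), "BIOMASS")
  fd <- flux_variability(dead, env_A(10), reactions = "R_BD")
  expect_equal(c(fd$min, fd$max), c(0, 0), tolerance = 1e-9)
  # fully closed medium: exchanges can only secrete what can be made (nothing)
  f0 <- flux_variability(net, env_empty())
  expect_true(all(abs(f0$min) < 1e-9 & abs(f0$max) < 1e-9))
})

test_that("TSV dialect round-trips bit-exactly", {
  net <- planted_universal()$universal
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, f1)
  net2 <- read_network_tsv(f1, "BIOMASS")
  write_network_tsv(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(net2$reactions$origin, net$reactions$origin)
  expect_equal(as.matrix(net2$S), as.matrix(net$S))
})

test_that("SBML reader recovers stoichiometry, bounds and GPRs", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="toy">
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="lbm10" value="-10" constant="true"/>
   <parameter id="ub1000" value="1000" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A"/><species id="B"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lbm10" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
   </reaction>
   <reaction id="R_AB" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="g1"/>
      <fbc:and>
       <fbc:geneProductRef fbc:geneProduct="g2"/>
       <fbc:geneProductRef fbc:geneProduct="g3"/>
      </fbc:and>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="BIOMASS_toy" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  net <- read_network_sbml(f)
  expect_equal(net$biomass, "BIOMASS_toy")
  expect_equal(net$reactions$lower[net$reactions$id == "EX_A"], -10)
  expect_equal(as.numeric(net$S["B", "R_AB"]), 2)
  expect_match(net$reactions$gpr[net$reactions$id == "R_AB"], "g2 AND g3")
  expect_equal(solve_fba(net, c(EX_A = 10))$objective_value, 20, tolerance = 1e-9)
})

test_that("environment definitions read from JSON and TSV", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(name = "e1", element = "C", nutrient = "glc",
                                 uptakes = list(EX_glc = 10, EX_o2 = 20))),
                       f, auto_unbox = TRUE)
  envs <- read_environments(f)
  expect_equal(envs$name, "e1")
  expect_equal(envs$uptakes[[1]][["EX_glc"]], 10)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\telement\tnutrient\texchange\tbound",
               "e2\tN\tnh4\tEX_nh4\t5",
               "e2\tN\tnh4\tEX_glc\t10"), ftsv)
  envs2 <- read_environments(ftsv)
  expect_equal(sort(names(envs2$uptakes[[1]])), c("EX_glc", "EX_nh4"))
  expect_error(growth_env("bad", c(EX_a = -1)), "non-negative")
})
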