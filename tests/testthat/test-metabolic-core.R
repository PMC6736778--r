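chain_model <- function(conv_ub = 1000) {
  metabolic_model("chain", list(
    EX_a = list(stoich = c(a_e = -1), lb = -10, ub = 1000,
                kind = "exchange"),
    CONV = list(stoich = c(a_e = -1, agm_e = 1), lb = 0, ub = conv_ub),
    EX_agm = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow")))
}

test_that("model construction enforces the structural invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(n_reactions(m), 3)
  expect_equal(n_metabolites(m), 2)

  expect_error(metabolic_model("bad", list(
    R1 = list(stoich = c(x_c = -1, y_c = 1), lb = 5, ub = 1))),
    "lower bound")
  expect_error(metabolic_model("bad", list(
    EX_x = list(stoich = c(x_e = -1, y_e = 1), kind = "exchange"))),
    "exactly one metabolite")
  expect_error(metabolic_model("bad", list(
    R1 = list(stoich = c(x_c = 1), kind = "nonsense"))), "unknown reaction")
  expect_error(metabolic_model("bad", list(
    B = list(stoich = c(x_c = 1), kind = "internal")),
    biomass_reaction_id = "B"), "not of kind")
  expect_error(metabolic_model("bad", list(
    B = list(stoich = c(x_c = 1))), biomass_reaction_id = "missing"),
    "does not resolve")
})

test_that("JSON and SBML dialects round-trip a model", {
  m <- chain_model(conv_ub = 7.5)
  for (ext in c("json", "xml")) {
    path <- file.path(tempdir(), paste0("chain.", ext))
    write_model(m, path)
    m2 <- load_model(path)
    expect_equal(m2$id, m$id)
    o <- order(m2$rxns$id)
    expect_equal(m2$rxns[o, c("id", "lb", "ub", "kind")],
                 m$rxns[order(m$rxns$id), c("id", "lb", "ub", "kind")],
                 ignore_attr = TRUE)
    expect_equal(sort(m2$mets$id), sort(m$mets$id))
    expect_equal(as.matrix(m2$S)[m$mets$id, m$rxns$id],
                 as.matrix(m$S)[m$mets$id, m$rxns$id])
    # write the re-read model again: byte-comparable content
    path2 <- file.path(tempdir(), paste0("chain2.", ext))
    write_model(m2, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("malformed model files produce informative errors", {
  p <- file.path(tempdir(), "broken.json")
  writeLines("{not json", p)
  expect_error(load_model(p), "parse failure")
  jsonlite::write_json(list(id = "x", reactions = list(
    list(id = "R1", metabolites = list()))), p, auto_unbox = TRUE)
  expect_error(load_model(p), "empty stoichiometry")
  expect_error(load_model(file.path(tempdir(), "nope.json")), "not found")
  # SBML referencing an undeclared species
  m <- chain_model()
  px <- file.path(tempdir(), "bad.xml")
  write_model(m, px, dialect = "sbml")
  txt <- gsub('species id="a_e"', 'species id="zzz_e"', readLines(px))
  writeLines(txt, px)
  expect_error(load_model(px), "undeclared species")
})

test_that("apply_diet sets uptake bounds and reports skipped compounds", {
  m <- chain_model()
  d1 <- apply_diet(m, c(a = 10))
  expect_equal(d1$rxns$lb[d1$rxns$id == "EX_a"], -10)
  expect_equal(d1$rxns$ub[d1$rxns$id == "EX_a"], 1000)

  # empty diet: all exchange uptake closed, production starves to zero
  d0 <- apply_diet(m, setNames(numeric(0), character(0)))
  expect_equal(d0$rxns$lb[d0$rxns$id == "EX_a"], 0)
  expect_equal(fba(d0, "EX_agm")$primary_objective, 0)

  # unknown compound: not fatal, recorded, model otherwise unchanged
  d2 <- apply_diet(m, c(a = 5, unobtainium = 3))
  expect_equal(attr(d2, "diet_skipped"), "unobtainium")
  expect_equal(d2$rxns$lb[d2$rxns$id == "EX_a"], -5)
  expect_error(apply_diet(m, c(a = -1)), ">= 0")
})

test_that("fba finds the binding bottleneck of a linear chain", {
  expect_equal(fba(chain_model(), "EX_agm")$primary_objective, 10,
               tolerance = 1e-9)
  expect_equal(fba(chain_model(conv_ub = 4), "EX_agm")$primary_objective, 4,
               tolerance = 1e-9)
  sol <- fba(chain_model(), "EX_agm")
  chk <- check_solution(chain_model(), sol)
  expect_lt(chk$max_residual, 1e-6)
  expect_lt(chk$max_bound_violation, 1e-9)
})

test_that("fba diagnoses unbounded and infeasible problems", {
  m <- metabolic_model("unb", list(
    A = list(stoich = c(x_c = 1), lb = 0, ub = Inf),
    B = list(stoich = c(x_c = -1), lb = 0, ub = Inf)))
  expect_warning(sol <- fba(m, "A"), "unbounded along")
  expect_equal(sol$status, "unbounded")

  m2 <- metabolic_model("inf", list(
    A = list(stoich = c(x_c = 1), lb = 2, ub = 5),
    B = list(stoich = c(x_c = -1), lb = 0, ub = 1)))
  expect_equal(fba(m2, "A")$status, "infeasible")
})

test_that("fba matches the enumeration oracle on random networks", {
  set.seed(101)
  for (i in 1:50) {
    net <- random_network(n_rxn = sample(4:8, 1), n_met = sample(2:5, 1),
                          feasible = FALSE)  # exercise infeasible cases too
    obj <- sample(net$rxns$id, 1)
    mine <- fba(net, obj)
    orc <- oracle_fba(net, obj)
    if (is.null(orc)) {
      expect_equal(mine$status, "infeasible")
    } else {
      expect_equal(mine$status, "optimal")
      expect_equal(mine$primary_objective, orc, tolerance = 1e-6)
      chk <- check_solution(net, mine)
      expect_lt(chk$max_residual, 1e-6)
      expect_lt(chk$max_bound_violation, 1e-9)
    }
  }
})

test_that("uptake relaxation never decreases a maximisation optimum", {
  set.seed(202)
  tested <- 0
  while (tested < 50) {
    net <- random_network(n_rxn = 6, n_met = 3)
    obj <- sample(net$rxns$id, 1)
    base <- fba(net, obj)
    if (base$status != "optimal") next
    j <- sample(n_reactions(net), 1)
    relaxed <- net
    relaxed$rxns$lb[j] <- relaxed$rxns$lb[j] - runif(1, 0, 5)
    after <- fba(relaxed, obj)
    expect_equal(after$status, "optimal")
    expect_gte(after$primary_objective, base$primary_objective - 1e-9)
    tested <- tested + 1
  }
})

two_route_model <- function(block = NULL) {
  rxns <- list(
    EX_a = list(stoich = c(a_e = -1), lb = -10, ub = 1000,
                kind = "exchange"),
    R1a = list(stoich = c(a_e = -1, x1_c = 1), lb = 0),
    R1b = list(stoich = c(x1_c = -1, agm_e = 1), lb = 0),
    R2a = list(stoich = c(a_e = -1, y1_c = 1), lb = 0),
    R2b = list(stoich = c(y1_c = -1, y2_c = 1), lb = 0),
    R2c = list(stoich = c(y2_c = -1, y3_c = 1), lb = 0),
    R2d = list(stoich = c(y3_c = -1, agm_e = 1), lb = 0),
    EX_agm = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow"))
  if (!is.null(block)) for (b in block) rxns[[b]]$ub <- 0
  metabolic_model("two_route", rxns)
}

test_that("the flux penalty selects the shorter of two equivalent routes", {
  sol <- fba_with_flux_penalty(two_route_model(), "EX_agm")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$primary_objective, 10, tolerance = 1e-5)
  expect_equal(unname(sol$fluxes["R2a"]), 0, tolerance = 1e-7)
  expect_equal(unname(sol$fluxes["R1a"]), 10, tolerance = 1e-5)
  # enumerate both route-blocked alternatives with the oracle: same
  # capacity, but the 4-step route carries strictly more total flux
  short <- fba_with_flux_penalty(two_route_model(block = c("R2a")), "EX_agm")
  long <- fba_with_flux_penalty(two_route_model(block = c("R1a")), "EX_agm")
  expect_equal(oracle_fba(two_route_model(block = "R2a"), "EX_agm"), 10)
  expect_equal(oracle_fba(two_route_model(block = "R1a"), "EX_agm"), 10)
  expect_lt(short$total_abs_flux, long$total_abs_flux)
  expect_equal(sol$total_abs_flux, short$total_abs_flux, tolerance = 1e-5)
})

test_that("penalised and plain objectives agree within the penalty bound", {
  m <- two_route_model()
  plain <- fba(m, "EX_agm")
  for (eps in c(1e-6, 1e-8)) {
    pen <- fba_with_flux_penalty(m, "EX_agm", epsilon = eps)
    expect_lt(abs(pen$primary_objective - plain$primary_objective),
              eps * pen$total_abs_flux + 1e-12)
    # split variables satisfy complementarity: total equals sum |v|
    expect_equal(pen$total_abs_flux, sum(abs(pen$fluxes)), tolerance = 1e-7)
  }
  # no path to the target: capacity zero
  m0 <- metabolic_model("nopath", list(
    EX_a = list(stoich = c(a_e = -1), lb = -10, kind = "exchange"),
    SINK = list(stoich = c(a_e = -1), lb = 0, kind = "outflow"),
    EX_agm = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow"),
    LOOP = list(stoich = c(agm_e = 1, z_c = -1), lb = 0, ub = 0)))
  expect_equal(fba_with_flux_penalty(m0, "EX_agm")$primary_objective, 0,
               tolerance = 1e-9)
})

test_that("penalised random networks stay steady-state and within bounds", {
  set.seed(303)
  checked <- 0
  while (checked < 25) {
    net <- random_network(n_rxn = 6, n_met = 3)
    obj <- sample(net$rxns$id, 1)
    pen <- fba_with_flux_penalty(net, obj, epsilon = 1e-6)
    if (pen$status != "optimal") next
    chk <- check_solution(net, pen)
    expect_lt(chk$max_residual, 1e-6)
    expect_lt(chk$max_bound_violation, 1e-7)
    expect_equal(pen$total_abs_flux, sum(abs(pen$fluxes)), tolerance = 1e-6)
    checked <- checked + 1
  }
})
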