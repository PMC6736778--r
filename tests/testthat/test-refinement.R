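raw_producer <- function(id = "P1", species = "Toyobacter sp01") {
  metabolic_model(id, list(
    EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
    BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0, kind = "outflow"),
    EX_arg = list(stoich = c(arg_e = -1), kind = "exchange"),
    ARGt = list(stoich = c(arg_e = -1, arg_c = 1), kind = "transport"),
    ARGDC = list(stoich = c(arg_c = -1, agm_c = 1, co2_c = 1), lb = 0),
    CO2t = list(stoich = c(co2_c = -1, co2_e = 1), kind = "transport"),
    EX_co2 = list(stoich = c(co2_e = -1), kind = "exchange")),
    taxonomy = list(genus = "Toyobacter", species = species),
    biomass_reaction_id = "BIOMASS")
}

hit_row <- function(strain, bitscore, coverage = 90, query = "agmT") {
  data.frame(query_protein = query, target_strain = strain,
             bitscore = bitscore, query_coverage = coverage,
             stringsAsFactors = FALSE)
}

test_that("the homology-table parser handles the 12+1 column dialect", {
  p <- file.path(tempdir(), "hits.tsv")
  hits_in <- rbind(hit_row("S01", 120.5, 88.2),
                   hit_row("S02", 45.0, 60.0),
                   hit_row("S01", 300.0, 95.0, query = "speA"))
  write_homology_table(hits_in, p)
  hits <- parse_homology_table(p)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$bitscore, c(120.5, 45.0, 300.0))
  expect_equal(hits$query_coverage, c(88.2, 60.0, 95.0))
  expect_equal(hits$target_strain, c("S01", "S02", "S01"))

  # a row with 11 columns is named in the error
  writeLines(c(paste(letters[1:12], collapse = "\t"),
               paste(letters[1:11], collapse = "\t")), p)
  expect_error(parse_homology_table(p), "2.*fewer than 12")

  # non-numeric bitscore is named by row
  writeLines(c("q\ts\t90\t100\t1\t0\t1\t100\t1\t100\t1e-10\t55.5",
               "q\ts\t90\t100\t1\t0\t1\t100\t1\t100\t1e-10\tbad"), p)
  expect_error(parse_homology_table(p), "row.*2")

  # duplicate (query, strain) rows are both retained
  writeLines(rep("q\ts\t90\t100\t1\t0\t1\t100\t1\t100\t1e-10\t55.5", 2), p)
  expect_equal(nrow(parse_homology_table(p)), 2)

  # 12-column files get coverage from a sidecar lengths table
  writeLines("q\ts\t90\t150\t1\t0\t1\t150\t1\t150\t1e-10\t80.1", p)
  h12 <- parse_homology_table(p, query_lengths = c(q = 200))
  expect_equal(h12$query_coverage, 75)
})

test_that("transporter assignment applies the strict/inclusive thresholds", {
  models <- list(S01 = raw_producer("S01"), S02 = raw_producer("S02"),
                 S03 = raw_producer("S03"))
  hits <- rbind(hit_row("S01", 50.0, 80),   # bitscore not strictly above 50
                hit_row("S02", 55, 75.0),   # coverage inclusive at 75
                hit_row("S03", 300, 60))    # coverage fails
  res <- assign_agmatine_transport(models, hits)
  expect_false(res$report$transporter_added[res$report$strain == "S01"])
  expect_true(res$report$transporter_added[res$report$strain == "S02"])
  expect_false(res$report$transporter_added[res$report$strain == "S03"])
  expect_true("AGMT" %in% res$models$S02$rxns$id)
  expect_false("AGMT" %in% res$models$S01$rxns$id)
  # the transporter is reversible between cytosol and periplasm/exterior
  j <- match("AGMT", res$models$S02$rxns$id)
  expect_equal(res$models$S02$rxns$lb[j], -1000)
  expect_warning(assign_agmatine_transport(models, hit_row("GHOST", 100, 90)),
                 "unknown strain")
})

test_that("extracellular decarboxylase assignment copies the template", {
  models <- list(S01 = raw_producer("S01"), S02 = raw_producer("S02"))
  res <- add_extracellular_argdc(models, rbind(hit_row("S01", 250),
                                               hit_row("S02", 200)))
  expect_true("ARGDC_EXT" %in% res$models$S01$rxns$id)
  expect_false("ARGDC_EXT" %in% res$models$S02$rxns$id)  # 200 not above 200
  j <- match("ARGDC_EXT", res$models$S01$rxns$id)
  st <- res$models$S01$S[, j]
  st <- st[st != 0]
  expect_equal(sort(names(st)), c("agm_e", "arg_e", "co2_e"))
  expect_equal(unname(st[c("arg_e", "agm_e", "co2_e")]), c(-1, 1, 1))
  # strain without the cytosolic template falls back with a warning
  no_tmpl <- metabolic_model("S09", list(
    EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
    BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0,
                      kind = "outflow")), biomass_reaction_id = "BIOMASS")
  expect_warning(res2 <- add_extracellular_argdc(list(S09 = no_tmpl),
                                                 hit_row("S09", 400)),
                 "lacks a cytosolic ARGDC")
  expect_true("ARGDC_EXT" %in% res2$models$S09$rxns$id)
})

test_that("the outflow is added for either refinement route", {
  models <- list(S01 = raw_producer("S01"), S02 = raw_producer("S02"),
                 S03 = raw_producer("S03"))
  st <- assign_agmatine_transport(models, hit_row("S01", 100, 90))
  st <- add_extracellular_argdc(st$models, hit_row("S02", 250),
                                report = st$report)
  res <- add_agmatine_outflow(st$models, st$report)
  expect_true(res$report$outflow_added[res$report$strain == "S01"])
  expect_true(res$report$outflow_added[res$report$strain == "S02"])
  expect_false(res$report$outflow_added[res$report$strain == "S03"])
  expect_true("EX_agm_out" %in% res$models$S01$rxns$id)
  expect_false("EX_agm_out" %in% res$models$S03$rxns$id)
  j <- match("EX_agm_out", res$models$S01$rxns$id)
  expect_equal(res$models$S01$rxns$lb[j], 0)
  expect_equal(res$models$S01$rxns$ub[j], 1000)
})

test_that("growth screen applies the inclusive biomass cutoff", {
  slow <- raw_producer("SLOW")
  slow <- set_bounds(slow, "BIOMASS", ub = 0.009)
  exact <- set_bounds(raw_producer("EXACT"), "BIOMASS", ub = 0.01)
  fast <- raw_producer("FAST")
  rep <- screen_growth(list(SLOW = slow, EXACT = exact, FAST = fast),
                       c(glc = 10, arg = 5))
  expect_false(rep$growth_pass[rep$strain == "SLOW"])
  expect_true(rep$growth_pass[rep$strain == "EXACT"])
  expect_true(rep$growth_pass[rep$strain == "FAST"])
})

test_that("producer screen requires an open route to the outflow", {
  models <- list(S01 = raw_producer("S01"), S02 = raw_producer("S02"))
  hits <- hit_row("S01", 100, 90)
  res <- refine_models(models, hits, hits[0, ], c(glc = 10, arg = 5))
  expect_true(res$report$producer[res$report$strain == "S01"])
  expect_false(res$report$producer[res$report$strain == "S02"])
  # remove arginine: no nitrogen route, producer flag drops
  rep2 <- screen_producers(res$models, c(glc = 10))
  expect_false(rep2$producer[rep2$strain == "S01"])
  # oracle confirms the zero optimum on the starved model
  starved <- apply_diet(res$models$S01, c(glc = 10))
  expect_equal(oracle_fba(starved, "EX_agm_out"), 0, tolerance = 1e-9)
})

test_that("refinement is idempotent, conservative and sharply thresholded", {
  models <- list(S01 = raw_producer("S01"), S02 = raw_producer("S02"),
                 S03 = raw_producer("S03"))
  tr <- rbind(hit_row("S01", 80, 90), hit_row("S02", 60, 80))
  sp <- hit_row("S03", 260)
  diet <- c(glc = 10, arg = 5)
  once <- refine_models(models, tr, sp, diet)
  twice <- refine_models(once$models, tr, sp, diet)
  expect_equal(lapply(twice$models, function(m) m$rxns),
               lapply(once$models, function(m) m$rxns))
  expect_equal(twice$report, once$report)

  # conservation: refinement never removes reactions or changes old bounds
  for (s in names(models)) {
    old <- models[[s]]$rxns
    new <- once$models[[s]]$rxns
    expect_true(all(old$id %in% new$id))
    expect_equal(new[match(old$id, new$id), c("lb", "ub")], old[, c("lb", "ub")],
                 ignore_attr = TRUE)
  }

  # report counts equal flagged strains
  sm <- summarize_refinement(once$report)
  expect_equal(sm$n_transporter, sum(once$report$transporter_added))
  expect_equal(sm$n_outflow, sum(once$report$outflow_added))
  expect_equal(sm$producer_denominator_all, 3)
  expect_equal(sm$producer_denominator_growing,
               sum(once$report$growth_pass))

  # nudging one bitscore across the cutoff flips exactly that strain
  tr2 <- tr; tr2$bitscore[2] <- 49.9
  alt <- refine_models(models, tr2, sp, diet)
  diff <- once$report$transporter_added != alt$report$transporter_added
  expect_equal(once$report$strain[diff], "S02")
  expect_equal(once$report$transporter_added[!diff],
               alt$report$transporter_added[!diff])
})
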