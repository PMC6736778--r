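test_that("mass-to-flux conversion follows the microbiota normalisation", {
  expect_equal(mass_to_flux(36, 180), 1.0)          # 200 mmol over 200 g
  expect_equal(mass_to_flux(0, 123.4), 0)
  expect_equal(mass_to_flux(36, 180, microbiota_mass = 100), 2.0)
  expect_error(mass_to_flux(10, 0), "> 0")
})

test_that("caloric normalisation rescales to the target and is idempotent", {
  d <- diet_spec(c(glc = 4, arg = 2), caloric_value_kJ = 17598)
  n1 <- normalize_caloric(d)
  expect_equal(unname(n1$amounts), c(1, 2))  # sorted: arg, glc; halved
  expect_equal(n1$caloric_value_kJ, 8799)
  at_target <- diet_spec(c(glc = 4), caloric_value_kJ = 8799)
  expect_equal(normalize_caloric(at_target)$amounts, at_target$amounts)
  expect_equal(normalize_caloric(n1)$amounts, n1$amounts)
  expect_error(normalize_caloric(diet_spec(c(glc = 1),
                                           caloric_value_kJ = 0)),
               "positive")
})

ffq_fixture <- function() {
  records <- data.frame(
    participant_id = "F01",
    food_item = c("beef", "cheese", "beer"),
    group_path = c("animal/meat", "animal/dairy", "drink/beer"),
    grams_per_day = c(100, 50, 200),
    stringsAsFactors = FALSE)
  purines <- data.frame(
    food_item = c("beef", "cheese", "ale"),
    adenosine_class = c(0.003, 0.001, 0.0005),
    guanosine_class = c(0.0015, NA, 0.0002),
    stringsAsFactors = FALSE)
  polyamines <- data.frame(
    food_item = c("beef", "cheese", "ale"),
    cadaverine = c(1e-4, 2e-4, 0),
    putrescine = c(2e-4, 1e-4, 5e-5),
    spermidine = c(3e-4, 1e-4, 0),
    spermine = c(1e-4, 5e-5, 0),
    ornithine = c(2e-3, NA, NA),
    stringsAsFactors = FALSE)
  list(records = records, purines = purines, polyamines = polyamines)
}

test_that("nucleotide augmentation satisfies the pyrimidine identities", {
  fx <- ffq_fixture()
  # 'beer' is missing: it must be imputed from the only other item of its
  # top-level 'drink' group would fail, so give it a same-group sibling
  fx$purines$food_item[3] <- "beer"
  d <- augment_nucleotides(diet_spec(), fx$records, fx$purines)
  # independent recomputation of the class totals (mmol/day / 200)
  aden <- (100 * 0.003 + 50 * 0.001 + 200 * 0.0005) / 200
  # cheese guanosine is imputed from its nearest populated group level:
  # no 'animal/dairy' sibling has data, so the 'animal' level (beef) is used
  guan_cheese_imputed <- 0.0015
  guan <- (100 * 0.0015 + 50 * guan_cheese_imputed + 200 * 0.0002) / 200
  expect_equal(unname(d$amounts["adenosine"]), aden)
  expect_equal(unname(d$amounts["guanosine"]), guan)
  expect_equal(unname(d$amounts["thymidine"] + d$amounts["uracil"]),
               aden)  # combined identity
  expect_equal(unname(d$amounts["cytosine"]), guan)
  # zero purines give zero pyrimidines
  z <- fx$purines; z$adenosine_class <- 0; z$guanosine_class <- 0
  dz <- augment_nucleotides(diet_spec(), fx$records, z)
  expect_equal(sum(dz$amounts), 0)
  # a group with no data anywhere in the hierarchy is a named error
  bad <- fx$purines[1:2, ]
  expect_error(augment_nucleotides(diet_spec(), fx$records, bad),
               "drink/beer")
})

test_that("polyamine augmentation extrapolates ornithine by the factor", {
  fx <- ffq_fixture()
  fx$polyamines$food_item[3] <- "beer"
  d <- augment_polyamines(diet_spec(), fx$records, fx$polyamines)
  # beef has measured ornithine; cheese and beer are extrapolated at 3.28
  pa_cheese <- 2e-4 + 1e-4 + 1e-4 + 5e-5
  pa_beer <- 5e-5
  orn <- (100 * 2e-3 + 50 * 3.28 * pa_cheese + 200 * 3.28 * pa_beer) / 200
  expect_equal(unname(d$amounts["ornithine"]), orn)
  expect_equal(unname(d$amounts["cadaverine"]),
               (100 * 1e-4 + 50 * 2e-4 + 200 * 0) / 200)
  # an item with zero polyamines gets zero extrapolated ornithine
  z <- fx$polyamines
  z[3, c("cadaverine", "putrescine", "spermidine", "spermine")] <- 0
  dz <- augment_polyamines(diet_spec(),
                           fx$records[3, , drop = FALSE], z)
  expect_equal(unname(dz$amounts["ornithine"]), 0)
  z$putrescine[1] <- -1
  expect_error(augment_polyamines(diet_spec(), fx$records, z), "negative")
})

test_that("reference blending weights compounds and retains minerals", {
  d <- diet_spec(c(x = 10, pi = 10))
  ref <- c(x = 2, pi = 2, y = 5)
  b <- blend_with_reference(d, ref, 0.9, retained_compounds = "pi")
  expect_equal(unname(b$amounts["x"]), 9.2)
  expect_equal(unname(b$amounts["pi"]), 2)     # retained at reference
  expect_equal(unname(b$amounts["y"]), 0.5)    # reference-only compound
  # blending a diet with itself is the identity for any fraction
  for (f in c(0, 0.3, 1)) {
    self <- blend_with_reference(d, d$amounts, f)
    expect_equal(self$amounts, d$amounts)
  }
  full <- blend_with_reference(d, ref, 1.0)
  expect_equal(full$amounts[names(d$amounts)], d$amounts)
})

test_that("absorption adjustment scales amounts by the retained fraction", {
  d <- diet_spec(c(a = 10, b = 3))
  adj <- adjust_absorption(d, c(a = 0.8))
  expect_equal(unname(adj$amounts["a"]), 2)
  expect_equal(unname(adj$amounts["b"]), 3)
  expect_equal(adjust_absorption(d, c(a = 0))$amounts, d$amounts)
  expect_equal(unname(adjust_absorption(d, c(a = 1))$amounts["a"]), 0)
  expect_error(adjust_absorption(d, c(a = 1.2)), "\\[0, 1\\]")
})

test_that("the full diet pipeline reproduces an independent composition", {
  cfg <- sim_config(seed = 11)
  ffq <- make_ffq(cfg)
  rec <- ffq$records[ffq$records$participant_id == "F01", ]
  diet <- build_participant_diet(
    rec, ffq$compound_map, ffq$purine_table, ffq$polyamine_table,
    ffq$reference_diet, retained_compounds = ffq$retained_compounds)

  # recompose the expected amounts step by step, independently of the
  # pipeline's internal helpers
  g <- setNames(rec$grams_per_day, rec$food_item)
  cm <- ffq$compound_map
  mapped <- setNames((g[cm$compound] / cm$molecular_weight) * 1000 / 200,
                     cm$exchange_id)
  caloric <- sum(g[cm$compound] * cm$kJ_per_gram)

  content <- function(tab, col) {
    v <- setNames(tab[[col]], tab$food_item)[rec$food_item]
    if (anyNA(v)) {  # group-average imputation, innermost group first
      for (i in which(is.na(v))) {
        grp <- rec$group_path[i]
        repeat {
          sib <- rec$food_item[startsWith(rec$group_path, grp) &
                                 rec$food_item != rec$food_item[i]]
          pool <- setNames(tab[[col]], tab$food_item)[sib]
          pool <- pool[!is.na(pool)]
          if (length(pool)) { v[i] <- mean(pool); break }
          if (!grepl("/", grp)) stop("no data for ", grp)
          grp <- sub("/[^/]*$", "", grp)
        }
      }
    }
    v
  }
  aden <- sum(g * content(ffq$purine_table, "adenosine_class")) / 200
  guan <- sum(g * content(ffq$purine_table, "guanosine_class")) / 200
  pa <- sapply(c("cadaverine", "putrescine", "spermidine", "spermine"),
               function(cl) content(ffq$polyamine_table, cl))
  orn_meas <- setNames(ffq$polyamine_table$ornithine,
                       ffq$polyamine_table$food_item)[rec$food_item]
  orn <- ifelse(is.na(orn_meas), 3.28 * rowSums(pa), orn_meas)
  expected <- c(mapped,
                adenosine = aden, guanosine = guan,
                thymidine = aden / 2, uracil = aden / 2, cytosine = guan,
                setNames(colSums(g * pa) / 200, colnames(pa)),
                ornithine = sum(g * orn) / 200)
  expected <- expected * 8799 / caloric          # caloric normalisation
  ref <- ffq$reference_diet$amounts
  allc <- union(names(expected), names(ref))
  full <- setNames(numeric(length(allc)), allc)
  full[names(expected)] <- 0.9 * expected
  full[names(ref)] <- full[names(ref)] + 0.1 * ref
  full[ffq$retained_compounds] <- ref[ffq$retained_compounds]

  expect_equal(diet$amounts[sort(allc)], full[sort(allc)])
  expect_true(all(diet$amounts >= 0))
  prov <- attr(diet, "provenance")
  expect_equal(prov$step[1], "map_and_convert")
  expect_equal(prov$caloric_kJ[nrow(prov)], 8799)

  # determinism: identical records give identical diets
  rec2 <- rec; rec2$participant_id <- "F99"
  diet2 <- build_participant_diet(
    rec2, ffq$compound_map, ffq$purine_table, ffq$polyamine_table,
    ffq$reference_diet, retained_compounds = ffq$retained_compounds)
  expect_equal(diet2$amounts, diet$amounts)

  # scale equivariance: doubling all grams then normalising caloric value
  # reproduces the original normalised diet
  rec3 <- rec; rec3$grams_per_day <- rec3$grams_per_day * 2
  diet3 <- build_participant_diet(
    rec3, ffq$compound_map, ffq$purine_table, ffq$polyamine_table,
    ffq$reference_diet, retained_compounds = ffq$retained_compounds)
  expect_equal(diet3$amounts, diet$amounts, tolerance = 1e-12)
})

test_that("cohort diet building reports the pre-normalisation median", {
  cfg <- sim_config(seed = 12, n_ffq_participants = 4)
  ffq <- make_ffq(cfg)
  diets <- build_cohort_diets(ffq$records, compound_map = ffq$compound_map,
                              purine_table = ffq$purine_table,
                              polyamine_table = ffq$polyamine_table,
                              reference_diet = ffq$reference_diet,
                              retained_compounds = ffq$retained_compounds,
                              target_kJ = NULL)
  log <- attr(diets, "cohort_log")
  expect_equal(log$n_participants, 4)
  expect_equal(log$target_kJ, log$median_caloric_pre_kJ)
  expect_true(all(vapply(diets, function(d)
    d$caloric_value_kJ, 0) == log$target_kJ))
})

test_that("diet TSVs round-trip through the writer and reader", {
  d <- diet_spec(c(glc = 1.25, arg = 0.5), participant_id = "F01",
                 caloric_value_kJ = 8799)
  p <- file.path(tempdir(), "diet.tsv")
  write_diet_tsv(d, p)
  d2 <- read_diet_tsv(p, participant_id = "F01")
  expect_equal(d2$amounts, d$amounts)
  expect_equal(d2$caloric_value_kJ, 8799)
})
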