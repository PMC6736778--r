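#' Simulation configuration for the synthetic-data generators
#'
#' One master seed drives every generator; each generator derives its own
#' substream seed from a fixed label, so adding a generator never shifts
#' the streams of the others. The defaults mirror the study conditions the
#' pipeline is meant to analyse: a cohort contrast of 30 participants per
#' group with a three-fold enrichment of producer taxa in the treated
#' group, and a plate screen of 337 nutrients with 4 replicates.
#'
#' @param seed master integer seed.
#' @param n_strains number of strain models in the toy resource.
#' @param producer_fraction fraction of strains carrying the
#'   arginine-to-agmatine route.
#' @param n_per_group cohort participants per group.
#' @param effect_size multiplier on producer-strain Dirichlet concentration
#'   parameters in the treated group (1 = no effect).
#' @param alpha_producer,alpha_other baseline Dirichlet concentrations.
#' @param producer_cap upper bound of the producers' decarboxylase flux.
#' @param n_nutrients,n_replicates screen design size.
#' @param sigma screen response noise (log2 units).
#' @param n_planted number of nutrients with a planted drug interaction.
#' @param planted_effect planted interaction magnitude (log2 units).
#' @param n_ffq_participants participants in the synthetic food-frequency
#'   generator.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_strains = 8, producer_fraction = 0.5,
                       n_per_group = 30, effect_size = 3,
                       alpha_producer = 0.4, alpha_other = 1.6,
                       producer_cap = 1000,
                       n_nutrients = 337, n_replicates = 4, sigma = 0.2,
                       n_planted = 30, planted_effect = 1,
                       n_ffq_participants = 5) {
  stopifnot(n_strains >= 1, producer_fraction >= 0, producer_fraction <= 1,
            n_per_group >= 1, sigma > 0, n_nutrients >= 1,
            n_replicates >= 1, n_planted >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic substream seed below 2^31 from (seed, label): the combined
# value is passed through a 32-bit avalanche mix (murmur-style finalizer) so
# that nearby master seeds yield well-separated, effectively independent
# generator states rather than a lattice of related ones
.substream_seed <- function(seed, label) {
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- a %/% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  v <- utf8ToInt(label)
  h <- (as.double(seed) * 10007 + sum(v * seq_along(v) * 97)) %% 4294967296
  h <- bitwXor(as.integer(h %% 2147483648), as.integer(h %/% 65536))
  h <- mul32(as.double(h) %% 4294967296, 2246822519)   # 0x85EBCA6B
  h <- bitwXor(as.integer(h %% 2147483648),
               as.integer((h %/% 8192) %% 2147483648))
  h <- mul32(as.double(bitwAnd(h, 2147483647L)), 3266489917)  # 0xC2B2AE35
  as.integer(h %% 2147483629)
}

#' Generate a toy strain-model resource
#'
#' Builds `n_strains` small stoichiometric models with a shared core (sugar
#' uptake feeding a biomass reaction with a dedicated outflow). A subset
#' (the producers) additionally carries arginine uptake, a cytosolic
#' arginine decarboxylase (`ARGDC`: arginine -> agmatine + CO2) and, when
#' `refined = TRUE`, the agmatine transport and outflow reactions that the
#' homology-driven refinement would add. Strains are paired into species so
#' species-level aggregation is exercised.
#'
#' @param config a `sim_config`.
#' @param refined return models in the post-refinement state (default);
#'   `FALSE` returns raw models whose agmatine route dead-ends, as input
#'   for [refine_models()].
#' @return list with `models` (named list), `producers` (strain ids),
#'   `diet` (a template `diet_spec` on which all strains grow and producers
#'   produce).
#' @export
make_toy_models <- function(config, refined = TRUE) {
  n <- config$n_strains
  n_prod <- ceiling(n * config$producer_fraction)
  ids <- sprintf("S%02d", seq_len(n))
  models <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    producer <- i <= n_prod
    rxns <- list(
      EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
      BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1),
                     lb = 0, kind = "biomass"),
      DM_biomass = list(stoich = c(biomass_c = -1), lb = 0,
                        kind = "outflow"))
    if (producer) {
      rxns <- c(rxns, list(
        EX_arg = list(stoich = c(arg_e = -1), kind = "exchange"),
        ARGt = list(stoich = c(arg_e = -1, arg_c = 1), kind = "transport"),
        ARGDC = list(stoich = c(arg_c = -1, agm_c = 1, co2_c = 1),
                     lb = 0, ub = config$producer_cap),
        CO2t = list(stoich = c(co2_c = -1, co2_e = 1), kind = "transport"),
        EX_co2 = list(stoich = c(co2_e = -1), kind = "exchange")))
      if (refined) {
        rxns <- c(rxns, list(
          AGMT = list(stoich = c(agm_c = -1, agm_e = 1), kind = "transport"),
          EX_agm_out = list(stoich = c(agm_e = -1), lb = 0,
                            kind = "outflow")))
      }
    }
    models[[i]] <- metabolic_model(
      ids[i], rxns,
      taxonomy = list(genus = "Toyobacter",
                      species = sprintf("Toyobacter sp%02d", ceiling(i / 2))),
      biomass_reaction_id = "BIOMASS")
  }
  # the template diet is arginine-replete: community production is then
  # limited by the coupling to member biomass (i.e. by producer abundance),
  # which keeps capacities continuous across participants instead of piling
  # up at the diet bound
  list(models = models, producers = ids[seq_len(n_prod)],
       diet = diet_spec(c(glc = 10, arg = 1000),
                        participant_id = "template",
                        caloric_value_kJ = 8799))
}

#' Generate homology-hit tables matching a toy model resource
#'
#' Producer strains alternate between transporter evidence (bitscore in
#' 100-300, coverage 80-100) and cell-wall decarboxylase (speA-like)
#' evidence (bitscore 250-400), so both refinement routes are exercised.
#' Non-producers receive sub-threshold transporter hits.
#'
#' @param config a `sim_config`.
#' @param toy result of [make_toy_models()].
#' @return list with data.frames `transporter_hits` and `spea_hits` in the
#'   column layout of [parse_homology_table()].
#' @export
make_homology_hits <- function(config, toy) {
  set.seed(.substream_seed(config$seed, "homology"))
  prods <- toy$producers
  others <- setdiff(names(toy$models), prods)
  via_transporter <- prods[seq_along(prods) %% 2 == 1]
  via_spea <- prods[seq_along(prods) %% 2 == 0]
  tr <- rbind(
    data.frame(query_protein = "agmatine_transporter_1",
               target_strain = via_transporter,
               bitscore = runif(length(via_transporter), 100, 300),
               query_coverage = runif(length(via_transporter), 80, 100),
               stringsAsFactors = FALSE),
    data.frame(query_protein = "agmatine_transporter_1",
               target_strain = others,
               bitscore = runif(length(others), 5, 45),
               query_coverage = runif(length(others), 20, 70),
               stringsAsFactors = FALSE))
  sp <- data.frame(query_protein = "speA",
                   target_strain = via_spea,
                   bitscore = runif(length(via_spea), 250, 400),
                   query_coverage = runif(length(via_spea), 80, 100),
                   stringsAsFactors = FALSE)
  list(transporter_hits = tr, spea_hits = sp)
}

#' Write a homology table in 12+1-column BLAST tabular format
#'
#' Emits the `outfmt 6` column layout with query coverage appended as a
#' 13th column, the file format [parse_homology_table()] consumes.
#'
#' @param hits data.frame with `query_protein`, `target_strain`,
#'   `bitscore`, `query_coverage`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t90.0\t300\t10\t2\t1\t300\t1\t300\t1e-50\t%.1f\t%.1f",
                   hits$query_protein, hits$target_strain, hits$bitscore,
                   hits$query_coverage)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic cohort of abundance profiles
#'
#' Relative abundances are Dirichlet distributed (normalised independent
#' gamma draws). In the treated group the producer strains' concentration
#' parameters are multiplied by `effect_size`, planting higher producer
#' abundance; `effect_size = 1` makes the groups exchangeable.
#'
#' @param config a `sim_config`.
#' @param toy result of [make_toy_models()] (identifies producer strains).
#' @param data_type profile data type (sets the presence cutoff downstream).
#' @return list with `profiles` (named list of `abundance_profile`s) and
#'   `groups` (named character vector, participant -> "metformin" /
#'   "control").
#' @export
make_cohort <- function(config, toy, data_type = "amplicon16S") {
  set.seed(.substream_seed(config$seed, "cohort"))
  strains <- names(toy$models)
  alpha0 <- ifelse(strains %in% toy$producers,
                   config$alpha_producer, config$alpha_other)
  n <- config$n_per_group
  pids <- sprintf("P%03d", seq_len(2 * n))
  groups <- setNames(rep(c("control", "metformin"), each = n), pids)
  profiles <- setNames(vector("list", 2 * n), pids)
  for (i in seq_along(pids)) {
    alpha <- alpha0
    if (groups[i] == "metformin") {
      alpha[strains %in% toy$producers] <-
        alpha[strains %in% toy$producers] * config$effect_size
    }
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[] <- 1
    profiles[[i]] <- abundance_profile(setNames(g / sum(g), strains),
                                       participant_id = pids[i],
                                       data_type = data_type)
  }
  list(profiles = profiles, groups = groups)
}

#' Nitrogen-gated production toy family
#'
#' A single-organism model whose agmatine synthesis consumes four ammonium
#' (matching the four nitrogen atoms of agmatine) plus one carbon unit.
#' Supplement compounds release 1-4 ammonium on degradation; a sugar-type
#' compound releases carbon only. On the nitrogen-poor base medium the
#' production capacity is gated by nitrogen supply, so supplementation
#' ratios form discrete steps ordered by the transferable nitrogen atoms
#' and sugars leave the capacity unchanged.
#'
#' @param base_nh4 ammonium in the base medium (mmol/L).
#' @param base_carb carbon source in the base medium (mmol/L).
#' @return list with `model`, `ngm_diet` (a `diet_spec`), and `compounds`
#'   (data.frame: compound, n_atoms, class).
#' @export
make_nitrogen_toy <- function(base_nh4 = 2, base_carb = 10) {
  rxns <- list(
    EX_nh4 = list(stoich = c(nh4_e = -1), kind = "exchange"),
    EX_carb = list(stoich = c(carb_e = -1), kind = "exchange"),
    AGMSYN = list(stoich = c(nh4_e = -4, carb_e = -1, agm_e = 1), lb = 0),
    EX_agm_out = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow"),
    BIOMASS = list(stoich = c(carb_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0, kind = "outflow"))
  compounds <- data.frame(
    compound = c("pep1n", "pep2n", "pep3n", "pep4n", "sugar1"),
    n_atoms = c(1, 2, 3, 4, 0),
    class = c(rep("nitrogen", 4), "sugar"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(compounds))) {
    cp <- compounds$compound[i]
    k <- compounds$n_atoms[i]
    st <- if (k > 0) setNames(c(-1, k), c(paste0(cp, "_e"), "nh4_e"))
          else setNames(c(-1, 1), c(paste0(cp, "_e"), "carb_e"))
    rxns[[paste0("DEG_", cp)]] <- list(stoich = st, lb = 0)
    rxns[[paste0("EX_", cp)]] <- list(
      stoich = setNames(-1, paste0(cp, "_e")), kind = "exchange")
  }
  model <- metabolic_model(
    "OP50_toy", rxns,
    taxonomy = list(genus = "Escherichia", species = "Escherichia coli"),
    biomass_reaction_id = "BIOMASS")
  list(model = model,
       ngm_diet = diet_spec(c(nh4 = base_nh4, carb = base_carb),
                            participant_id = "NGM"),
       compounds = compounds)
}

#' Cross-feeding community fixture
#'
#' Strain A converts the sugar to arginine and secretes it; strain B
#' decarboxylates extracellular arginine to agmatine but cannot make
#' arginine itself. On a sugar-only diet neither strain produces agmatine
#' alone, while the joined community does (A feeds B through the lumen).
#'
#' @return list with `models` (named list of the two strains), `profile`
#'   (a 50/50 `abundance_profile`) and `diet` (sugar-only).
#' @export
make_cross_feeding_pair <- function() {
  a <- metabolic_model("XF_A", list(
    EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
    BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0, kind = "outflow"),
    ARGSYN = list(stoich = c(glc_e = -1, arg_e = 1), lb = 0),
    EX_arg = list(stoich = c(arg_e = -1), kind = "exchange")),
    taxonomy = list(genus = "Toyobacter", species = "Toyobacter feeder"),
    biomass_reaction_id = "BIOMASS")
  b <- metabolic_model("XF_B", list(
    EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
    BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0, kind = "outflow"),
    EX_arg = list(stoich = c(arg_e = -1), kind = "exchange"),
    ARGDC_EXT = list(stoich = c(arg_e = -1, agm_e = 1, co2_e = 1), lb = 0),
    EX_agm_out = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow"),
    EX_co2 = list(stoich = c(co2_e = -1), kind = "exchange")),
    taxonomy = list(genus = "Toyobacter", species = "Toyobacter converter"),
    biomass_reaction_id = "BIOMASS")
  list(models = list(XF_A = a, XF_B = b),
       profile = abundance_profile(c(XF_A = 0.5, XF_B = 0.5),
                                   participant_id = "xf",
                                   data_type = "amplicon16S"),
       diet = diet_spec(c(glc = 10), participant_id = "xf"))
}

#' Generate synthetic food-frequency records and lookup tables
#'
#' Emulates hierarchically grouped food records: some recorded items map
#' directly to exchange compounds (with molecular weights and caloric
#' densities), others contribute only through the purine and polyamine
#' augmentation tables, several of which have missing entries so that the
#' group-average imputation and the ornithine extrapolation are exercised.
#'
#' @param config a `sim_config`.
#' @return list: `records`, `compound_map`, `purine_table`,
#'   `polyamine_table`, `reference_diet`, `retained_compounds`.
#' @export
make_ffq <- function(config) {
  set.seed(.substream_seed(config$seed, "ffq"))
  items <- data.frame(
    food_item = c("glucose_syrup", "arginine_supplement", "glycerol_food",
                  "ribose_food", "serine_food",
                  "beef", "chicken", "cheese", "yoghurt", "apple",
                  "spinach", "bread"),
    group_path = c("additive/sugar", "additive/amino", "additive/sugar",
                   "additive/sugar", "additive/amino",
                   "animal/meat", "animal/meat", "animal/dairy",
                   "animal/dairy", "plant/fruit", "plant/vegetable",
                   "grain/bread"),
    stringsAsFactors = FALSE)
  compound_map <- data.frame(
    compound = c("glucose_syrup", "arginine_supplement", "glycerol_food",
                 "ribose_food", "serine_food"),
    exchange_id = c("glc", "arg", "glyc", "rib", "ser"),
    molecular_weight = c(180.16, 174.2, 92.09, 150.13, 105.09),
    kJ_per_gram = c(15.6, 16.7, 18.0, 15.6, 16.7),
    stringsAsFactors = FALSE)
  purine_table <- data.frame(
    food_item = items$food_item,
    adenosine_class = c(0, 0, 0, 0, 0,
                        0.004, 0.0035, 0.001, NA, 0.0002, 0.0008, 0.0004),
    guanosine_class = c(0, 0, 0, 0, 0,
                        0.002, 0.0018, 0.0006, NA, 0.0001, 0.0004, 0.0003),
    stringsAsFactors = FALSE)
  polyamine_table <- data.frame(
    food_item = items$food_item,
    cadaverine = c(0, 0, 0, 0, 0, 2e-4, 1e-4, 3e-4, 1e-4, 0, 5e-5, 1e-5),
    putrescine = c(0, 0, 0, 0, 0, 3e-4, 2e-4, 4e-4, 2e-4, 1e-4, 2e-4, 5e-5),
    spermidine = c(0, 0, 0, 0, 0, 4e-4, 3e-4, 2e-4, 1e-4, 5e-5, 3e-4, 1e-4),
    spermine = c(0, 0, 0, 0, 0, 2e-4, 2e-4, 1e-4, 5e-5, 2e-5, 1e-4, 4e-5),
    ornithine = c(0, 0, 0, 0, 0, 1e-3, NA, NA, 5e-4, NA, NA, NA),
    stringsAsFactors = FALSE)
  reference_diet <- diet_spec(
    c(glc = 4, arg = 0.5, glyc = 1, rib = 0.5, ser = 0.5,
      pi = 2, cu = 0.05, mn = 0.05, zn = 0.05, fe3 = 0.1, cl = 2),
    participant_id = "western_reference", caloric_value_kJ = 8799)
  n <- config$n_ffq_participants
  records <- do.call(rbind, lapply(seq_len(n), function(p) {
    data.frame(participant_id = sprintf("F%02d", p),
               food_item = items$food_item,
               group_path = items$group_path,
               grams_per_day = round(runif(nrow(items), 0, 250), 1),
               stringsAsFactors = FALSE)
  }))
  list(records = records, compound_map = compound_map,
       purine_table = purine_table, polyamine_table = polyamine_table,
       reference_diet = reference_diet,
       retained_compounds = c("pi", "cu", "mn", "zn", "fe3", "cl"))
}

#' Generate a per-well interaction design table
#'
#' Direct log2-response simulation of the screen's 2x2 design (nutrient x
#' drug with shared base-medium wells): responses are additive in the
#' nutrient, drug and planted interaction effects plus Gaussian noise.
#' This is the input shape [fit_interactions()] consumes and the generator
#' used for null and power simulation.
#'
#' @param config a `sim_config`; `n_planted` nutrients receive an
#'   interaction of `planted_effect` log2 units (set `n_planted = 0` for a
#'   global null).
#' @param drug_effect main drug effect (log2; negative = growth
#'   impairment).
#' @return list with `design` (nutrient, drug, replicate, response) and
#'   `truth` (nutrient, interaction).
#' @export
make_interaction_design <- function(config, drug_effect = -1) {
  set.seed(.substream_seed(config$seed, "screen_design"))
  nutrients <- sprintf("N%03d", seq_len(config$n_nutrients))
  planted <- if (config$n_planted > 0) {
    sort(sample(nutrients, min(config$n_planted, length(nutrients))))
  } else character(0)
  truth <- data.frame(nutrient = nutrients,
                      interaction = ifelse(nutrients %in% planted,
                                           config$planted_effect, 0),
                      stringsAsFactors = FALSE)
  nrep <- config$n_replicates
  base <- data.frame(nutrient = "", drug = rep(c(FALSE, TRUE), each = nrep),
                     replicate = rep(seq_len(nrep), 2),
                     stringsAsFactors = FALSE)
  nut_eff <- setNames(rnorm(length(nutrients), 0, 0.3), nutrients)
  cells <- do.call(rbind, lapply(nutrients, function(nu) {
    data.frame(nutrient = nu, drug = rep(c(FALSE, TRUE), each = nrep),
               replicate = rep(seq_len(nrep), 2), stringsAsFactors = FALSE)
  }))
  design <- rbind(base, cells)
  mu <- ifelse(design$nutrient == "", 0, nut_eff[design$nutrient]) +
    drug_effect * design$drug +
    ifelse(design$nutrient %in% planted & design$drug,
           config$planted_effect, 0)
  design$response <- 3 + mu + rnorm(nrow(design), 0, config$sigma)
  list(design = design, truth = truth)
}

#' Generate raw plate-screen measurements
#'
#' Emulates the four-way screen's raw data: logistic bacterial growth
#' curves `OD(t) = K / (1 + exp(-r (t - t0)))` plus Gaussian noise, with
#' the carrying capacity `K` modulated by drug, nutrient and planted
#' interaction effects on the log2 scale, and log-normal per-worm reporter
#' intensities whose drug upshift is suppressed by the planted nutrients.
#'
#' @param config a `sim_config`; generator scale is
#'   `n_nutrients x 2 drug levels x n_replicates` wells.
#' @param times measurement grid in hours.
#' @param noise_od additive OD noise standard deviation.
#' @param n_worms worms per well.
#' @param drug_effect_growth,drug_effect_worm main drug effects (log2).
#' @return list with `curves` (long data.frame: well_id, nutrient,
#'   metformin_mM, replicate, time_h, od), `worms` (well_id, nutrient,
#'   metformin_mM, replicate, worm, intensity) and `truth`.
#' @export
make_screen <- function(config, times = seq(0, 18, by = 0.25),
                        noise_od = 0.005, n_worms = 5,
                        drug_effect_growth = -1, drug_effect_worm = 1.5) {
  set.seed(.substream_seed(config$seed, "screen_raw"))
  nutrients <- sprintf("N%03d", seq_len(config$n_nutrients))
  planted <- if (config$n_planted > 0) {
    sort(sample(nutrients, min(config$n_planted, length(nutrients))))
  } else character(0)
  truth <- data.frame(nutrient = nutrients,
                      interaction = ifelse(nutrients %in% planted,
                                           config$planted_effect, 0),
                      stringsAsFactors = FALSE)
  nut_eff <- setNames(rnorm(length(nutrients), 0, 0.3), nutrients)
  wells <- expand.grid(nutrient = c("", nutrients),
                       metformin_mM = c(0, 50),
                       replicate = seq_len(config$n_replicates),
                       stringsAsFactors = FALSE)
  wells$well_id <- sprintf("W%05d", seq_len(nrow(wells)))
  drug <- wells$metformin_mM > 0
  has_nut <- wells$nutrient != ""
  log2K <- log2(1) +
    ifelse(has_nut, nut_eff[wells$nutrient], 0) +
    drug_effect_growth * drug +
    ifelse(has_nut & wells$nutrient %in% planted & drug,
           config$planted_effect, 0) +
    rnorm(nrow(wells), 0, config$sigma)
  K <- 2^log2K
  r <- 0.8
  t0 <- 6
  curves <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    od <- K[i] / (1 + exp(-r * (times - t0))) +
      rnorm(length(times), 0, noise_od)
    data.frame(well_id = wells$well_id[i], nutrient = wells$nutrient[i],
               metformin_mM = wells$metformin_mM[i],
               replicate = wells$replicate[i], time_h = times,
               od = pmax(od, 1e-4), stringsAsFactors = FALSE)
  }))
  mu_worm <- 8 +
    drug_effect_worm * drug -
    ifelse(has_nut & wells$nutrient %in% planted & drug,
           config$planted_effect, 0)
  worms <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    data.frame(well_id = wells$well_id[i], nutrient = wells$nutrient[i],
               metformin_mM = wells$metformin_mM[i],
               replicate = wells$replicate[i], worm = seq_len(n_worms),
               intensity = 2^rnorm(n_worms, mu_worm[i], 0.5),
               stringsAsFactors = FALSE)
  }))
  list(curves = curves, worms = worms, truth = truth)
}

#' Run the full cohort prediction pipeline on synthetic data
#'
#' End-to-end analysis on generated inputs: raw toy models are refined from
#' generated homology evidence, screened for growth, assembled into
#' diet-constrained coupled community models for every synthetic
#' participant, the per-participant agmatine production capacity is
#' predicted, and the treated and control groups are compared by Wilcoxon
#' rank-sum with Benjamini-Hochberg adjustment.
#'
#' @param config a `sim_config`.
#' @param coupling coupling parameters (list with `c`, `u_slack`), or NULL.
#' @return list: `capacities` (named vector), `groups`, `comparison` (from
#'   [compare_groups()]), `report` (refinement report).
#' @export
run_cohort_pipeline <- function(config,
                                coupling = list(c = 400, u_slack = 0.01)) {
  toy <- make_toy_models(config, refined = FALSE)
  hits <- make_homology_hits(config, toy)
  ref <- refine_models(toy$models, hits$transporter_hits, hits$spea_hits,
                       toy$diet)
  keep <- ref$report$strain[ref$report$growth_pass %in% TRUE]
  models <- ref$models[keep]
  cohort <- make_cohort(config, toy)
  caps <- vapply(cohort$profiles, function(pr) {
    pr$abundances <- pr$abundances[names(pr$abundances) %in% keep]
    s <- sum(pr$abundances)
    if (s <= 0) return(0)
    pr$abundances <- pr$abundances / s
    comm <- assemble_participant(models, pr, toy$diet, coupling = coupling)
    predict_capacity(comm)$capacity
  }, 0)
  list(capacities = caps, groups = cohort$groups,
       comparison = compare_groups(caps, cohort$groups),
       report = ref$report)
}
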