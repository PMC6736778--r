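#' Parse a homology-hit table (BLAST tabular dialect)
#'
#' Consumes 12-column whitespace/tab-delimited BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally extended with a 13th `qcovs` column.
#' Query coverage is taken from that extended column when present; otherwise
#' it is computed as `100 * alignment_length / query_length` from a sidecar
#' table of query lengths; if neither source is available the coverage is NA
#' and threshold filtering on coverage will fail loudly downstream.
#'
#' @param path tabular hit file. The subject id (`sseqid`) is interpreted as
#'   the target strain model id.
#' @param query_lengths optional named numeric vector or two-column
#'   data.frame (query, length) of query protein lengths.
#' @return data.frame with columns `query_protein`, `target_strain`,
#'   `bitscore`, `query_coverage` (percent, 0-100). Duplicate
#'   (query, strain) rows are retained; filtering happens downstream.
#' @export
parse_homology_table <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(data.frame(query_protein = character(), target_strain = character(),
                      bitscore = numeric(), query_coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("homology table row(s) ", paste(which(nf < 12), collapse = ", "),
         " have fewer than 12 columns")
  }
  bits <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  if (anyNA(bits)) {
    stop("non-numeric bitscore in row(s) ",
         paste(which(is.na(bits)), collapse = ", "))
  }
  alen <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  qcov <- rep(NA_real_, length(fields))
  has13 <- nf >= 13
  qcov[has13] <- suppressWarnings(as.numeric(
    vapply(fields[has13], `[[`, "", 13L)))
  qid <- vapply(fields, `[[`, "", 1L)
  if (any(is.na(qcov)) && !is.null(query_lengths)) {
    if (is.data.frame(query_lengths)) {
      query_lengths <- setNames(as.numeric(query_lengths[[2]]),
                                query_lengths[[1]])
    }
    need <- is.na(qcov) & qid %in% names(query_lengths)
    qcov[need] <- 100 * alen[need] / query_lengths[qid[need]]
  }
  data.frame(query_protein = qid,
             target_strain = vapply(fields, `[[`, "", 2L),
             bitscore = bits, query_coverage = qcov,
             stringsAsFactors = FALSE)
}

.empty_refinement_report <- function(strains, species = strains) {
  structure(data.frame(
    strain = strains, species = species,
    transporter_added = FALSE, argdc_ext_added = FALSE,
    outflow_added = FALSE, growth_pass = NA, producer = NA,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("refinement_report", "data.frame"))
}

.report_for <- function(models, report = NULL) {
  if (!is.null(report)) return(report)
  .empty_refinement_report(
    vapply(models, `[[`, "", "id"),
    vapply(models, function(m) {
      s <- m$taxonomy$species
      if (is.null(s) || is.na(s)) m$id else s
    }, ""))
}

#' Add agmatine transport reactions from transporter homology evidence
#'
#' A strain receives one reversible agmatine transport reaction
#' (`agm_c <-> agm_e`, id `AGMT`) if it has at least one transporter-query
#' hit with bitscore strictly above `bitscore_min` and query coverage at or
#' above `coverage_min`. The operation is idempotent: a strain that already
#' carries `AGMT` is left unchanged (but still flagged in the report).
#'
#' @param models named list of `metabolic_model`s (names = strain ids).
#' @param hits data.frame as returned by [parse_homology_table()].
#' @param bitscore_min strict lower bitscore threshold (default 50).
#' @param coverage_min inclusive coverage threshold in percent (default 75).
#' @param report optional existing refinement report to update.
#' @return list with `models` (updated) and `report` (a
#'   `refinement_report` data.frame with per-strain flags).
#' @export
assign_agmatine_transport <- function(models, hits, bitscore_min = 50,
                                      coverage_min = 75, report = NULL) {
  report <- .report_for(models, report)
  unknown <- setdiff(unique(hits$target_strain), names(models))
  if (length(unknown)) {
    warning("hits reference unknown strain(s), skipped: ",
            paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(hits$query_coverage))) {
    stop("query coverage unavailable for some hits; supply a coverage ",
         "column or query lengths")
  }
  pass <- hits$bitscore > bitscore_min & hits$query_coverage >= coverage_min
  qualifying <- intersect(unique(hits$target_strain[pass]), names(models))
  for (s in qualifying) {
    report$transporter_added[report$strain == s] <- TRUE
    if ("AGMT" %in% models[[s]]$rxns$id) next
    models[[s]] <- .add_reaction(models[[s]], "AGMT",
                                 c(agm_c = -1, agm_e = 1),
                                 lb = -1000, ub = 1000, kind = "transport")
  }
  list(models = models, report = report)
}

#' Add an extracellular arginine decarboxylase from speA homology
#'
#' Strains with a speA hit of bitscore strictly above `bitscore_min`
#' (default 200) gain reaction `ARGDC_EXT`: extracellular arginine ->
#' extracellular agmatine (+ extracellular CO2), with the stoichiometric
#' coefficients copied from the strain's cytosolic `ARGDC` template. A
#' qualifying strain lacking that template gets the canonical 1:1:1
#' stoichiometry with a warning.
#'
#' @inheritParams assign_agmatine_transport
#' @param bitscore_min strict bitscore threshold (default 200).
#' @export
add_extracellular_argdc <- function(models, hits, bitscore_min = 200,
                                    report = NULL) {
  report <- .report_for(models, report)
  pass <- hits$bitscore > bitscore_min
  qualifying <- intersect(unique(hits$target_strain[pass]), names(models))
  for (s in qualifying) {
    report$argdc_ext_added[report$strain == s] <- TRUE
    m <- models[[s]]
    if ("ARGDC_EXT" %in% m$rxns$id) next
    j <- match("ARGDC", m$rxns$id)
    if (is.na(j)) {
      warning("strain '", s, "' lacks a cytosolic ARGDC template; ",
              "using canonical stoichiometry")
      st <- c(arg_e = -1, agm_e = 1, co2_e = 1)
    } else {
      cyt <- m$S[, j]
      cyt <- cyt[cyt != 0]
      sp <- split_met_id(names(cyt))
      names(cyt) <- paste0(sp$base, "_e")  # relocate to the e compartment
      st <- cyt
    }
    models[[s]] <- .add_reaction(m, "ARGDC_EXT", st, lb = 0, ub = 1000,
                                 kind = "internal")
  }
  list(models = models, report = report)
}

#' Add an agmatine outflow to every refined strain
#'
#' Strains flagged with either an agmatine transporter or an extracellular
#' biosynthesis reaction gain an irreversible outflow `agm_e -> 0` (id
#' `EX_agm_out`, bounds \[0, 1000\]), the objective of the producer screen.
#'
#' @param models named list of models.
#' @param report a `refinement_report` from the two assignment steps.
#' @return list with `models` and the updated `report`.
#' @export
add_agmatine_outflow <- function(models, report) {
  for (i in seq_len(nrow(report))) {
    if (!(report$transporter_added[i] || report$argdc_ext_added[i])) next
    s <- report$strain[i]
    report$outflow_added[i] <- TRUE
    if ("EX_agm_out" %in% models[[s]]$rxns$id) next
    models[[s]] <- .add_reaction(models[[s]], "EX_agm_out", c(agm_e = -1),
                                 lb = 0, ub = 1000, kind = "outflow")
  }
  list(models = models, report = report)
}

#' Screen strain models for growth on a diet
#'
#' A model passes if its maximal biomass flux under the diet is at least
#' `biomass_cutoff` (default 0.01 mmol/gM/d); infeasible optimisations fail
#' the screen.
#'
#' @param models named list of models with biomass reactions.
#' @param diet diet passed to [apply_diet()].
#' @param biomass_cutoff minimal biomass production (inclusive).
#' @param report optional report to update.
#' @return the updated `refinement_report` with `growth_pass` filled in.
#' @export
screen_growth <- function(models, diet, biomass_cutoff = 0.01,
                          report = NULL) {
  report <- .report_for(models, report)
  for (s in names(models)) {
    m <- models[[s]]
    if (is.na(m$biomass_reaction_id)) {
      stop("model '", s, "' has no biomass reaction")
    }
    sol <- fba(apply_diet(m, diet), m$biomass_reaction_id, "max")
    report$growth_pass[report$strain == s] <-
      sol$status == "optimal" && sol$primary_objective >= biomass_cutoff
  }
  report
}

#' Screen strain models for agmatine production on a diet
#'
#' A model is a producer if its maximal agmatine outflow under the diet
#' exceeds `tol`. Models without an agmatine outflow reaction are
#' non-producers by definition. Models that failed the growth screen keep
#' `producer = NA` (they are excluded upstream).
#'
#' @inheritParams screen_growth
#' @param tol numeric tolerance on the maximal outflow (default 1e-9).
#' @param outflow_id id of the agmatine outflow reaction.
#' @return the updated `refinement_report` with `producer` filled in.
#' @export
screen_producers <- function(models, diet, tol = 1e-9, report = NULL,
                             outflow_id = "EX_agm_out") {
  report <- .report_for(models, report)
  for (s in names(models)) {
    i <- which(report$strain == s)
    if (isFALSE(report$growth_pass[i])) next
    m <- models[[s]]
    if (!(outflow_id %in% m$rxns$id)) {
      report$producer[i] <- FALSE
      next
    }
    sol <- fba(apply_diet(m, diet), outflow_id, "max")
    report$producer[i] <- sol$status == "optimal" &&
      sol$primary_objective > tol
  }
  report
}

#' Full homology-driven refinement of a strain model set
#'
#' Applies, in order: transporter assignment, extracellular decarboxylase
#' assignment, agmatine outflow addition, growth screen and producer screen.
#' Refinement only ever adds reactions; rerunning it is a no-op.
#'
#' @param models named list of models.
#' @param transporter_hits,spea_hits homology tables (see
#'   [parse_homology_table()]).
#' @param diet diet for the growth and producer screens.
#' @param bitscore_min,coverage_min,spea_bitscore_min,biomass_cutoff
#'   thresholds, as in the individual steps.
#' @return list with `models` and `report`. The report aggregates to species
#'   with [summarize_refinement()].
#' @export
refine_models <- function(models, transporter_hits, spea_hits, diet,
                          bitscore_min = 50, coverage_min = 75,
                          spea_bitscore_min = 200, biomass_cutoff = 0.01) {
  st1 <- assign_agmatine_transport(models, transporter_hits,
                                   bitscore_min, coverage_min)
  st2 <- add_extracellular_argdc(st1$models, spea_hits, spea_bitscore_min,
                                 report = st1$report)
  st3 <- add_agmatine_outflow(st2$models, st2$report)
  rep4 <- screen_growth(st3$models, diet, biomass_cutoff, report = st3$report)
  rep5 <- screen_producers(st3$models, diet, report = rep4)
  list(models = st3$models, report = rep5)
}

#' Aggregate a strain-level refinement report to species counts
#'
#' @param report a `refinement_report`.
#' @return list of counts: strains/species refined with each feature, species
#'   with at least one growing model, species with at least one producer, and
#'   both producer-screen denominators (all strains vs growth-passing
#'   strains).
#' @export
summarize_refinement <- function(report) {
  by_sp <- function(flag) length(unique(report$species[flag %in% TRUE]))
  list(
    n_strains = nrow(report),
    n_transporter = sum(report$transporter_added),
    n_argdc_ext = sum(report$argdc_ext_added),
    n_outflow = sum(report$outflow_added),
    species_with_transporter = by_sp(report$transporter_added),
    species_with_argdc_ext = by_sp(report$argdc_ext_added),
    n_growth_fail = sum(report$growth_pass %in% FALSE),
    n_producers = sum(report$producer %in% TRUE),
    producer_denominator_all = nrow(report),
    producer_denominator_growing = sum(report$growth_pass %in% TRUE))
}

# internal: append one reaction (and any new metabolites) to a model
.add_reaction <- function(model, id, stoich, lb, ub, kind) {
  if (id %in% model$rxns$id) stop("reaction '", id, "' already present")
  new_mets <- setdiff(names(stoich), model$mets$id)
  if (length(new_mets)) {
    sp <- split_met_id(new_mets)
    model$mets <- rbind(model$mets,
                        data.frame(id = new_mets, name = new_mets,
                                   base = sp$base, compartment = sp$compartment,
                                   stringsAsFactors = FALSE))
  }
  S <- model$S
  newcol <- Matrix::sparseMatrix(
    i = match(names(stoich), model$mets$id), j = rep(1L, length(stoich)),
    x = as.numeric(stoich), dims = c(nrow(model$mets), 1),
    dimnames = list(model$mets$id, id))
  if (nrow(S) < nrow(model$mets)) {
    pad <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow(model$mets) - nrow(S), ncol(S)),
                                dimnames = list(setdiff(model$mets$id,
                                                        rownames(S)),
                                                colnames(S)))
    S <- rbind(S, pad)
  }
  model$S <- cbind(S, newcol)
  model$rxns <- rbind(model$rxns,
                      data.frame(id = id, lb = lb, ub = ub, kind = kind,
                                 stringsAsFactors = FALSE))
  model
}
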