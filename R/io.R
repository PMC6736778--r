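#' Read a metabolic model from disk
#'
#' Two dialects are supported: a documented JSON dialect whose fields mirror
#' the `metabolic_model` structure, and a subset of SBML Level 3 with the
#' flux-bounds (fbc) package: compartments, species, reactions with
#' stoichiometries, per-reaction bound parameters, and an active fbc
#' objective naming the biomass reaction. Unannotated reversible reactions
#' default to bounds \[-1000, 1000\], irreversible ones to \[0, 1000\].
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml"`; guessed from the extension by default.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "json") .read_model_json(path) else .read_model_sbml(path)
}

#' Write a metabolic model to disk
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (dialect == "json") .write_model_json(model, path)
  else .write_model_sbml(model, path)
  invisible(path)
}

.read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("id", "reactions")) {
    if (is.null(doc[[f]])) stop("model JSON lacks required field '", f, "'")
  }
  mets <- NULL
  if (!is.null(doc$metabolites)) {
    mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
      data.frame(id = m$id,
                 name = if (is.null(m$name)) m$id else m$name,
                 compartment = if (is.null(m$compartment))
                   split_met_id(m$id)$compartment else m$compartment,
                 stringsAsFactors = FALSE)
    }))
  }
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (!length(st)) stop("reaction '", r$id, "' has empty stoichiometry")
    list(stoich = st,
         lb = if (is.null(r$lower_bound)) NULL else r$lower_bound,
         ub = if (is.null(r$upper_bound)) NULL else r$upper_bound,
         kind = if (is.null(r$kind)) "internal" else r$kind)
  })
  names(rxns) <- vapply(doc$reactions, `[[`, "", "id")
  tax <- list(genus = NA_character_, species = NA_character_)
  if (!is.null(doc$taxonomy)) {
    tax$genus <- doc$taxonomy$genus %||% NA_character_
    tax$species <- doc$taxonomy$species %||% NA_character_
  }
  metabolic_model(doc$id, rxns, metabolites = mets, taxonomy = tax,
                  biomass_reaction_id = doc$biomass_reaction_id %||%
                    NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_model_json <- function(model, path) {
  rl <- .reaction_list(model)
  doc <- list(
    id = model$id,
    taxonomy = model$taxonomy,
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = lapply(seq_len(n_metabolites(model)), function(i) {
      list(id = model$mets$id[i], name = model$mets$name[i],
           compartment = model$mets$compartment[i])
    }),
    reactions = lapply(names(rl), function(rid) {
      r <- rl[[rid]]
      list(id = rid, lower_bound = r$lb, upper_bound = r$ub, kind = r$kind,
           metabolites = as.list(r$stoich))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
AGC_NS <- "https://agmacap.r-pkg/ns"

.write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:agc="%s" level="3"',
                   ' version="1" fbc:required="false">'),
            SBML_NS, FBC_NS, AGC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))
  comps <- unique(model$mets$compartment)
  comps[!nzchar(comps)] <- "default"
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>',
                     esc(unique(comps))),
             "    </listOfCompartments>", "    <listOfSpecies>",
             sprintf(paste0('      <species id="%s" name="%s" compartment="%s"',
                            ' hasOnlySubstanceUnits="false"',
                            ' boundaryCondition="false" constant="false"/>'),
                     esc(model$mets$id), esc(model$mets$name),
                     esc(ifelse(nzchar(model$mets$compartment),
                                model$mets$compartment, "default"))),
             "    </listOfSpecies>", "    <listOfParameters>")
  n <- n_reactions(model)
  lines <- c(lines,
             sprintf(paste0('      <parameter id="lb_%d" value="%.12g"',
                            ' constant="true"/>'), seq_len(n), model$rxns$lb),
             sprintf(paste0('      <parameter id="ub_%d" value="%.12g"',
                            ' constant="true"/>'), seq_len(n), model$rxns$ub),
             "    </listOfParameters>", "    <listOfReactions>")
  rl <- .reaction_list(model)
  for (k in seq_len(n)) {
    st <- rl[[k]]$stoich
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d"',
             ' agc:kind="%s">'),
      esc(model$rxns$id[k]),
      if (model$rxns$lb[k] < 0) "true" else "false", k, k,
      model$rxns$kind[k]))
    rea <- st[st < 0]; pro <- st[st > 0]
    if (length(rea)) lines <- c(lines, "        <listOfReactants>",
      sprintf(paste0('          <speciesReference species="%s"',
                     ' stoichiometry="%.12g" constant="true"/>'),
              esc(names(rea)), -rea), "        </listOfReactants>")
    if (length(pro)) lines <- c(lines, "        <listOfProducts>",
      sprintf(paste0('          <speciesReference species="%s"',
                     ' stoichiometry="%.12g" constant="true"/>'),
              esc(names(pro)), pro), "        </listOfProducts>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.na(model$biomass_reaction_id)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s"',
                     ' fbc:coefficient="1"/>'),
              esc(model$biomass_reaction_id)),
      '        </fbc:listOfFluxObjectives>', '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS, agc = AGC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl, ns))) stop("no <model> element in ", path)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("no reactions in ", path)
  obj_rxn <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")
  rxns <- list()
  for (node in rx) {
    rid <- xml2::xml_attr(node, "id")
    get_side <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp, ns)
      if (!length(sr)) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")),
               xml2::xml_attr(sr, "species"))
    }
    st0 <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
             get_side("./s:listOfProducts/s:speciesReference", +1))
    st <- tapply(st0, names(st0), sum)  # merge duplicated species refs
    st <- setNames(as.numeric(st), names(st))
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(parval)) parval[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(parval)) parval[[ub_ref]]
          else 1000
    kind <- xml2::xml_attr(node, "agc:kind", ns)
    if (is.na(kind)) {
      kind <- if (length(st) == 1 && st[[1]] == -1 &&
                  grepl("^EX_", rid)) "exchange"
      else if (!is.na(obj_rxn) && identical(rid, obj_rxn)) "biomass"
      else "internal"
    }
    rxns[[rid]] <- list(stoich = st, lb = lb, ub = ub, kind = kind)
  }
  biomass <- NA_character_
  if (!is.na(obj_rxn)) biomass <- obj_rxn
  else {
    kb <- vapply(rxns, function(r) r$kind, "")
    if (any(kb == "biomass")) biomass <- names(rxns)[kb == "biomass"][1]
  }
  undeclared <- setdiff(unique(unlist(lapply(rxns, function(r)
    names(r$stoich)))), mets$id)
  if (length(undeclared)) {
    stop("reactions reference undeclared species: ",
         paste(undeclared, collapse = ", "))
  }
  metabolic_model(xml2::xml_attr(mdl, "id"), rxns, metabolites = mets,
                  biomass_reaction_id = biomass)
}
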