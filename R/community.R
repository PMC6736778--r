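#' Construct a taxon relative-abundance profile
#'
#' @param abundances named non-negative numeric vector of relative
#'   abundances (strain id -> fraction); must sum to 1 within 1e-9.
#' @param participant_id participant identifier.
#' @param data_type `"amplicon16S"` or `"metagenome"`; selects the presence
#'   cutoff in [filter_and_renormalize()].
#' @return object of class `abundance_profile`.
#' @export
abundance_profile <- function(abundances, participant_id = NA_character_,
                              data_type = c("amplicon16S", "metagenome")) {
  data_type <- match.arg(data_type)
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("abundances must be named by strain")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", format(sum(abundances)), ")")
  structure(list(participant_id = participant_id, data_type = data_type,
                 abundances = abundances[order(names(abundances))]),
            class = "abundance_profile")
}

#' Apply the presence cutoff and renormalise
#'
#' Strains below the data-type-specific relative-abundance cutoff (0.1% of
#' reads for 16S profiles, 0.01% for metagenomes, both inclusive) are
#' considered absent; the surviving fractions are renormalised to sum to 1
#' so they can serve as community biomass coefficients.
#'
#' @param profile an `abundance_profile`.
#' @param cutoff_16s,cutoff_mgx inclusive presence cutoffs per data type.
#' @return the filtered, renormalised `abundance_profile`.
#' @export
filter_and_renormalize <- function(profile, cutoff_16s = 0.001,
                                   cutoff_mgx = 0.0001) {
  cutoff <- if (profile$data_type == "amplicon16S") cutoff_16s else cutoff_mgx
  keep <- profile$abundances >= cutoff
  if (!any(keep)) stop("no strains above the presence cutoff (",
                       format(cutoff), "): no community to build")
  ab <- profile$abundances[keep]
  profile$abundances <- ab / sum(ab)
  profile
}

#' Join strain models into one community metabolic model
#'
#' Each member model is tagged with its strain id; its boundary (exchange /
#' outflow) reactions are rewired into reversible transport reactions that
#' move the compound between the member and a shared lumen compartment
#' `"u"`, and fresh community exchange reactions (`EX_<compound>_u`) connect
#' the lumen to the environment. Member biomass outflows are blocked
#' (bounds \[0, 0\]) and a community biomass reaction consumes each member's
#' biomass metabolite with coefficient `-f_k` (the filtered, renormalised
#' relative abundance), producing one unit of community biomass whose
#' outflow carries the community growth bounds.
#'
#' @param models named list of `metabolic_model`s covering every strain in
#'   the profile.
#' @param profile a filtered `abundance_profile` (fractions sum to 1).
#' @param biomass_bounds bounds on the community biomass outflow in 1/day
#'   (default `c(0.4, 1)`, about one gut turnover per day).
#' @return a `metabolic_model` with class `community_model` prepended,
#'   carrying a `members` table and a `lumen_transports` map (transport
#'   reaction -> member, compound).
#' @export
build_community <- function(models, profile, biomass_bounds = c(0.4, 1)) {
  fr <- profile$abundances
  if (abs(sum(fr) - 1) > 1e-9) stop("member fractions must sum to 1")
  missing <- setdiff(names(fr), names(models))
  if (length(missing)) stop("no model for strain(s): ",
                            paste(missing, collapse = ", "))
  strains <- sort(names(fr))

  met_id <- character(); met_base <- character(); met_comp <- character()
  rxn_id <- character(); rxn_lb <- numeric(); rxn_ub <- numeric()
  rxn_kind <- character(); rxn_member <- character()
  ti <- integer(); tj <- integer(); tx <- numeric()
  lumen <- character()
  tr_rxn <- character(); tr_member <- character(); tr_base <- character()
  mem_biomass_rxn <- character(); mem_biomass_met <- character()
  mem_species <- character()

  n_met <- 0L; n_rxn <- 0L
  for (s in strains) {
    m <- models[[s]]
    if (is.na(m$biomass_reaction_id)) {
      stop("member '", s, "' has no biomass reaction")
    }
    jb <- match(m$biomass_reaction_id, m$rxns$id)
    bcol <- m$S[, jb]
    bio_met_local <- which(bcol > 0)
    if (length(bio_met_local) != 1) {
      stop("member '", s, "' biomass reaction must produce exactly one ",
           "biomass metabolite")
    }
    tag <- function(x) paste0(x, "__", s)
    met_off <- n_met
    met_id <- c(met_id, tag(m$mets$id))
    met_base <- c(met_base, m$mets$base)
    met_comp <- c(met_comp, paste0(m$mets$compartment, "__", s))
    n_met <- n_met + nrow(m$mets)

    Su <- as(m$S, "TsparseMatrix")
    boundary <- m$rxns$kind %in% c("exchange", "outflow")
    is_bio_boundary <- boundary &
      (Matrix::colSums(m$S != 0) == 1) &
      (m$S[bio_met_local, ] != 0)

    rxn_off <- n_rxn
    rxn_id <- c(rxn_id, tag(m$rxns$id))
    rxn_kind <- c(rxn_kind, m$rxns$kind)
    rxn_member <- c(rxn_member, rep(s, nrow(m$rxns)))
    lb <- m$rxns$lb; ub <- m$rxns$ub
    lb[is_bio_boundary] <- 0; ub[is_bio_boundary] <- 0  # block biomass outflow
    conv <- boundary & !is_bio_boundary
    # boundary -> lumen transport: exchanges open in both directions, an
    # irreversible outflow keeps its one-way orientation into the lumen
    lb[conv] <- ifelse(m$rxns$kind[conv] == "outflow", pmax(lb[conv], 0),
                       -1000)
    ub[conv] <- 1000
    rxn_lb <- c(rxn_lb, lb); rxn_ub <- c(rxn_ub, ub)
    kind_new <- m$rxns$kind
    kind_new[conv] <- "transport"
    rxn_kind[rxn_off + which(conv)] <- "transport"
    n_rxn <- n_rxn + nrow(m$rxns)

    ti <- c(ti, met_off + Su@i + 1L)
    tj <- c(tj, rxn_off + Su@j + 1L)
    tx <- c(tx, Su@x)

    # add the lumen side of each converted boundary reaction
    for (k in which(conv)) {
      met_local <- which(m$S[, k] != 0)
      base <- m$mets$base[met_local]
      lm <- paste0(base, "_u")
      lumen <- union(lumen, lm)
      # original coefficient is -1 on the member side; +1 on the lumen side
      ti <- c(ti, NA_integer_)  # placeholder resolved below via lumen index
      tj <- c(tj, rxn_off + k)
      tx <- c(tx, 1)
      tr_rxn <- c(tr_rxn, tag(m$rxns$id[k]))
      tr_member <- c(tr_member, s)
      tr_base <- c(tr_base, base)
    }
    mem_biomass_rxn <- c(mem_biomass_rxn, tag(m$rxns$id[jb]))
    mem_biomass_met <- c(mem_biomass_met, tag(m$mets$id[bio_met_local]))
    sp <- m$taxonomy$species
    mem_species <- c(mem_species, if (is.null(sp) || is.na(sp)) s else sp)
  }

  # lumen metabolites after all members are known
  lumen <- sort(lumen)
  lumen_index <- setNames(n_met + seq_along(lumen), lumen)
  holes <- which(is.na(ti))
  ti[holes] <- lumen_index[paste0(tr_base, "_u")]
  met_id <- c(met_id, lumen)
  met_base <- c(met_base, sub("_u$", "", lumen))
  met_comp <- c(met_comp, rep("u", length(lumen)))
  n_met <- n_met + length(lumen)

  # community biomass metabolite + reaction + outflow
  cb_met <- "cbiomass_u"
  met_id <- c(met_id, cb_met); met_base <- c(met_base, "cbiomass")
  met_comp <- c(met_comp, "u"); n_met <- n_met + 1L
  cb_idx <- n_met
  mb_idx <- match(mem_biomass_met, met_id)

  rxn_id <- c(rxn_id, "BIOMASS_COMMUNITY")
  rxn_lb <- c(rxn_lb, 0); rxn_ub <- c(rxn_ub, 1000)
  rxn_kind <- c(rxn_kind, "biomass"); rxn_member <- c(rxn_member, NA)
  n_rxn <- n_rxn + 1L
  ti <- c(ti, mb_idx, cb_idx)
  tj <- c(tj, rep(n_rxn, length(mb_idx) + 1L))
  tx <- c(tx, -unname(fr[strains]), 1)

  rxn_id <- c(rxn_id, "EX_cbiomass_u")
  rxn_lb <- c(rxn_lb, biomass_bounds[1]); rxn_ub <- c(rxn_ub, biomass_bounds[2])
  rxn_kind <- c(rxn_kind, "outflow"); rxn_member <- c(rxn_member, NA)
  n_rxn <- n_rxn + 1L
  ti <- c(ti, cb_idx); tj <- c(tj, n_rxn); tx <- c(tx, -1)

  # community exchanges: lumen <-> environment, open until a diet is applied
  for (lm in lumen) {
    rxn_id <- c(rxn_id, paste0("EX_", lm))
    rxn_lb <- c(rxn_lb, -1000); rxn_ub <- c(rxn_ub, 1000)
    rxn_kind <- c(rxn_kind, "exchange"); rxn_member <- c(rxn_member, NA)
    n_rxn <- n_rxn + 1L
    ti <- c(ti, lumen_index[[lm]]); tj <- c(tj, n_rxn); tx <- c(tx, -1)
  }

  if (anyDuplicated(rxn_id)) stop("reaction id collision after tagging")
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_met, n_rxn),
                            dimnames = list(met_id, rxn_id))
  comm <- structure(list(
    id = paste0("community_", profile$participant_id),
    taxonomy = list(genus = NA_character_, species = NA_character_),
    mets = data.frame(id = met_id, name = met_id, base = met_base,
                      compartment = met_comp, stringsAsFactors = FALSE),
    rxns = data.frame(id = rxn_id, lb = rxn_lb, ub = rxn_ub, kind = rxn_kind,
                      member = rxn_member, stringsAsFactors = FALSE),
    S = S, biomass_reaction_id = "BIOMASS_COMMUNITY", coupling = NULL,
    members = data.frame(strain = strains, species = mem_species,
                         fraction = unname(fr[strains]),
                         biomass_rxn = mem_biomass_rxn,
                         biomass_met = mem_biomass_met,
                         stringsAsFactors = FALSE),
    lumen_transports = data.frame(rxn = tr_rxn, member = tr_member,
                                  compound = tr_base,
                                  stringsAsFactors = FALSE)),
    class = c("community_model", "metabolic_model"))
  validate_model(comm)
  comm
}

#' Add flux-biomass coupling constraints to a community
#'
#' For every reaction `j` belonging to member `k` (other than the member's
#' biomass reaction itself) two linear constraints tie the flux magnitude to
#' that member's biomass production:
#' `v_j <= c * v_biomass_k + u_slack` and `v_j >= -c * v_biomass_k - u_slack`.
#' A member forced to zero biomass can therefore carry at most `u_slack`
#' flux on any reaction, preventing metabolically active "ghost" members.
#'
#' @param community a `community_model`.
#' @param c coupling factor (default 400).
#' @param u_slack additive slack (default 0.01 mmol/gM/d).
#' @return the community with a `coupling` constraint block attached
#'   (replacing any previous one).
#' @export
add_coupling <- function(community, c = 400, u_slack = 0.01) {
  stopifnot(inherits(community, "community_model"))
  rx <- community$rxns
  n <- nrow(rx)
  bio_j <- setNames(match(community$members$biomass_rxn, rx$id),
                    community$members$strain)
  target <- which(!is.na(rx$member) & !(rx$id %in% community$members$biomass_rxn))
  if (!length(target)) stop("community has no member reactions to couple")
  bj <- bio_j[rx$member[target]]
  R <- length(target)
  C <- Matrix::sparseMatrix(
    i = c(seq_len(R), seq_len(R), R + seq_len(R), R + seq_len(R)),
    j = c(target, bj, target, bj),
    x = c(rep(1, R), rep(-c, R), rep(-1, R), rep(-c, R)),
    dims = c(2 * R, n))
  community$coupling <- list(C = C, dir = rep("<=", 2 * R),
                             rhs = rep(u_slack, 2 * R),
                             c = c, u_slack = u_slack)
  community
}

#' Assemble a participant's diet-constrained community model
#'
#' Pipeline: presence filtering and renormalisation of the abundance
#' profile, community joining, coupling constraints, then diet application
#' to the community exchange reactions.
#'
#' @param models named list of strain models.
#' @param profile an `abundance_profile`.
#' @param diet a `diet_spec` (or named amounts vector).
#' @param coupling list with elements `c` and `u_slack`, or NULL to skip
#'   coupling.
#' @param biomass_bounds community biomass outflow bounds.
#' @param cutoff_16s,cutoff_mgx presence cutoffs.
#' @return a diet-constrained `community_model`.
#' @export
assemble_participant <- function(models, profile, diet,
                                 coupling = list(c = 400, u_slack = 0.01),
                                 biomass_bounds = c(0.4, 1),
                                 cutoff_16s = 0.001, cutoff_mgx = 0.0001) {
  prof <- filter_and_renormalize(profile, cutoff_16s, cutoff_mgx)
  comm <- build_community(models, prof, biomass_bounds)
  if (!is.null(coupling)) {
    comm <- add_coupling(comm, c = coupling$c, u_slack = coupling$u_slack)
  }
  apply_diet(comm, diet)
}
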