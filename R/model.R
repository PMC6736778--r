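#' @useDynLib agmacap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats median p.adjust phyper quantile rgamma rnorm runif
#'   setNames wilcox.test lm coef pt var
#' @importFrom utils read.delim head tail
"_PACKAGE"

REACTION_KINDS <- c("internal", "exchange", "transport", "biomass", "outflow")

#' Split a metabolite id into compound base and compartment
#'
#' Metabolite ids follow the `<base>_<compartment>` convention used by gut
#' reconstruction resources (e.g. `arg_e`, `glc_c`, `agm_u`). Community
#' member tags (`<id>__<strain>`) are ignored for the purpose of the split.
#'
#' @param id character vector of metabolite ids.
#' @return data.frame with columns `base` and `compartment`.
#' @keywords internal
split_met_id <- function(id) {
  core <- sub("__.*$", "", id)
  base <- sub("_[^_]*$", "", core)
  comp <- sub("^.*_", "", core)
  bad <- !grepl("_", core)
  base[bad] <- core[bad]
  comp[bad] <- ""
  data.frame(base = base, compartment = comp, stringsAsFactors = FALSE)
}

#' Construct a strain-level metabolic model
#'
#' A model is a set of metabolites and reactions with flux bounds, a sparse
#' stoichiometric matrix `S` (metabolites x reactions, negative = consumed)
#' and a designated biomass reaction. All fluxes are in mmol per gram
#' microbiota per day (mmol/gM/d). Exchange reactions follow the convention
#' of a single metabolite with coefficient -1: negative flux is uptake from
#' the environment, positive flux is secretion.
#'
#' @param id strain identifier.
#' @param reactions named list; each element is a list with `stoich` (named
#'   numeric, metabolite id -> coefficient), and optional `lb`, `ub`, `kind`.
#'   Unannotated bounds default to \[-1000, 1000\] for reversible reactions and
#'   \[0, 1000\] when `lb` is omitted but `kind` is "outflow".
#' @param metabolites optional data.frame with columns `id`, `name`,
#'   `compartment` (+ optional `formula`, `charge`); inferred from reaction
#'   stoichiometries when omitted.
#' @param taxonomy list with `genus` and `species` character scalars.
#' @param biomass_reaction_id id of the biomass reaction (kind "biomass"),
#'   or NA for models without one.
#' @return object of class `metabolic_model`.
#' @export
#' @examples
#' m <- metabolic_model("toy", reactions = list(
#'   EX_a   = list(stoich = c(a_e = -1), lb = -10, ub = 1000, kind = "exchange"),
#'   CONV   = list(stoich = c(a_e = -1, agm_e = 1)),
#'   EX_agm = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow")))
#' fba(m, "EX_agm")$primary_objective
metabolic_model <- function(id, reactions, metabolites = NULL,
                            taxonomy = list(genus = NA_character_,
                                            species = NA_character_),
                            biomass_reaction_id = NA_character_) {
  stopifnot(is.character(id), nzchar(id), length(reactions) >= 1)
  rids <- names(reactions)
  if (is.null(rids) || any(!nzchar(rids)) || anyDuplicated(rids)) {
    stop("reactions must be a uniquely named list")
  }
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoich)),
                           use.names = FALSE))
  if (is.null(metabolites)) {
    sp <- split_met_id(met_ids)
    metabolites <- data.frame(id = met_ids, name = met_ids,
                              base = sp$base, compartment = sp$compartment,
                              stringsAsFactors = FALSE)
  } else {
    metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
    if (is.null(metabolites$base)) {
      metabolites$base <- split_met_id(metabolites$id)$base
    }
    if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  }
  missing_mets <- setdiff(met_ids, metabolites$id)
  if (length(missing_mets)) {
    stop("reactions reference undeclared metabolites: ",
         paste(missing_mets, collapse = ", "))
  }

  n <- length(reactions)
  lbs <- ubs <- numeric(n)
  kinds <- character(n)
  trip_i <- vector("list", n)
  for (k in seq_len(n)) {
    r <- reactions[[k]]
    if (is.null(r$stoich) || !length(r$stoich)) {
      stop("reaction '", rids[k], "' has empty stoichiometry")
    }
    kinds[k] <- if (is.null(r$kind)) "internal" else r$kind
    lbs[k] <- if (is.null(r$lb)) {
      if (kinds[k] %in% c("outflow", "biomass")) 0 else -1000
    } else r$lb
    ubs[k] <- if (is.null(r$ub)) 1000 else r$ub
    trip_i[[k]] <- match(names(r$stoich), metabolites$id)
  }
  S <- Matrix::sparseMatrix(
    i = unlist(trip_i),
    j = rep(seq_len(n), lengths(trip_i)),
    x = unlist(lapply(reactions, function(r) as.numeric(r$stoich)),
               use.names = FALSE),
    dims = c(nrow(metabolites), n),
    dimnames = list(metabolites$id, rids))

  m <- structure(list(
    id = id, taxonomy = taxonomy, mets = metabolites,
    rxns = data.frame(id = rids, lb = lbs, ub = ubs, kind = kinds,
                      stringsAsFactors = FALSE),
    S = S, biomass_reaction_id = biomass_reaction_id,
    coupling = NULL, members = NULL), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering (lb <= ub), non-empty reaction
#' stoichiometries, resolution of the biomass reaction to kind "biomass",
#' recognised reaction kinds, and the single-metabolite/-1 convention for
#' exchange reactions.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe all offending elements.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  r <- model$rxns
  if (anyDuplicated(r$id)) stop("duplicate reaction ids")
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids")
  if (any(!nzchar(model$mets$id))) stop("empty metabolite id")
  bad <- r$id[r$lb > r$ub]
  if (length(bad)) stop("lower bound exceeds upper bound for: ",
                        paste(bad, collapse = ", "))
  if (!all(r$kind %in% REACTION_KINDS)) {
    stop("unknown reaction kind(s): ",
         paste(setdiff(r$kind, REACTION_KINDS), collapse = ", "))
  }
  nnz <- Matrix::colSums(model$S != 0)
  if (any(nnz == 0)) stop("empty stoichiometry for: ",
                          paste(r$id[nnz == 0], collapse = ", "))
  ex <- which(r$kind == "exchange")
  for (k in ex) {
    col <- model$S[, k]
    nz <- which(col != 0)
    if (length(nz) != 1 || col[nz] != -1) {
      stop("exchange reaction '", r$id[k],
           "' must touch exactly one metabolite with coefficient -1")
    }
  }
  if (!is.na(model$biomass_reaction_id)) {
    j <- match(model$biomass_reaction_id, r$id)
    if (is.na(j)) stop("biomass_reaction_id '", model$biomass_reaction_id,
                       "' does not resolve to a reaction")
    if (r$kind[j] != "biomass") stop("biomass reaction '",
                                     model$biomass_reaction_id,
                                     "' is not of kind 'biomass'")
  }
  invisible(model)
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$rxns)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$mets)

#' Look up exchange reactions by the compound they exchange
#'
#' @param model a `metabolic_model`.
#' @param compounds character vector of compound base names (e.g. `"arg"`).
#' @return named character vector mapping compound -> exchange reaction id
#'   (NA where the model has no exchange for that compound).
#' @export
exchange_for_compound <- function(model, compounds) {
  ex <- which(model$rxns$kind == "exchange")
  if (!length(ex)) return(setNames(rep(NA_character_, length(compounds)),
                                   compounds))
  ex_met <- apply(model$S[, ex, drop = FALSE] != 0, 2, which)
  ex_base <- model$mets$base[unlist(ex_met)]
  setNames(model$rxns$id[ex][match(compounds, ex_base)], compounds)
}

#' Set flux bounds on named reactions
#' @param model a `metabolic_model`.
#' @param reaction_ids reaction ids.
#' @param lb,ub new bounds (recycled); NA leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_ids, lb = NA, ub = NA) {
  j <- match(reaction_ids, model$rxns$id)
  if (anyNA(j)) stop("unknown reaction(s): ",
                     paste(reaction_ids[is.na(j)], collapse = ", "))
  lb <- rep_len(lb, length(j)); ub <- rep_len(ub, length(j))
  model$rxns$lb[j[!is.na(lb)]] <- lb[!is.na(lb)]
  model$rxns$ub[j[!is.na(ub)]] <- ub[!is.na(ub)]
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions\n",
              x$id, n_metabolites(x), n_reactions(x)))
  if (!is.null(x$members)) {
    cat(sprintf("  community of %d members (lumen 'u')\n", nrow(x$members)))
  }
  if (!is.null(x$coupling)) {
    cat(sprintf("  %d coupling constraints\n", length(x$coupling$rhs)))
  }
  invisible(x)
}

# internal: reconstruct the reaction list form (used by writers)
.reaction_list <- function(model) {
  Su <- as(model$S, "TsparseMatrix")
  by_rxn <- split(seq_along(Su@x), Su@j + 1L)
  out <- vector("list", n_reactions(model))
  names(out) <- model$rxns$id
  for (jc in names(by_rxn)) {
    k <- as.integer(jc)
    idx <- by_rxn[[jc]]
    out[[k]] <- list(
      stoich = setNames(Su@x[idx], model$mets$id[Su@i[idx] + 1L]),
      lb = model$rxns$lb[k], ub = model$rxns$ub[k],
      kind = model$rxns$kind[k])
  }
  out
}
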