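#' Predict a community's agmatine production capacity
#'
#' Maximises the community exchange flux of the target compound under the
#' penalised objective (target outflow minus `epsilon` times the total
#' absolute flux, see [fba_with_flux_penalty()]). The capacity is the
#' resulting target flux in mmol/gM/d.
#'
#' @param community a diet-constrained `community_model`.
#' @param target compound base name of the target metabolite (default
#'   `"agm"`, agmatine).
#' @param epsilon total-flux penalty coefficient.
#' @return object of class `capacity_result`: `participant_id`, `capacity`,
#'   `solution` (a `flux_solution`), plus the community itself for
#'   downstream attribution.
#' @export
predict_capacity <- function(community, target = "agm", epsilon = 1e-6) {
  ex_id <- paste0("EX_", target, "_u")
  if (!(ex_id %in% community$rxns$id)) {
    warning("community has no lumen exchange for '", target,
            "'; capacity is 0")
    sol <- NULL
    cap <- 0
  } else {
    sol <- fba_with_flux_penalty(community, ex_id, epsilon)
    cap <- if (sol$status == "optimal") max(0, sol$primary_objective) else 0
    if (sol$status != "optimal") {
      warning("community optimisation not optimal (", sol$status,
              "); capacity reported as 0")
    }
  }
  structure(list(participant_id = sub("^community_", "", community$id),
                 capacity = cap, target = target, solution = sol,
                 community = community), class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> %s: %s capacity %.6g mmol/gM/d\n",
              x$participant_id, x$target, x$capacity))
  invisible(x)
}

#' Attribute community production to species
#'
#' Each member's net export of the target compound into the shared lumen
#' (the flux of its lumen transport reaction) is summed across all strains
#' of the same species. By lumen mass balance the contributions sum to the
#' community capacity.
#'
#' @param result a `capacity_result`.
#' @return named numeric vector, species -> mmol/gM/d.
#' @export
species_contributions <- function(result) {
  comm <- result$community
  tr <- comm$lumen_transports
  tr <- tr[tr$compound == result$target, , drop = FALSE]
  members <- comm$members
  out <- setNames(rep(0, length(unique(members$species))),
                  sort(unique(members$species)))
  if (is.null(result$solution) || result$solution$status != "optimal") {
    return(out)
  }
  if (!nrow(tr)) return(out)
  fl <- result$solution$fluxes[tr$rxn]
  sp <- members$species[match(tr$member, members$strain)]
  agg <- tapply(fl, sp, sum)
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Side-product yields of the production optimum
#'
#' For every community exchange with positive secretion flux other than the
#' target, the yield is reported in moles of side product secreted per mole
#' of target produced.
#'
#' @param result a `capacity_result` with positive capacity.
#' @param tol secretion fluxes below `tol` are ignored; a capacity below
#'   `tol` yields an empty map.
#' @return named numeric vector, compound -> mol per mol of target.
#' @export
side_product_yields <- function(result, tol = 1e-9) {
  if (result$capacity <= tol || is.null(result$solution)) {
    return(setNames(numeric(0), character(0)))
  }
  comm <- result$community
  ex <- which(comm$rxns$kind == "exchange")
  fl <- result$solution$fluxes[comm$rxns$id[ex]]
  base <- comm$mets$base[apply(comm$S[, ex, drop = FALSE] != 0, 2, which)]
  keep <- fl > tol & base != result$target
  setNames(as.numeric(fl[keep]) / result$capacity, base[keep])
}

#' In-silico nutrient supplementation screen on a community
#'
#' For each compound the community exchange uptake bound is relaxed by an
#' additional `amount` (default 1 mmol/gM/d) and the production capacity is
#' recomputed; the result reports the ratio of supplemented to baseline
#' capacity. Since supplementation only relaxes a constraint, the ratio
#' cannot fall below 1 (up to solver tolerance).
#'
#' @param community a diet-constrained `community_model`.
#' @param compounds character vector of compound base names to supplement.
#' @param amount additional uptake in mmol/gM/d.
#' @param target target compound base name.
#' @param epsilon penalty coefficient.
#' @return data.frame: `compound`, `baseline_capacity`,
#'   `supplemented_capacity`, `ratio` (NA when the baseline is 0). Unknown
#'   compounds are skipped with a warning.
#' @export
supplement_screen <- function(community, compounds, amount = 1,
                              target = "agm", epsilon = 1e-6) {
  stopifnot(amount >= 0)
  base <- predict_capacity(community, target, epsilon)$capacity
  ex_ids <- paste0("EX_", compounds, "_u")
  known <- ex_ids %in% community$rxns$id
  if (any(!known)) {
    warning("no community exchange for compound(s), skipped: ",
            paste(compounds[!known], collapse = ", "))
  }
  rows <- lapply(which(known), function(i) {
    mod <- community
    j <- match(ex_ids[i], mod$rxns$id)
    mod$rxns$lb[j] <- mod$rxns$lb[j] - amount
    cap <- predict_capacity(mod, target, epsilon)$capacity
    data.frame(compound = compounds[i], baseline_capacity = base,
               supplemented_capacity = cap,
               ratio = if (base > 0) cap / base else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Nutrient supplementation screen on a single strain model
#'
#' Emulates the growth-medium supplementation screen on a single organism
#' (such as the worm diet bacterium *E. coli* OP50 on nematode growth
#' medium): the model is constrained by the base medium, each compound's
#' uptake is extended by `amount` (default +5 mmol/L), and the ratio of
#' supplemented to baseline maximal production of the target outflow is
#' reported. Fluxes here are on the single-organism scale of the medium
#' (mmol/L), not the community scale.
#'
#' @param model a strain `metabolic_model` with an outflow for the target.
#' @param ngm_diet the base medium as a `diet_spec` or named vector.
#' @param compounds compound base names to supplement.
#' @param amount additional inflow (mmol/L).
#' @param target_outflow id of the production objective reaction.
#' @return data.frame as in [supplement_screen()].
#' @export
op50_supplement_screen <- function(model, ngm_diet, compounds, amount = 5,
                                   target_outflow = "EX_agm_out") {
  stopifnot(amount >= 0)
  if (!(target_outflow %in% model$rxns$id)) {
    stop("model lacks target outflow '", target_outflow, "'")
  }
  based <- apply_diet(model, ngm_diet)
  base_sol <- fba(based, target_outflow, "max")
  base <- if (base_sol$status == "optimal") base_sol$primary_objective else 0
  ex <- exchange_for_compound(based, compounds)
  if (any(is.na(ex))) {
    warning("no exchange for compound(s), skipped: ",
            paste(compounds[is.na(ex)], collapse = ", "))
  }
  rows <- lapply(which(!is.na(ex)), function(i) {
    mod <- based
    j <- match(ex[[i]], mod$rxns$id)
    mod$rxns$lb[j] <- mod$rxns$lb[j] - amount
    sol <- fba(mod, target_outflow, "max")
    cap <- if (sol$status == "optimal") sol$primary_objective else 0
    data.frame(compound = compounds[i], baseline_capacity = base,
               supplemented_capacity = cap,
               ratio = if (base > 0) cap / base else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare production capacities between participant groups
#'
#' All pairwise two-sided Wilcoxon rank-sum tests between group capacity
#' distributions, with Benjamini-Hochberg adjustment across the pairs.
#'
#' @param capacities named numeric vector, participant -> capacity.
#' @param groups named character vector, participant -> group label.
#' @param exact passed to [stats::wilcox.test()]; the default lets the test
#'   enumerate exactly for small untied samples and use the tie-corrected
#'   normal approximation otherwise.
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `median1`, `median2`,
#'   `statistic`, `p`, `fdr`.
#' @export
compare_groups <- function(capacities, groups, exact = NULL) {
  common <- intersect(names(capacities), names(groups))
  if (length(common) < length(capacities)) {
    warning("dropping ", length(capacities) - length(common),
            " participants without group labels")
  }
  x <- capacities[common]
  g <- factor(groups[common])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- x[g == pr[1]]; b <- x[g == pr[2]]
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               median1 = median(a), median2 = median(b),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
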