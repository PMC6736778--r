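# Independent oracles used across the suite. These deliberately avoid the
# package's simplex: the LP oracle enumerates basic solutions of the
# equality system with variables pinned at their bounds and takes the best
# feasible vertex, and the hypergeometric oracle sums the exact tail.

# brute-force dense LP: optimise cobj'v s.t. S v = 0, lb <= v <= ub
lp_oracle <- function(S, lb, ub, cobj, maximize = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  k <- n - qr(S)$rank
  if (k < 0) k <- 0
  idxsets <- if (k == 0) list(integer(0)) else combn(n, k, simplify = FALSE)
  best <- NULL
  for (fix in idxsets) {
    pats <- if (length(fix)) {
      expand.grid(rep(list(c(FALSE, TRUE)), length(fix)))
    } else data.frame(row.names = 1)
    for (p in seq_len(nrow(pats))) {
      atub <- if (length(fix)) unlist(pats[p, ]) else logical(0)
      A <- rbind(S, diag(n)[fix, , drop = FALSE])
      b <- c(rep(0, nrow(S)), ifelse(atub, ub[fix], lb[fix]))
      sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - b)) > 1e-7) next
      if (any(sol < lb - 1e-8) || any(sol > ub + 1e-8)) next
      obj <- sum(cobj * sol)
      if (is.null(best) || (maximize && obj > best) ||
          (!maximize && obj < best)) best <- obj
    }
  }
  best  # NULL when infeasible
}

# oracle applied to a metabolic_model and a named objective reaction
oracle_fba <- function(model, objective, maximize = TRUE) {
  j <- match(objective, model$rxns$id)
  cobj <- numeric(n_reactions(model)); cobj[j] <- 1
  lp_oracle(model$S, model$rxns$lb, model$rxns$ub, cobj, maximize)
}

# random small flux network as a metabolic_model (all-internal reactions);
# feasible = TRUE keeps 0 inside every bound so the zero flux vector is
# always admissible, feasible = FALSE also draws sign-forced bounds
random_network <- function(n_rxn = 6, n_met = 4, feasible = TRUE) {
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), n_met * n_rxn, replace = TRUE),
                n_met, n_rxn)
    if (all(colSums(S != 0) > 0)) break
  }
  if (feasible) {
    lb <- round(runif(n_rxn, -10, 0), 1)
    ub <- round(runif(n_rxn, 0, 12), 1)
  } else {
    lb <- round(runif(n_rxn, -10, 2), 1)
    ub <- lb + round(runif(n_rxn, 0, 12), 1)
  }
  mets <- paste0("m", seq_len(n_met), "_c")
  rxns <- lapply(seq_len(n_rxn), function(jj) {
    st <- S[, jj]; names(st) <- mets
    list(stoich = st[st != 0], lb = lb[jj], ub = ub[jj], kind = "internal")
  })
  names(rxns) <- paste0("R", seq_len(n_rxn))
  metabolic_model(paste0("net", sample.int(1e6, 1)), rxns)
}

# exact upper-tail hypergeometric probability by direct tail summation
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  if (!length(js)) return(1)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random single-strain producer toy with a designed capacity cap
random_producer_toy <- function(id = "RP", cap = round(runif(1, 1, 8), 2)) {
  metabolic_model(id, list(
    EX_glc = list(stoich = c(glc_e = -1), kind = "exchange"),
    BIOMASS = list(stoich = c(glc_e = -1, biomass_c = 1), lb = 0,
                   kind = "biomass"),
    DM_biomass = list(stoich = c(biomass_c = -1), lb = 0, kind = "outflow"),
    EX_arg = list(stoich = c(arg_e = -1), kind = "exchange"),
    ARGt = list(stoich = c(arg_e = -1, arg_c = 1), kind = "transport"),
    ARGDC = list(stoich = c(arg_c = -1, agm_c = 1, co2_c = 1), lb = 0,
                 ub = cap),
    CO2t = list(stoich = c(co2_c = -1, co2_e = 1), kind = "transport"),
    EX_co2 = list(stoich = c(co2_e = -1), kind = "exchange"),
    AGMT = list(stoich = c(agm_c = -1, agm_e = 1), kind = "transport"),
    EX_agm_out = list(stoich = c(agm_e = -1), lb = 0, kind = "outflow")),
    taxonomy = list(genus = "Toyobacter",
                    species = paste0("Toyobacter ", id)),
    biomass_reaction_id = "BIOMASS")
}
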