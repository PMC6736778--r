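#' Constrain a model's exchange bounds by a diet
#'
#' For every diet compound with a matching exchange reaction the uptake
#' (lower) bound is set to minus the available amount; exchange reactions for
#' compounds absent from the diet are closed for uptake (lower bound 0).
#' Secretion (upper) bounds are never touched. Diet compounds without a
#' matching exchange are not an error: they are recorded in the
#' `"diet_skipped"` attribute of the returned model.
#'
#' @param model a `metabolic_model` (strain or community).
#' @param diet a `diet_spec` or a named numeric vector of uptake amounts
#'   (mmol/gM/d, >= 0) keyed by compound base name (e.g. `arg`).
#' @return the constrained model, with attribute `diet_skipped` listing diet
#'   compounds the model has no exchange for.
#' @export
apply_diet <- function(model, diet) {
  amounts <- if (inherits(diet, "diet_spec")) diet$amounts else diet
  if (length(amounts) && (is.null(names(amounts)) || any(!nzchar(names(amounts)))))
    stop("diet amounts must be named by compound")
  if (any(amounts < 0)) stop("diet amounts must be >= 0")
  ex <- which(model$rxns$kind == "exchange")
  ex_met <- apply(model$S[, ex, drop = FALSE] != 0, 2, which)
  ex_base <- model$mets$base[unlist(ex_met)]
  hit <- match(ex_base, names(amounts))
  model$rxns$lb[ex] <- ifelse(is.na(hit), 0, -unname(amounts[hit]))
  attr(model, "diet_skipped") <- setdiff(names(amounts), ex_base)
  model
}

# assemble the LP rows shared by fba() and fba_with_flux_penalty():
# steady state (S v = 0) plus any coupling constraints carried by the model
.model_rows <- function(model) {
  S <- model$S
  A <- S
  dirs <- rep("==", nrow(S))
  rhs <- rep(0, nrow(S))
  if (!is.null(model$coupling)) {
    A <- rbind(A, model$coupling$C)
    dirs <- c(dirs, model$coupling$dir)
    rhs <- c(rhs, model$coupling$rhs)
  }
  list(A = A, dir = dirs, rhs = rhs)
}

.flux_solution <- function(status, fluxes, primary, total_abs, epsilon) {
  structure(list(status = status, fluxes = fluxes,
                 primary_objective = primary, total_abs_flux = total_abs,
                 penalty_coefficient = epsilon),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective=%.6g total|v|=%.6g\n",
              x$status, x$primary_objective, x$total_abs_flux))
  invisible(x)
}

#' Flux balance analysis
#'
#' Optimises the flux of one reaction subject to steady state (S v = 0), the
#' flux bounds, and any coupling constraints attached to the model.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction id to optimise.
#' @param sense `"max"` (default) or `"min"`.
#' @return a `flux_solution` with fields `status` ("optimal", "infeasible" or
#'   "unbounded"), `fluxes` (named), `primary_objective` (the objective
#'   reaction's flux) and `total_abs_flux`. For an unbounded problem the
#'   message names a reaction on the unbounded ray.
#' @export
fba <- function(model, objective_reaction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- match(objective_reaction, model$rxns$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective_reaction)
  n <- n_reactions(model)
  rows <- .model_rows(model)
  obj <- numeric(n); obj[j] <- 1
  res <- solve_lp(obj, rows$A, rows$dir, rows$rhs,
                  lower = model$rxns$lb, upper = model$rxns$ub,
                  maximize = sense == "max")
  if (res$status == "unbounded" && !is.na(res$unbounded_index)) {
    warning("objective is unbounded along reaction '",
            model$rxns$id[res$unbounded_index], "'")
  }
  fl <- setNames(res$x, model$rxns$id)
  .flux_solution(res$status, fl,
                 if (res$status == "optimal") res$objective else NA_real_,
                 if (res$status == "optimal") sum(abs(res$x)) else NA_real_,
                 0)
}

#' Flux balance analysis with a total-flux penalty
#'
#' Maximises `v_target - epsilon * sum(|v|)`: the target outflow gets
#' objective coefficient one and every reaction's absolute flux is penalised
#' with a small coefficient (default 1e-6), which selects, among alternate
#' optima, a parsimonious flux distribution. Absolute values are handled by
#' splitting each flux into two non-negative directional variables
#' (`v = v+ - v-`); the penalty drives `v+ * v- = 0` at the optimum, so the
#' reported `total_abs_flux = sum(v+ + v-)` equals `sum(|v|)`.
#'
#' @param model a `metabolic_model`.
#' @param target_outflow reaction id whose flux is maximised.
#' @param epsilon penalty coefficient (> 0) on the total absolute flux.
#' @param penalize_exchanges include boundary (exchange/outflow) reactions in
#'   the penalty sum (default TRUE: all reactions are penalised).
#' @return a `flux_solution`; `primary_objective` is the target flux itself
#'   (not the penalised objective value).
#' @export
fba_with_flux_penalty <- function(model, target_outflow, epsilon = 1e-6,
                                  penalize_exchanges = TRUE) {
  stopifnot(epsilon > 0)
  j <- match(target_outflow, model$rxns$id)
  if (is.na(j)) stop("unknown target outflow: ", target_outflow)
  n <- n_reactions(model)
  lb <- model$rxns$lb; ub <- model$rxns$ub

  # directional split: v = p - m, p in [0, max(ub,0)], m in [0, max(-lb,0)]
  p_hi <- pmax(ub, 0); m_hi <- pmax(-lb, 0)
  rows <- .model_rows(model)
  A <- cbind(rows$A, -rows$A)
  dirs <- rows$dir; rhs <- rows$rhs
  # reactions forced positive (lb > 0) or negative (ub < 0) need a range row
  forced <- which(lb > 0 | ub < 0)
  if (length(forced)) {
    B <- Matrix::sparseMatrix(
      i = rep(seq_along(forced), 2L), j = c(forced, n + forced),
      x = rep(c(1, -1), each = length(forced)), dims = c(length(forced), 2 * n))
    flo <- which(lb[forced] > 0); fhi <- which(ub[forced] < 0)
    if (length(flo)) {
      A <- rbind(A, B[flo, , drop = FALSE])
      dirs <- c(dirs, rep(">=", length(flo)))
      rhs <- c(rhs, lb[forced][flo])
    }
    if (length(fhi)) {
      A <- rbind(A, B[fhi, , drop = FALSE])
      dirs <- c(dirs, rep("<=", length(fhi)))
      rhs <- c(rhs, ub[forced][fhi])
    }
  }
  pen <- rep(epsilon, n)
  if (!penalize_exchanges) {
    pen[model$rxns$kind %in% c("exchange", "outflow")] <- 0
  }
  obj <- c(-pen, -pen)
  obj[j] <- obj[j] + 1
  obj[n + j] <- obj[n + j] - 1
  res <- solve_lp(obj, A, dirs, rhs, lower = 0, upper = c(p_hi, m_hi),
                  maximize = TRUE)
  if (res$status != "optimal") {
    return(.flux_solution(res$status, setNames(rep(NA_real_, n),
                                               model$rxns$id),
                          NA_real_, NA_real_, epsilon))
  }
  p <- res$x[seq_len(n)]; m <- res$x[n + seq_len(n)]
  fl <- setNames(p - m, model$rxns$id)
  .flux_solution("optimal", fl, fl[[target_outflow]], sum(p) + sum(m),
                 epsilon)
}

#' Verify a flux solution against a model
#'
#' Returns the largest steady-state residual `max |S v|` and the largest
#' bound violation; both should be ~0 for an optimal solution.
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_solution` for that model.
#' @return list with `max_residual` and `max_bound_violation`.
#' @export
check_solution <- function(model, solution) {
  v <- solution$fluxes[model$rxns$id]
  list(max_residual = max(abs(as.numeric(model$S %*% v))),
       max_bound_violation = max(0, model$rxns$lb - v, v - model$rxns$ub))
}
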