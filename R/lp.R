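#' Solve a bounded linear program
#'
#' Thin wrapper around the package's compiled two-phase simplex. Solves
#' \deqn{\max / \min\; c'v \quad s.t. \quad A v \;(\le,=,\ge)\; b, \quad
#' l \le v \le u.}
#' Infinite bounds are replaced internally by a large box (1e6); a solution
#' pinned to that artificial box is reported as `unbounded` together with the
#' offending variable, so genuinely unbounded rays are diagnosed by name.
#'
#' @param objective numeric objective coefficients (length n).
#' @param A constraint matrix (may be a sparse `Matrix`), or NULL for a pure
#'   box problem.
#' @param dir character vector of `"<="`, `"=="`, `">="` per row of `A`.
#' @param rhs numeric right-hand sides per row of `A`.
#' @param lower,upper variable bounds, recycled to length n.
#' @param maximize logical; maximize (default) or minimize.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (the solution on the original variable scale), `objective`, and
#'   `unbounded_index` (index of the variable certifying unboundedness).
#' @keywords internal
solve_lp <- function(objective, A = NULL, dir = character(), rhs = numeric(),
                     lower = -Inf, upper = Inf, maximize = TRUE) {
  n <- length(objective)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(lower > upper + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, unbounded_index = NA_integer_))
  }
  BIG <- 1e6
  inf_lo <- !is.finite(lower)
  inf_hi <- !is.finite(upper)
  lo <- ifelse(inf_lo, -BIG, lower)
  hi <- ifelse(inf_hi, BIG, upper)

  if (is.null(A)) {
    A <- matrix(0, 0, n)
    dir <- character(0)
    rhs <- numeric(0)
  }
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == length(dir), length(dir) == length(rhs))
  dcode <- match(dir, c("<=", "==", ">=")) - 2L
  if (anyNA(dcode)) stop("constraint directions must be '<=', '==' or '>='")

  # equilibrate constraint rows so ill-scaled coefficients (e.g. very large
  # coupling factors) do not defeat the solver's fixed pivot tolerances
  if (nrow(A)) {
    rs <- pmax(1, apply(abs(A), 1, max))
    A <- A / rs
    rhs <- rhs / rs
  }

  # shift to x = v - lo >= 0; add upper-bound rows x <= hi - lo
  rhs_shift <- rhs - as.numeric(A %*% lo)
  Aub <- diag(1, n)[hi - lo < 2 * BIG - 1, , drop = FALSE]
  bub <- (hi - lo)[hi - lo < 2 * BIG - 1]
  Afull <- rbind(A, Aub)
  bfull <- c(rhs_shift, bub)
  dfull <- c(dcode, rep(-1L, length(bub)))

  cc <- if (maximize) -objective else objective
  res <- .simplex_core(Afull, bfull, cc, as.integer(dfull))

  if (res$status == 1L) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, unbounded_index = NA_integer_))
  }
  if (res$status == 2L) {
    idx <- res$entering_index
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = NA_real_,
                unbounded_index = if (!is.na(idx) && idx <= n) idx else NA_integer_))
  }
  v <- res$x + lo
  # solution pinned against the artificial box on an infinite bound
  hit_lo <- inf_lo & (v <= -BIG * 0.999)
  hit_hi <- inf_hi & (v >= BIG * 0.999)
  if (any(hit_lo | hit_hi)) {
    return(list(status = "unbounded", x = v, objective = NA_real_,
                unbounded_index = which(hit_lo | hit_hi)[1]))
  }
  obj <- sum(objective * v)
  list(status = "optimal", x = v, objective = obj,
       unbounded_index = NA_integer_)
}
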