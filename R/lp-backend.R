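# Thin interface to the linear-programming backend.
#
# All flux LPs in the package go through solve_lp(), so a different solver
# can be substituted in one place. The default backend is the package's own
# dense bounded-variable two-phase simplex (compiled); problems here are
# small (tens to a few hundred reactions) and dense, which that method
# handles in well under a millisecond.

#' Solve a linear program over a flux polytope
#'
#' Maximizes (or minimizes) `obj . v` subject to `S v = 0`, optional extra
#' inequality rows `A v <= rhs`, and `lb <= v <= ub`.
#'
#' @param obj Objective coefficient vector (length = n columns of `S`).
#' @param S Equality-constraint matrix (steady-state stoichiometry).
#' @param lb,ub Bound vectors; lower bounds must be finite, upper bounds may
#'   be `Inf`.
#' @param A,rhs Optional inequality constraints `A v <= rhs`.
#' @param maximize Direction; `TRUE` by default.
#' @param tolerance Pivot/feasibility tolerance.
#' @param maxiter Simplex iteration cap.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failed"`), `flux` (solution vector, `NULL` unless optimal) and
#'   `objective` (value of `obj . v`).
#' @keywords internal
#' @export
solve_lp <- function(obj, S, lb, ub, A = NULL, rhs = NULL,
                     maximize = TRUE, tolerance = 1e-9, maxiter = 20000L) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    abort("solve_lp: lower bounds must be finite (clamp free reactions to a large negative bound)")
  }
  Aeq <- S
  lo <- lb; hi <- ub; cc <- obj
  if (!is.null(A)) {
    # slack variables turn A v <= rhs into equalities; slack in [0, Inf)
    k <- nrow(A)
    Aeq <- rbind(cbind(S, matrix(0, nrow(S), k)), cbind(A, diag(k)))
    cc <- c(obj, rep(0, k))
    lo <- c(lb, rep(0, k))
    hi <- c(ub, rep(Inf, k))
  }
  beq <- c(rep(0, nrow(S)), if (is.null(A)) NULL else rhs)
  res <- .lp_simplex_cpp(Aeq, beq, cc, lo, hi, maximize, as.integer(maxiter), tolerance)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded", "failed")
  flux <- if (status == "optimal") res$x[seq_len(n)] else NULL
  list(status = status, flux = flux,
       objective = if (status == "optimal") sum(obj * flux) else NA_real_)
}

lp_parts <- function(model) {
  list(S = stoich_matrix(model),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

objective_vector <- function(model) {
  cvec <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  if (length(model$objective) > 0) cvec[names(model$objective)] <- model$objective
  unname(cvec)
}
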