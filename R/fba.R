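#' Flux balance analysis
#'
#' Solves the canonical FBA linear program: maximize the objective `c . v`
#' over steady-state flux vectors, `S v = 0`, within the reaction bounds.
#' The optimal flux vector is generally non-unique; only the objective value
#' is part of the contract, the returned vertex is whichever the simplex
#' lands on (deterministic for a given model).
#'
#' @param model A [metabolic_model()] with an objective (possibly all-zero,
#'   in which case any feasible vector is returned with objective 0).
#' @param objective Optional named vector overriding the model objective for
#'   this solve.
#' @param tolerance LP tolerance.
#' @return An object of class `fba_fit`: fields `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `flux` (named
#'   vector, `NULL` unless optimal). Infeasibility is reported as a status,
#'   never coerced to zeros.
#' @export
fba <- function(model, objective = NULL, tolerance = 1e-9) {
  p <- lp_parts(model)
  if (!is.null(objective)) model <- set_objective(model, objective)
  cvec <- objective_vector(model)
  res <- solve_lp(cvec, p$S, p$lb, p$ub, maximize = TRUE, tolerance = tolerance)
  flux <- if (res$status == "optimal") stats::setNames(res$flux, p$ids) else NULL
  structure(list(status = res$status,
                 objective_value = res$objective,
                 flux = flux,
                 model_name = model$name,
                 tolerance = tolerance),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat(sprintf("<fba_fit> model %s: status %s", x$model_name, x$status))
  if (x$status == "optimal") cat(sprintf(", objective %.6g", x$objective_value))
  cat("\n")
  invisible(x)
}

#' @export
tidy.fba_fit <- function(x, ...) {
  if (is.null(x$flux)) return(tibble(reaction_id = character(), flux = numeric()))
  tibble(reaction_id = names(x$flux), flux = unname(x$flux))
}

#' @export
glance.fba_fit <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         n_reactions = length(x$flux), model = x$model_name)
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux over the steady-state
#' polytope, optionally holding the model objective at a fraction `gamma` of
#' its FBA optimum `Z0` (`c . v >= gamma * Z0`). `gamma = 1` explores the
#' optimal face only; `gamma = 0` the whole polytope.
#'
#' @param model A [metabolic_model()].
#' @param gamma Sub-optimality control in `[0, 1]`. Default: 1 when the model
#'   has an objective, 0 otherwise.
#' @param reactions Optional character vector restricting the reaction subset.
#' @param tolerance LP tolerance.
#' @return An `fva_result`: a tibble with columns `reaction_id`, `min_flux`,
#'   `max_flux`, `status` plus attributes `gamma` and `objective_value_used`
#'   (`Z0`; `NA` when `gamma = 0` or no objective). Per-reaction LP failures
#'   are flagged in `status`, not dropped.
#' @export
fva <- function(model, gamma = NULL, reactions = NULL, tolerance = 1e-9) {
  has_obj <- length(model$objective) > 0
  if (is.null(gamma)) gamma <- if (has_obj) 1 else 0
  if (gamma < 0 || gamma > 1) abort("gamma must lie in [0, 1]")
  if (gamma > 0 && !has_obj) {
    abort("gamma > 0 requires a model objective (the sub-optimality constraint references Z0)")
  }
  p <- lp_parts(model)
  subset <- if (is.null(reactions)) p$ids else {
    unknown <- setdiff(reactions, p$ids)
    if (length(unknown) > 0) {
      abort(paste0("unknown reaction(s): ", paste(unknown, collapse = ", ")))
    }
    reactions
  }
  A <- NULL; rhs <- NULL; z0 <- NA_real_
  if (gamma > 0) {
    base <- fba(model, tolerance = tolerance)
    if (base$status != "optimal") {
      abort(sprintf("FBA on '%s' is %s; cannot anchor FVA at gamma > 0",
                    model$name, base$status))
    }
    z0 <- base$objective_value
    cvec <- objective_vector(model)
    A <- matrix(-cvec, nrow = 1)       # -c.v <= -gamma Z0
    rhs <- -gamma * z0
  }
  n <- length(p$ids)
  out <- lapply(subset, function(id) {
    j <- match(id, p$ids)
    e <- rep(0, n); e[j] <- 1
    lo <- solve_lp(e, p$S, p$lb, p$ub, A = A, rhs = rhs, maximize = FALSE,
                   tolerance = tolerance)
    hi <- solve_lp(e, p$S, p$lb, p$ub, A = A, rhs = rhs, maximize = TRUE,
                   tolerance = tolerance)
    tibble(reaction_id = id,
           min_flux = if (lo$status == "optimal") lo$objective else NA_real_,
           max_flux = if (hi$status == "optimal") hi$objective else NA_real_,
           status = if (lo$status == "optimal" && hi$status == "optimal") "ok"
                    else paste0("min:", lo$status, ";max:", hi$status))
  })
  res <- dplyr::bind_rows(out)
  if (all(is.na(res$min_flux)) && nrow(res) > 0) {
    abort(sprintf("model '%s' is infeasible: every FVA subproblem failed (%s)",
                  model$name, res$status[1]))
  }
  structure(res, gamma = gamma, objective_value_used = z0,
            model_name = model$name,
            class = c("fva_result", class(res)))
}

#' @export
tidy.fva_result <- function(x, ...) {
  dplyr::mutate(as_tibble(x), span = .data$max_flux - .data$min_flux)
}

#' @export
glance.fva_result <- function(x, ...) {
  tibble(gamma = attr(x, "gamma"),
         objective_value_used = attr(x, "objective_value_used"),
         n_reactions = nrow(x),
         median_span = stats::median(x$max_flux - x$min_flux, na.rm = TRUE))
}

#' Extreme feasible flux of an exchange reaction
#'
#' Used for oxygen-uptake-rate estimation: the most extreme exchange flux
#' the remaining constraints allow. For `direction = "uptake"` the LP
#' minimizes the exchange flux and the result is reported as a magnitude
#' (`-min`); a negative magnitude then signals that the model can only
#' secrete the metabolite. For `"secretion"` the maximum is returned as-is.
#'
#' @param model A [metabolic_model()].
#' @param exchange_id Id of an exchange reaction.
#' @param direction `"uptake"` or `"secretion"`.
#' @param tolerance LP tolerance.
#' @return A single flux magnitude (mmol/gDW/h).
#' @export
maximal_exchange <- function(model, exchange_id,
                             direction = c("uptake", "secretion"),
                             tolerance = 1e-9) {
  direction <- match.arg(direction)
  if (!exchange_id %in% model$reactions$id) {
    abort(sprintf("reaction '%s' not found in model '%s'", exchange_id, model$name))
  }
  if (!exchange_id %in% find_exchanges(model)) {
    abort(sprintf("reaction '%s' is not an exchange (touches more than one metabolite)",
                  exchange_id))
  }
  p <- lp_parts(model)
  j <- match(exchange_id, p$ids)
  e <- rep(0, length(p$ids)); e[j] <- 1
  res <- solve_lp(e, p$S, p$lb, p$ub, maximize = (direction == "secretion"),
                  tolerance = tolerance)
  if (res$status != "optimal") {
    abort(sprintf("cannot compute maximal %s of '%s': solver status %s",
                  direction, exchange_id, res$status))
  }
  if (direction == "uptake") -res$objective else res$objective
}
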