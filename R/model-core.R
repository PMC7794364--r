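#' Construct a stoichiometric metabolic model
#'
#' The central container of the package: a set of metabolites, a set of
#' reactions (each a sparse column of the stoichiometric matrix `S` with flux
#' bounds and an optional gene-protein-reaction rule), and an objective
#' vector. Steady-state flux vectors `v` satisfy `S v = 0` with
#' `lower_bound <= v <= upper_bound`; by convention a negative flux through an
#' exchange reaction is uptake and a positive flux is secretion.
#'
#' @param metabolites A data frame with columns `id`, `name`, `compartment`
#'   (single-letter codes such as `"c"` cytosol, `"m"` mitochondrion,
#'   `"e"` extracellular).
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, negative coefficients = consumed),
#'   `lower_bound`, `upper_bound` (mmol/gDW/h), `gpr` (infix boolean rule over
#'   gene symbols with `and`/`or`, `""` if none) and optionally `subsystem`.
#' @param objective Named numeric vector of objective weights, names are
#'   reaction ids. May be empty.
#' @param name Model name.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [read_metabolic_model()], [fba()]
#' @export
metabolic_model <- function(metabolites, reactions, objective = numeric(), name = "model") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  m <- structure(
    list(
      name = name,
      metabolites = metabolites[, c("id", "name", "compartment")],
      reactions = reactions[, c("id", "stoichiometry", "lower_bound", "upper_bound", "gpr", "subsystem")],
      objective = objective
    ),
    class = "metabolic_model"
  )
  viol <- validate_model(m)
  if (nrow(viol) > 0) {
    abort(c("invalid metabolic model",
            stats::setNames(paste(viol$entity, "-", viol$message), rep("x", nrow(viol)))))
  }
  m
}

#' Validate a metabolic model against its structural invariants
#'
#' Checks id uniqueness, non-empty compartments, bound ordering, non-empty
#' stoichiometries, resolvable metabolite and objective references, and
#' single-metabolite arity for reactions already identifiable as exchanges.
#' Violations are returned as data, never raised.
#'
#' @param model A `metabolic_model` (or the bare list underlying one; the
#'   function never modifies its input).
#' @return A tibble with columns `entity`, `rule`, `message`; zero rows iff
#'   the model is well formed.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1]] <<- tibble(entity = entity, rule = rule, message = message)
  }
  met <- model$metabolites
  rxn <- model$reactions
  dup <- met$id[duplicated(met$id)]
  for (d in unique(dup)) add(d, "metabolite_id_unique", "duplicated metabolite id")
  bad <- met$id[is.na(met$compartment) | !nzchar(met$compartment)]
  for (b in bad) add(b, "compartment_nonempty", "metabolite has empty compartment")
  dup <- rxn$id[duplicated(rxn$id)]
  for (d in unique(dup)) add(d, "reaction_id_unique", "duplicated reaction id")
  for (i in seq_len(nrow(rxn))) {
    id <- rxn$id[i]
    st <- rxn$stoichiometry[[i]]
    if (length(st) == 0) add(id, "stoichiometry_nonempty", "reaction has empty stoichiometry")
    unknown <- setdiff(names(st), met$id)
    if (length(unknown) > 0) {
      add(id, "metabolite_resolves",
          paste0("unknown metabolite(s): ", paste(unknown, collapse = ", ")))
    }
    if (is.na(rxn$lower_bound[i]) || is.na(rxn$upper_bound[i]) ||
        rxn$lower_bound[i] > rxn$upper_bound[i]) {
      add(id, "bounds_ordered", sprintf("lower_bound %g > upper_bound %g",
                                        rxn$lower_bound[i], rxn$upper_bound[i]))
    }
  }
  unknown_obj <- setdiff(names(model$objective), rxn$id)
  for (u in unknown_obj) add(u, "objective_resolves", "objective names unknown reaction")
  if (length(v) == 0) {
    return(tibble(entity = character(), rule = character(), message = character()))
  }
  dplyr::bind_rows(v)
}

#' Identify exchange reactions
#'
#' An exchange reaction touches exactly one metabolite (uptake/secretion
#' across the system boundary, demand and sink reactions included).
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids in lexicographic order.
#' @export
find_exchanges <- function(model) {
  n_met <- vapply(model$reactions$stoichiometry, length, integer(1))
  sort(model$reactions$id[n_met == 1L])
}

#' Add a reaction to a model
#'
#' Returns a modified copy; the input model is never changed in place. New
#' metabolites referenced by the reaction can be added in the same call.
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id, must not already be present.
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param lower_bound,upper_bound Flux bounds (mmol/gDW/h).
#' @param gpr Gene-protein-reaction rule string (`""` for none).
#' @param subsystem Optional subsystem label.
#' @param new_metabolites Optional data frame (`id`, `name`, `compartment`)
#'   of metabolites to add together with the reaction.
#' @return A new `metabolic_model` with one extra reaction column.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                         upper_bound = 1000, gpr = "", subsystem = NA_character_,
                         new_metabolites = NULL) {
  if (id %in% model$reactions$id) {
    abort(sprintf("reaction id '%s' already present in model '%s'", id, model$name))
  }
  met <- model$metabolites
  if (!is.null(new_metabolites)) {
    nm <- as_tibble(new_metabolites)
    if (!"name" %in% names(nm)) nm$name <- nm$id
    met <- dplyr::bind_rows(met, nm[, c("id", "name", "compartment")])
  }
  rxn <- dplyr::bind_rows(
    model$reactions,
    tibble(id = id, stoichiometry = list(stoichiometry),
           lower_bound = lower_bound, upper_bound = upper_bound,
           gpr = gpr, subsystem = subsystem)
  )
  metabolic_model(met, rxn, objective = model$objective, name = model$name)
}

#' Set or replace the model objective
#'
#' @param model A `metabolic_model`.
#' @param objective Named numeric vector of weights over reaction ids.
#' @return The model with the new objective.
#' @export
set_objective <- function(model, objective) {
  unknown <- setdiff(names(objective), model$reactions$id)
  if (length(unknown) > 0) {
    abort(paste0("objective names unknown reaction(s): ", paste(unknown, collapse = ", ")))
  }
  model$objective <- objective
  model
}

#' Set flux bounds on one reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model (copy).
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) abort(sprintf("reaction '%s' not found", id))
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    abort(sprintf("reaction '%s': lower_bound %g > upper_bound %g", id,
                  model$reactions$lower_bound[i], model$reactions$upper_bound[i]))
  }
  model
}

#' Dense stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Numeric matrix `S` of shape n_metabolites x n_reactions with
#'   dimnames (metabolite ids, reaction ids).
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$name))
  cat(sprintf("  metabolites: %d  reactions: %d  exchanges: %d\n",
              nrow(x$metabolites), nrow(x$reactions), length(find_exchanges(x))))
  if (length(x$objective) > 0) {
    cat("  objective:", paste(sprintf("%+g %s", x$objective, names(x$objective)),
                              collapse = " "), "\n")
  } else {
    cat("  objective: (none)\n")
  }
  invisible(x)
}

#' Tidy the reaction table of a model
#'
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: id, bounds, gpr, subsystem,
#'   number of metabolites, exchange flag and objective weight.
#' @export
tidy.metabolic_model <- function(x, ...) {
  ex <- find_exchanges(x)
  obj <- x$objective
  dplyr::mutate(
    x$reactions,
    n_metabolites = vapply(.data$stoichiometry, length, integer(1)),
    is_exchange = .data$id %in% ex,
    objective_weight = ifelse(.data$id %in% names(obj), obj[.data$id], 0)
  )[, c("id", "lower_bound", "upper_bound", "gpr", "subsystem",
        "n_metabolites", "is_exchange", "objective_weight")]
}

#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(name = x$name,
         n_metabolites = nrow(x$metabolites),
         n_reactions = nrow(x$reactions),
         n_exchanges = length(find_exchanges(x)),
         n_objective = length(x$objective))
}
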