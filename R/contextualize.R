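#' Biomass composition of a cell line
#'
#' Macromolecule dry-weight fractions (g per gDW). Defaults: protein 0.70
#' (dominant fraction of dry cell weight), lipid 0.20, RNA 0.08, DNA 0.02,
#' diploid chromosome count 46. When `chromosome_count` differs from 46 the
#' DNA fraction is scaled by `chromosome_count / 46` (DNA mass tracks ploidy)
#' and the difference is absorbed proportionally by the lipid and RNA
#' fractions so the four fractions still sum to one; the protein fraction is
#' held fixed.
#'
#' @param protein,dna,rna,lipid Mass fractions (g/gDW); must sum to 1.
#' @param chromosome_count Chromosome units of the line (e.g. 44 for a
#'   hypodiploid glioblastoma karyotype).
#' @return A `biomass_composition` list with adjusted fractions.
#' @export
biomass_composition <- function(protein = 0.70, dna = 0.02, rna = 0.08,
                                lipid = 0.20, chromosome_count = 46L) {
  fr <- c(protein = protein, dna = dna, rna = rna, lipid = lipid)
  if (any(fr < 0)) abort("biomass fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) {
    abort(sprintf("biomass fractions must sum to 1 (got %.12g)", sum(fr)))
  }
  dna_adj <- dna * chromosome_count / 46
  spare <- 1 - protein - dna_adj
  base <- rna + lipid
  rna_adj <- if (base > 0) spare * rna / base else spare / 2
  lipid_adj <- if (base > 0) spare * lipid / base else spare / 2
  structure(list(protein_fraction = protein, dna_fraction = dna_adj,
                 rna_fraction = rna_adj, lipid_fraction = lipid_adj,
                 chromosome_count = as.integer(chromosome_count)),
            class = "biomass_composition")
}

#' Build a biomass reaction from a composition
#'
#' The biomass reaction drains one pseudo-metabolite per macromolecule class
#' with a coefficient equal to the class mass fraction (precursor pool units
#' are g per mmol of pool, so biomass flux is in 1/h). Coefficients scale
#' linearly with the fractions.
#'
#' @param composition A [biomass_composition()].
#' @param template The model supplying the precursor metabolites.
#' @param precursors Named character vector mapping classes
#'   (`protein`, `dna`, `rna`, `lipid`) to metabolite ids in the template.
#' @param id Reaction id for the biomass reaction.
#' @return A list describing the reaction (fields `id`, `stoichiometry`,
#'   `lower_bound`, `upper_bound`), ready for [add_reaction()].
#' @export
build_biomass <- function(composition, template,
                          precursors = c(protein = "prot_c", dna = "dna_c",
                                         rna = "rna_c", lipid = "lip_c"),
                          id = "BIOMASS") {
  missing <- setdiff(unname(precursors), template$metabolites$id)
  if (length(missing) > 0) {
    abort(paste0("template lacks biomass precursor metabolite(s): ",
                 paste(missing, collapse = ", ")))
  }
  fr <- c(protein = composition$protein_fraction, dna = composition$dna_fraction,
          rna = composition$rna_fraction, lipid = composition$lipid_fraction)
  st <- stats::setNames(-unname(fr), unname(precursors[names(fr)]))
  st <- st[st != 0]
  list(id = id, stoichiometry = st, lower_bound = 0, upper_bound = 1000,
       gpr = "", subsystem = "biomass")
}

#' Constrain exchange reactions to measured rates
#'
#' Each row fixes the exchange of one metabolite to a symmetric band
#' `rate +/- (|rate| * tolerance_band + tolerance_abs)` (negative rate =
#' uptake; a zero band pins the flux exactly). The absolute term
#' accommodates rates near zero whose measurement error has an absolute
#' floor. All other exchanges are untouched.
#'
#' @param model A [metabolic_model()].
#' @param exchanges Data frame with columns `metabolite`, `rate`
#'   (mmol/gDW/h) and optionally `tolerance_band` (fraction, default 0.05)
#'   and `tolerance_abs` (mmol/gDW/h, default 0).
#' @return The re-bounded model; attribute `"n_rebounded"` carries the count
#'   of modified reactions (equal to `nrow(exchanges)`).
#' @export
apply_exchange_constraints <- function(model, exchanges) {
  exchanges <- as_tibble(exchanges)
  if (nrow(exchanges) == 0) return(model)
  if (!"tolerance_band" %in% names(exchanges)) exchanges$tolerance_band <- 0.05
  if (!"tolerance_abs" %in% names(exchanges)) exchanges$tolerance_abs <- 0
  if (any(exchanges$tolerance_band < 0) || any(exchanges$tolerance_abs < 0)) {
    abort("tolerance_band and tolerance_abs must be >= 0")
  }
  ex_ids <- find_exchanges(model)
  ex_met <- vapply(ex_ids, function(id) {
    names(model$reactions$stoichiometry[[match(id, model$reactions$id)]])
  }, character(1))
  hit <- match(exchanges$metabolite, ex_met)
  if (anyNA(hit)) {
    abort(paste0("no exchange reaction for metabolite(s): ",
                 paste(exchanges$metabolite[is.na(hit)], collapse = ", ")))
  }
  for (i in seq_len(nrow(exchanges))) {
    rid <- ex_ids[hit[i]]
    rate <- exchanges$rate[i]
    half <- abs(rate) * exchanges$tolerance_band[i] + exchanges$tolerance_abs[i]
    model <- set_bounds(model, rid, lower_bound = rate - half,
                        upper_bound = rate + half)
  }
  attr(model, "n_rebounded") <- nrow(exchanges)
  model
}

#' Contract bounds of reactions impaired by deleterious mutations
#'
#' For every reaction whose gene-protein-reaction rule fails once the
#' deleterious genes are inactivated (`and` = complex subunits, `or` =
#' isozymes), the upper bound is pulled down to
#' `v_min + factor * |v_min - v_max|`, where `(v_min, v_max)` is the
#' reaction's feasible range in the *unaltered* model from flux variability
#' analysis, and the lower bound is set to that `v_min`. The default factor
#' 0.25 leaves the impaired reaction a quarter of its unaltered flux width,
#' anchored at the low end (the `"literal"` mode); `"symmetric"` instead
#' keeps the middle quarter of the range.
#'
#' @param model A [metabolic_model()].
#' @param mutations Data frame with columns `gene`, and either
#'   `is_deleterious` (logical) or `deleterious_probability` thresholded at
#'   `pph2_threshold`. Optional `variant_label`.
#' @param fva_unaltered An [fva()] result computed on the model *before*
#'   mutation constraints.
#' @param factor Contraction factor in (0, 1].
#' @param pph2_threshold Probability cutoff when `is_deleterious` is absent.
#' @param mode `"literal"` (anchor at v_min) or `"symmetric"` (centered).
#' @return The constrained model; attribute `"contracted_reactions"` lists
#'   the modified reaction ids. Genes that appear in no rule trigger a
#'   warning, not an error (mutations may hit non-metabolic genes).
#' @export
apply_enzymopathies <- function(model, mutations, fva_unaltered,
                                factor = 0.25, pph2_threshold = 0.95,
                                mode = c("literal", "symmetric")) {
  mode <- match.arg(mode)
  if (factor <= 0 || factor > 1) abort("enzymopathy factor must be in (0, 1]")
  mutations <- as_tibble(mutations)
  if (!"is_deleterious" %in% names(mutations)) {
    if (!"deleterious_probability" %in% names(mutations)) {
      abort("mutations need an is_deleterious or deleterious_probability column")
    }
    mutations$is_deleterious <- mutations$deleterious_probability >= pph2_threshold
  }
  del_genes <- unique(mutations$gene[mutations$is_deleterious])
  attr(model, "contracted_reactions") <- character()
  if (length(del_genes) == 0) return(model)
  all_genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  orphan <- setdiff(del_genes, all_genes)
  if (length(orphan) > 0) {
    warn(paste0("deleterious gene(s) not in any GPR (ignored): ",
                paste(orphan, collapse = ", ")))
  }
  impaired <- model$reactions$id[!vapply(model$reactions$gpr, gpr_active,
                                         logical(1), inactive_genes = del_genes)]
  contracted <- character()
  for (rid in impaired) {
    k <- match(rid, fva_unaltered$reaction_id)
    if (is.na(k) || is.na(fva_unaltered$min_flux[k])) next
    vmin <- fva_unaltered$min_flux[k]
    vmax <- fva_unaltered$max_flux[k]
    w <- abs(vmin - vmax)
    if (mode == "literal") {
      lo <- vmin
      hi <- vmin + factor * w
    } else {
      mid <- (vmin + vmax) / 2
      lo <- mid - factor * w / 2
      hi <- mid + factor * w / 2
    }
    model <- set_bounds(model, rid, lower_bound = lo, upper_bound = hi)
    contracted <- c(contracted, rid)
  }
  attr(model, "contracted_reactions") <- contracted
  model
}

#' Add in-silico redox probe reactions
#'
#' Two cytosolic probes: a pseudo-hypoxia reaction
#' `nad[c] + h2[c] -> nadh[c] + h[c]` that converts NAD+ to NADH to emulate
#' a hypoxic redox push, and an NADH oxidase
#' `nadh[c] + h[c] + 1/2 o2[c] -> nad[c] + h2o[c]` whose maximal flux probes
#' the model's capacity to re-oxidize cytosolic NADH (recycle NAD+). Both
#' are irreversible with bounds `[0, 1000]`.
#'
#' @param model A [metabolic_model()].
#' @param pseudo_hypoxia,nadh_oxidase Which probes to add.
#' @param cofactors Named map from roles (`nad`, `nadh`, `h`, `h2`, `o2`,
#'   `h2o`) to metabolite ids in the model.
#' @param ids Reaction ids used for the probes.
#' @return The model with the requested probe reactions appended.
#' @export
add_probe_reactions <- function(model, pseudo_hypoxia = TRUE, nadh_oxidase = FALSE,
                                cofactors = c(nad = "nad_c", nadh = "nadh_c",
                                              h = "h_c", h2 = "h2_c",
                                              o2 = "o2_c", h2o = "h2o_c"),
                                ids = c(pseudo_hypoxia = "PSEUDO_HYPOXIA",
                                        nadh_oxidase = "NADH_OXIDASE")) {
  need <- character()
  if (pseudo_hypoxia) need <- c(need, c("nad", "nadh", "h", "h2"))
  if (nadh_oxidase) need <- c(need, c("nad", "nadh", "h", "o2", "h2o"))
  missing <- setdiff(unname(cofactors[unique(need)]), model$metabolites$id)
  if (length(missing) > 0) {
    abort(paste0("model lacks cofactor metabolite(s) for probe reactions: ",
                 paste(missing, collapse = ", ")))
  }
  if (pseudo_hypoxia) {
    st <- stats::setNames(c(-1, -1, 1, 1),
                          unname(cofactors[c("nad", "h2", "nadh", "h")]))
    model <- add_reaction(model, ids[["pseudo_hypoxia"]], st,
                          lower_bound = 0, upper_bound = 1000,
                          subsystem = "probe")
  }
  if (nadh_oxidase) {
    st <- stats::setNames(c(-1, -1, -0.5, 1, 1),
                          unname(cofactors[c("nadh", "h", "o2", "nad", "h2o")]))
    model <- add_reaction(model, ids[["nadh_oxidase"]], st,
                          lower_bound = 0, upper_bound = 1000,
                          subsystem = "probe")
  }
  model
}

#' Cell-line contextualization bundle
#'
#' Collects everything needed to turn the template network into a
#' cell-line-specific model: biomass composition, measured exchange rates,
#' growth rate, ATP maintenance, oxygen-uptake capping mode, probe flags and
#' the mutation table driving enzymopathy constraints.
#'
#' @param cell_line_name Label for the contextualized model.
#' @param biomass A [biomass_composition()].
#' @param exchanges Exchange-rate table (`metabolite`, `rate`, optional
#'   `tolerance_band`).
#' @param growth_rate Measured specific growth rate (1/h).
#' @param mutations Optional mutation table (`gene`,
#'   `deleterious_probability` and/or `is_deleterious`).
#' @param atp_maintenance Non-growth ATP demand flux, fixed in the model
#'   (default 1.07 mmol/gDW/h).
#' @param our_cap_mode `"fba_max"` caps oxygen uptake at the FBA-maximal
#'   feasible value; `"fixed"` uses `our_value`.
#' @param our_value Fixed oxygen-uptake cap (magnitude), for mode `"fixed"`.
#' @param add_pseudo_hypoxia,add_nadh_oxidase Probe flags.
#' @param enzymopathy_factor Contraction factor for impaired reactions.
#' @param pph2_threshold Deleterious-probability cutoff (default 0.95).
#' @param growth_band Fractional band around `growth_rate` (default 0.02).
#' @param biomass_id,atp_maintenance_id,oxygen_exchange_id Reaction ids in
#'   the template convention.
#' @param precursors Biomass precursor map, see [build_biomass()].
#' @return A `context_spec` list.
#' @export
context_spec <- function(cell_line_name, biomass, exchanges, growth_rate,
                         mutations = NULL, atp_maintenance = 1.07,
                         our_cap_mode = c("fba_max", "fixed"), our_value = NA_real_,
                         add_pseudo_hypoxia = FALSE, add_nadh_oxidase = FALSE,
                         enzymopathy_factor = 0.25, pph2_threshold = 0.95,
                         growth_band = 0.02,
                         biomass_id = "BIOMASS", atp_maintenance_id = "ATPM",
                         oxygen_exchange_id = "EX_o2_e",
                         precursors = c(protein = "prot_c", dna = "dna_c",
                                        rna = "rna_c", lipid = "lip_c")) {
  our_cap_mode <- match.arg(our_cap_mode)
  stopifnot(growth_rate >= 0, atp_maintenance >= 0,
            enzymopathy_factor > 0, enzymopathy_factor <= 1, growth_band >= 0)
  structure(list(cell_line_name = cell_line_name, biomass = biomass,
                 exchanges = as_tibble(exchanges), growth_rate = growth_rate,
                 mutations = if (is.null(mutations)) NULL else as_tibble(mutations),
                 atp_maintenance = atp_maintenance,
                 our_cap_mode = our_cap_mode, our_value = our_value,
                 add_pseudo_hypoxia = add_pseudo_hypoxia,
                 add_nadh_oxidase = add_nadh_oxidase,
                 enzymopathy_factor = enzymopathy_factor,
                 pph2_threshold = pph2_threshold, growth_band = growth_band,
                 biomass_id = biomass_id, atp_maintenance_id = atp_maintenance_id,
                 oxygen_exchange_id = oxygen_exchange_id, precursors = precursors),
            class = "context_spec")
}

#' Contextualize the template model for one cell line
#'
#' Applies the contextualization stages in a fixed order: (1) build and add
#' the biomass reaction and make it the objective; (2) constrain exchanges to
#' measured rates; (3) fix biomass flux to the measured growth rate (within
#' `growth_band`); (4) fix the ATP maintenance flux; (5) cap oxygen uptake at
#' the FBA-maximal feasible value (or a fixed value); (6) add probe
#' reactions; (7) contract impaired reactions using flux variability of the
#' model *before* this stage (the "unaltered" reference) and the
#' enzymopathy factor. After every stage feasibility is re-checked; an
#' infeasibility is reported with the name of the stage that introduced it.
#'
#' @param template A [metabolic_model()] containing the biomass precursors,
#'   an ATP maintenance reaction and an oxygen exchange.
#' @param spec A [context_spec()].
#' @return The contextualized `metabolic_model` with attributes `"context"`
#'   (the spec) and `"contracted_reactions"`.
#' @export
contextualize_cell_line <- function(template, spec) {
  stopifnot(inherits(spec, "context_spec"))
  stage <- function(model, name, f) {
    model <- f(model)
    chk <- fba(model)
    if (chk$status != "optimal") {
      abort(sprintf("contextualization of '%s' became %s at stage '%s'",
                    spec$cell_line_name, chk$status, name))
    }
    model
  }
  m <- template
  m$name <- spec$cell_line_name
  m <- stage(m, "biomass", function(m) {
    br <- build_biomass(spec$biomass, m, precursors = spec$precursors,
                        id = spec$biomass_id)
    m <- add_reaction(m, br$id, br$stoichiometry, br$lower_bound,
                      br$upper_bound, subsystem = "biomass")
    set_objective(m, stats::setNames(1, spec$biomass_id))
  })
  m <- stage(m, "exchange_constraints",
             function(m) apply_exchange_constraints(m, spec$exchanges))
  m <- stage(m, "growth_rate", function(m) {
    half <- spec$growth_rate * spec$growth_band
    set_bounds(m, spec$biomass_id, lower_bound = spec$growth_rate - half,
               upper_bound = spec$growth_rate + half)
  })
  m <- stage(m, "atp_maintenance", function(m) {
    if (!spec$atp_maintenance_id %in% m$reactions$id) {
      abort(sprintf("template lacks ATP maintenance reaction '%s'",
                    spec$atp_maintenance_id))
    }
    set_bounds(m, spec$atp_maintenance_id, lower_bound = spec$atp_maintenance,
               upper_bound = spec$atp_maintenance)
  })
  m <- stage(m, "oxygen_uptake_cap", function(m) {
    cap <- if (spec$our_cap_mode == "fba_max") {
      maximal_exchange(m, spec$oxygen_exchange_id, "uptake")
    } else spec$our_value
    if (is.na(cap)) abort("our_cap_mode 'fixed' needs a finite our_value")
    set_bounds(m, spec$oxygen_exchange_id, lower_bound = -abs(cap))
  })
  if (spec$add_pseudo_hypoxia || spec$add_nadh_oxidase) {
    m <- stage(m, "probe_reactions", function(m) {
      add_probe_reactions(m, pseudo_hypoxia = spec$add_pseudo_hypoxia,
                          nadh_oxidase = spec$add_nadh_oxidase)
    })
  }
  contracted <- character()
  if (!is.null(spec$mutations) && nrow(spec$mutations) > 0) {
    fva_ref <- fva(m, gamma = 0)
    m <- stage(m, "enzymopathy", function(m) {
      apply_enzymopathies(m, spec$mutations, fva_ref,
                          factor = spec$enzymopathy_factor,
                          pph2_threshold = spec$pph2_threshold)
    })
    contracted <- attr(m, "contracted_reactions")
  }
  attr(m, "context") <- spec
  attr(m, "contracted_reactions") <- contracted
  m
}

#' Leave-one-out prediction of nutrient exchange rates
#'
#' Validation protocol for a contextualized model: for each primary nutrient
#' (an exchange-constrained metabolite with negative measured rate, i.e. an
#' uptake), rebuild the model with every *other* exchange pinned exactly at
#' its measured rate and the biomass flux fixed at the measured growth rate,
#' leave the focal exchange free, and predict its flux by FBA. Accuracy per
#' nutrient is `100 * (1 - |predicted - measured| / |measured|)`.
#'
#' @param template The template [metabolic_model()].
#' @param spec A [context_spec()]; its `exchanges` table supplies the
#'   measured rates.
#' @param nutrients Optional metabolite subset; defaults to all uptaken
#'   (rate < 0) metabolites in the exchange table.
#' @return A tibble `metabolite`, `measured`, `predicted`, `accuracy`.
#' @export
predict_uptake_rates <- function(template, spec, nutrients = NULL) {
  exch <- spec$exchanges
  if (is.null(nutrients)) nutrients <- exch$metabolite[exch$rate < 0]
  missing <- setdiff(nutrients, exch$metabolite)
  if (length(missing) > 0) {
    abort(paste0("nutrient(s) not in the exchange table: ",
                 paste(missing, collapse = ", ")))
  }
  base <- template
  br <- build_biomass(spec$biomass, base, precursors = spec$precursors,
                      id = spec$biomass_id)
  base <- add_reaction(base, br$id, br$stoichiometry, br$lower_bound,
                       br$upper_bound, subsystem = "biomass")
  base <- set_objective(base, stats::setNames(1, spec$biomass_id))
  base <- set_bounds(base, spec$biomass_id, lower_bound = spec$growth_rate,
                     upper_bound = spec$growth_rate)
  base <- set_bounds(base, spec$atp_maintenance_id,
                     lower_bound = spec$atp_maintenance,
                     upper_bound = spec$atp_maintenance)
  ex_ids <- find_exchanges(template)
  ex_met <- vapply(ex_ids, function(id) {
    names(template$reactions$stoichiometry[[match(id, template$reactions$id)]])
  }, character(1))
  rows <- lapply(nutrients, function(metab) {
    others <- exch[exch$metabolite != metab, ]
    others$tolerance_band <- 0                    # measured rates taken as exact
    m <- apply_exchange_constraints(base, others)
    focal_id <- ex_ids[match(metab, ex_met)]
    j <- match(focal_id, template$reactions$id)
    m <- set_bounds(m, focal_id,
                    lower_bound = template$reactions$lower_bound[j],
                    upper_bound = template$reactions$upper_bound[j])
    sol <- fba(m)
    measured <- exch$rate[exch$metabolite == metab]
    predicted <- if (sol$status == "optimal") unname(sol$flux[focal_id]) else NA_real_
    tibble(metabolite = metab, measured = measured, predicted = predicted,
           accuracy = 100 * (1 - abs(predicted - measured) / abs(measured)))
  })
  dplyr::bind_rows(rows)
}
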