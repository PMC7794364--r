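#' Toy metabolic networks with analytically known flux polytopes
#'
#' Small networks whose flux variability ranges (and, for `"simplex"`, the
#' uniform measure over the polytope) are known in closed form, so solver and
#' sampler behaviour can be checked against ground truth that never passes
#' through the code under test.
#'
#' * `chain`: linear pathway `EX_A -> R1 -> ... -> EX_B` with uptake bound
#'   10; every internal flux is pinned to the uptake. `size` = total
#'   reactions (>= 3).
#' * `branch`: one uptake fixed at 10 splitting into two free exports
#'   (objective: export of B).
#' * `cycle`: a 3-cycle with capacity 50 riding on a throughput of <= 10.
#' * `simplex`: fixed uptake 10 split across `size` parallel drains, so the
#'   polytope is the scaled (`size`-1)-simplex `sum v_i = 10, v_i >= 0`.
#' * `random`: a flux-consistent random network built from a reference flux
#'   vector (feasible by construction); ranges are not analytic and the
#'   truth record carries the reference flux and seed instead.
#'
#' @param kind One of `"chain"`, `"branch"`, `"cycle"`, `"simplex"`,
#'   `"random"`.
#' @param size Size parameter (see above); ignored for `branch`/`cycle`.
#' @param seed Seed for `random` (deterministic regeneration).
#' @return List with `model` (a [metabolic_model()]) and `truth` (a list
#'   with `fva_ranges` for the analytic kinds, the `reference_flux` for
#'   `random`, and bookkeeping fields).
#' @export
make_toy_network <- function(kind = c("chain", "branch", "cycle", "simplex", "random"),
                             size = 3, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    chain = toy_chain(size),
    branch = toy_branch(),
    cycle = toy_cycle(),
    simplex = toy_simplex(size),
    random = toy_random(size, seed)
  )
}

toy_mets <- function(ids, compartment = "c") {
  tibble(id = ids, name = ids, compartment = compartment)
}

toy_rxn <- function(id, st, lb = 0, ub = 1000, gpr = "", subsystem = NA_character_) {
  tibble(id = id, stoichiometry = list(st), lower_bound = lb, upper_bound = ub,
         gpr = gpr, subsystem = subsystem)
}

toy_chain <- function(size) {
  if (size < 3) abort("chain toys need size >= 3 (uptake, >=1 conversion, export)")
  n_int <- size - 2
  mets <- paste0("M", seq_len(n_int + 1))
  rx <- list(toy_rxn("EX_A", c(M1 = -1), lb = -10, ub = 0))
  for (i in seq_len(n_int)) {
    st <- stats::setNames(c(-1, 1), mets[c(i, i + 1)])
    rx[[length(rx) + 1]] <- toy_rxn(sprintf("R%d", i), st)
  }
  rx[[length(rx) + 1]] <- toy_rxn("EX_B", stats::setNames(-1, mets[n_int + 1]))
  model <- metabolic_model(toy_mets(mets), dplyr::bind_rows(rx),
                           objective = c(EX_B = 1), name = sprintf("toy_chain_%d", size))
  truth <- list(
    kind = "chain",
    fva_ranges = tibble(
      reaction_id = c("EX_A", sprintf("R%d", seq_len(n_int)), "EX_B"),
      min_flux = c(-10, rep(0, n_int + 1)),
      max_flux = c(0, rep(10, n_int + 1))),
    fva_ranges_gamma1 = tibble(
      reaction_id = c("EX_A", sprintf("R%d", seq_len(n_int)), "EX_B"),
      min_flux = c(-10, rep(10, n_int + 1)),
      max_flux = c(-10, rep(10, n_int + 1))),
    coupled_flux = 10)
  list(model = model, truth = truth)
}

toy_branch <- function() {
  rx <- dplyr::bind_rows(
    toy_rxn("EX_A", c(A = -1), lb = -10, ub = -10),
    toy_rxn("AB", c(A = -1, B = 1)),
    toy_rxn("AC", c(A = -1, C = 1)),
    toy_rxn("EX_B", c(B = -1)),
    toy_rxn("EX_C", c(C = -1)))
  model <- metabolic_model(toy_mets(c("A", "B", "C")), rx,
                           objective = c(EX_B = 1), name = "toy_branch")
  truth <- list(
    kind = "branch",
    fva_ranges = tibble(
      reaction_id = c("EX_A", "AB", "AC", "EX_B", "EX_C"),
      min_flux = c(-10, 0, 0, 0, 0),
      max_flux = c(-10, 10, 10, 10, 10)),
    fva_ranges_gamma1 = tibble(
      reaction_id = c("EX_A", "AB", "AC", "EX_B", "EX_C"),
      min_flux = c(-10, 10, 0, 10, 0),
      max_flux = c(-10, 10, 0, 10, 0)))
  list(model = model, truth = truth)
}

toy_cycle <- function() {
  rx <- dplyr::bind_rows(
    toy_rxn("EX_A", c(A = -1), lb = -10, ub = 0),
    toy_rxn("R1", c(A = -1, B = 1), ub = 50),
    toy_rxn("R2", c(B = -1, C = 1), ub = 50),
    toy_rxn("R3", c(C = -1, A = 1), ub = 50),
    toy_rxn("EX_B", c(B = -1)))
  model <- metabolic_model(toy_mets(c("A", "B", "C")), rx,
                           objective = c(EX_B = 1), name = "toy_cycle")
  truth <- list(
    kind = "cycle",
    fva_ranges = tibble(
      reaction_id = c("EX_A", "R1", "R2", "R3", "EX_B"),
      min_flux = c(-10, 0, 0, 0, 0),
      max_flux = c(0, 50, 50, 50, 10)))
  list(model = model, truth = truth)
}

toy_simplex <- function(size) {
  if (size < 2) abort("simplex toys need size >= 2 parallel drains")
  rx <- list(toy_rxn("EX_A", c(A = -1), lb = -10, ub = -10))
  for (i in seq_len(size)) {
    rx[[length(rx) + 1]] <- toy_rxn(sprintf("V%d", i), c(A = -1))
  }
  model <- metabolic_model(toy_mets("A"), dplyr::bind_rows(rx),
                           name = sprintf("toy_simplex_%d", size))
  truth <- list(
    kind = "simplex", total = 10, k = size,
    fva_ranges = tibble(
      reaction_id = c("EX_A", sprintf("V%d", seq_len(size))),
      min_flux = c(-10, rep(0, size)),
      max_flux = c(-10, rep(10, size))))
  list(model = model, truth = truth)
}

toy_random <- function(size, seed) {
  if (size < 4) abort("random toys need size >= 4 reactions")
  set.seed(seed)
  n_met <- max(3, size %/% 2)
  m <- size - 1                              # one column reserved for the closer
  repeat {
    S <- matrix(sample(-2:2, n_met * m, replace = TRUE), n_met, m)
    if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)) break
  }
  vref <- round(runif(m, -3, 3), 3)
  closer <- -as.vector(S %*% vref)           # flux 1 through it restores balance
  if (all(abs(closer) < 1e-9)) closer[1] <- 1 # degenerate: give it substance
  S <- cbind(S, closer)
  vref <- c(vref, 1)
  mets <- sprintf("X%d", seq_len(n_met))
  rownames(S) <- mets
  rx <- lapply(seq_len(size), function(j) {
    st <- S[, j]; st <- st[st != 0]
    toy_rxn(sprintf("R%d", j), st,
            lb = vref[j] - round(runif(1, 0.5, 4), 3),
            ub = vref[j] + round(runif(1, 0.5, 4), 3))
  })
  model <- metabolic_model(toy_mets(mets), dplyr::bind_rows(rx),
                           name = sprintf("toy_random_%d_s%d", size, seed))
  list(model = model,
       truth = list(kind = "random", seed = seed,
                    reference_flux = stats::setNames(vref, sprintf("R%d", seq_len(size)))))
}

#' Specification of a paired cell-line scenario
#'
#' Parameters for [make_paired_scenario()] and [make_timecourses()]. The
#' defaults emulate a drug-sensitive, fast-growing, strongly Warburg-shifted
#' line "A" (doubling ~20 h, 80% of glycolytic pyruvate to lactate,
#' hypodiploid 44 chromosomes) paired with a resistant, slow-growing, more
#' oxidative line "B" (doubling ~46 h, 60% to lactate) carrying a planted
#' deleterious complex-I mutation.
#'
#' @param seed Integer seed (noise and any randomized pieces).
#' @param n_exchanges Number of exchange-constrained metabolites (glucose +
#'   lactate + `n_exchanges - 2` amino acids; default 21).
#' @param n_extra_reactions Inert internal reactions appended to enlarge the
#'   network (0 = the curated core only).
#' @param planted_enzymopathies Data frame `gene`, `reaction` of deleterious
#'   mutations planted in line B; every gene must impair its reaction's GPR.
#' @param growth_mu_a,growth_mu_b Specific growth rates (1/h).
#' @param warburg_a,warburg_b Fraction of glycolytic pyruvate routed to
#'   lactate in the planted reference flux.
#' @param noise_cv Multiplicative coefficient of variation for generated
#'   time courses (0 = noiseless).
#' @param exchange_band,growth_band Fractional tolerance bands used in the
#'   generated context specs.
#' @param atp_maintenance Maintenance flux (mmol/gDW/h).
#' @param chromosomes_a,chromosomes_b Chromosome counts entering the two
#'   biomass compositions (set equal to make the lines differ only in
#'   mutations and rates).
#' @param zero_rate_metabolites Extra metabolites reported in time courses
#'   with a planted rate of exactly zero (flat concentration series).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, n_exchanges = 21, n_extra_reactions = 0,
                          planted_enzymopathies = tibble(gene = "NDUFS1",
                                                         reaction = "ETC"),
                          growth_mu_a = 0.035, growth_mu_b = 0.015,
                          warburg_a = 0.8, warburg_b = 0.6,
                          noise_cv = 0, exchange_band = 0.05,
                          growth_band = 0.02, atp_maintenance = 1.07,
                          chromosomes_a = 44L, chromosomes_b = 46L,
                          zero_rate_metabolites = character()) {
  stopifnot(n_exchanges >= 3, noise_cv >= 0,
            warburg_a > 0, warburg_a < 1, warburg_b > 0, warburg_b < 1)
  structure(list(seed = as.integer(seed), n_exchanges = n_exchanges,
                 n_extra_reactions = n_extra_reactions,
                 planted_enzymopathies = as_tibble(planted_enzymopathies),
                 growth_mu_a = growth_mu_a, growth_mu_b = growth_mu_b,
                 warburg_a = warburg_a, warburg_b = warburg_b,
                 noise_cv = noise_cv, exchange_band = exchange_band,
                 growth_band = growth_band, atp_maintenance = atp_maintenance,
                 chromosomes_a = as.integer(chromosomes_a),
                 chromosomes_b = as.integer(chromosomes_b),
                 zero_rate_metabolites = zero_rate_metabolites),
            class = "scenario_spec")
}

# The curated core template: glycolysis, lactate fermentation, pyruvate
# oxidation, a lumped respiratory chain, ATP maintenance, macromolecule
# synthesis from glucose and amino acids, and the cofactor pools the redox
# probes need. Amino acids feed protein synthesis directly from the medium.
scenario_template <- function(spec) {
  n_aa <- spec$n_exchanges - 2
  aa_e <- sprintf("aa%02d_e", seq_len(n_aa))
  mets_e <- c("glc_e", "lac_e", "o2_e", aa_e)
  mets_c <- c("glc_c", "pyr_c", "lac_c", "o2_c", "atp_c", "adp_c",
              "nad_c", "nadh_c", "h_c", "h2_c", "h2o_c", "co2_c",
              "prot_c", "dna_c", "rna_c", "lip_c")
  mets <- dplyr::bind_rows(toy_mets(mets_e, "e"), toy_mets(mets_c, "c"))
  rx <- list(
    toy_rxn("EX_glc_e", c(glc_e = -1), lb = -1000, ub = 1000),
    toy_rxn("EX_lac_e", c(lac_e = -1), lb = -1000, ub = 1000),
    toy_rxn("EX_o2_e", c(o2_e = -1), lb = -1000, ub = 0),
    toy_rxn("GLCt", c(glc_e = -1, glc_c = 1), gpr = "SLC2A1", subsystem = "transport"),
    toy_rxn("GLYC", c(glc_c = -1, adp_c = -2, nad_c = -2,
                      pyr_c = 2, atp_c = 2, nadh_c = 2),
            gpr = "HK1 and GAPDH and PKM", subsystem = "glycolysis"),
    toy_rxn("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
            gpr = "LDHA or LDHB", subsystem = "glycolysis"),
    toy_rxn("LACt", c(lac_c = -1, lac_e = 1), subsystem = "transport"),
    toy_rxn("O2t", c(o2_e = -1, o2_c = 1), subsystem = "transport"),
    toy_rxn("TCA", c(pyr_c = -1, nad_c = -4, adp_c = -1,
                     nadh_c = 4, atp_c = 1, co2_c = 3),
            gpr = "PDHA1 and CS and IDH1", subsystem = "tca"),
    toy_rxn("ETC", c(nadh_c = -1, o2_c = -0.5, adp_c = -2.5,
                     nad_c = 1, atp_c = 2.5, h2o_c = 1),
            gpr = "NDUFS1 and SDHA and COX4I1", subsystem = "oxphos"),
    toy_rxn("ATPM", c(atp_c = -1, adp_c = 1), subsystem = "maintenance"),
    toy_rxn("DNAsyn", c(glc_c = -1, atp_c = -1, adp_c = 1, dna_c = 1),
            subsystem = "biosynthesis"),
    toy_rxn("RNAsyn", c(glc_c = -1, atp_c = -1, adp_c = 1, rna_c = 1),
            subsystem = "biosynthesis"),
    toy_rxn("LIPsyn", c(glc_c = -1, atp_c = -2, nadh_c = -2,
                        adp_c = 2, nad_c = 2, lip_c = 1),
            gpr = "FASN", subsystem = "biosynthesis"),
    toy_rxn("SINK_co2", c(co2_c = -1), subsystem = "sink"),
    toy_rxn("DM_h2o", c(h2o_c = -1), subsystem = "sink"),
    toy_rxn("SRC_h2", c(h2_c = 1), subsystem = "sink"),
    toy_rxn("DM_h", c(h_c = -1), subsystem = "sink")
  )
  for (a in aa_e) {
    rx[[length(rx) + 1]] <- toy_rxn(paste0("EX_", a), stats::setNames(-1, a),
                                    lb = -1000, ub = 1000)
  }
  prot_st <- c(stats::setNames(rep(-1 / n_aa, n_aa), aa_e),
               c(atp_c = -30, adp_c = 30, prot_c = 1))
  rx[[length(rx) + 1]] <- toy_rxn("PROTsyn", prot_st, gpr = "RPL3",
                                  subsystem = "biosynthesis")
  if (spec$n_extra_reactions > 0) {
    prev <- "co2_c"
    extra_mets <- character()
    for (k in seq_len(spec$n_extra_reactions)) {
      mid <- sprintf("dum%02d_c", k)
      extra_mets <- c(extra_mets, mid)
      rx[[length(rx) + 1]] <- toy_rxn(sprintf("DUMMY%02d", k),
                                      stats::setNames(c(-1, 1), c(prev, mid)),
                                      ub = 10, subsystem = "inert")
      prev <- mid
    }
    rx[[length(rx) + 1]] <- toy_rxn("DUMMY_SINK", stats::setNames(-1, prev),
                                    ub = 10, subsystem = "inert")
    mets <- dplyr::bind_rows(mets, toy_mets(extra_mets, "c"))
  }
  metabolic_model(mets, dplyr::bind_rows(rx), name = "paired_template")
}

# closed-form reference flux for one cell line of the scenario; the
# generator solves the steady-state balances analytically so the truth
# record never depends on the LP machinery it is used to test
scenario_reference_flux <- function(spec, mu, phi, composition) {
  s_p <- composition$protein_fraction * mu
  s_d <- composition$dna_fraction * mu
  s_r <- composition$rna_fraction * mu
  s_l <- composition$lipid_fraction * mu
  M <- spec$atp_maintenance
  rhs <- M + 30 * s_p + s_d + s_r + 2 * s_l
  g <- (rhs + 5 * s_l) / (29 - 27 * phi)
  l <- 2 * g * phi
  tca <- 2 * g * (1 - phi)
  e <- 10 * g * (1 - phi) - 2 * s_l
  stopifnot(g > 0, l > 0, tca > 0, e > 0)
  u_glc <- g + s_d + s_r + s_l
  n_aa <- spec$n_exchanges - 2
  flux <- c(
    EX_glc_e = -u_glc, GLCt = u_glc, GLYC = g, LDH = l, LACt = l,
    EX_lac_e = l, TCA = tca, ETC = e, O2t = 0.5 * e, EX_o2_e = -0.5 * e,
    ATPM = M, PROTsyn = s_p, DNAsyn = s_d, RNAsyn = s_r, LIPsyn = s_l,
    SINK_co2 = 3 * tca, DM_h2o = e, SRC_h2 = 0, DM_h = 0, BIOMASS = mu
  )
  aa_flux <- stats::setNames(rep(-s_p / n_aa, n_aa),
                             sprintf("EX_aa%02d_e", seq_len(n_aa)))
  c(flux, aa_flux)
}

#' Generate a paired two-cell-line scenario
#'
#' Builds the shared template network plus a [context_spec()] per cell line
#' (differing in growth rate, exchange rates derived from a closed-form
#' reference flux, and planted deleterious mutations in line B), together
#' with a ground-truth record: the two reference flux vectors, the planted
#' exchange-rate tables, the reactions whose spans must contract (including
#' `coupled_contracted`, the reactions stoichiometrically forced to contract
#' with a lesion when the redox probes are disabled), and the reference
#' oxygen uptake of each line. The truth record is computed analytically
#' from the steady-state balances, independently of any LP solve.
#'
#' @param spec A [scenario_spec()].
#' @return List `template`, `spec_a`, `spec_b`, `truth`.
#' @export
make_paired_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  template <- scenario_template(spec)
  # planted genes must exist in, and individually impair, their reactions
  pe <- spec$planted_enzymopathies
  for (i in seq_len(nrow(pe))) {
    j <- match(pe$reaction[i], template$reactions$id)
    if (is.na(j)) abort(sprintf("planted reaction '%s' not in template", pe$reaction[i]))
    rule <- template$reactions$gpr[j]
    if (!pe$gene[i] %in% gpr_genes(rule)) {
      abort(sprintf("planted gene '%s' absent from GPR of '%s' ('%s')",
                    pe$gene[i], pe$reaction[i], rule))
    }
    if (gpr_active(rule, inactive_genes = pe$gene[i])) {
      abort(sprintf("planted gene '%s' does not impair '%s' (isozyme backup in '%s')",
                    pe$gene[i], pe$reaction[i], rule))
    }
  }
  comp_a <- biomass_composition(chromosome_count = spec$chromosomes_a)
  comp_b <- biomass_composition(chromosome_count = spec$chromosomes_b)
  vref_a <- scenario_reference_flux(spec, spec$growth_mu_a, spec$warburg_a, comp_a)
  vref_b <- scenario_reference_flux(spec, spec$growth_mu_b, spec$warburg_b, comp_b)
  rate_table <- function(vref) {
    ex <- grep("^EX_(glc|lac|aa)", names(vref), value = TRUE)
    mets <- sub("^EX_", "", ex)
    tibble(metabolite = mets, rate = unname(vref[ex]),
           tolerance_band = spec$exchange_band)
  }
  mut_a <- tibble(gene = "LDHB", variant_label = "p.R46C",
                  deleterious_probability = 0.30)
  mut_b <- dplyr::bind_rows(
    tibble(gene = pe$gene, variant_label = sprintf("planted_%s", pe$gene),
           deleterious_probability = 0.998),
    tibble(gene = "LDHA", variant_label = "p.A12T", deleterious_probability = 0.10))
  mk_spec <- function(name, comp, mu, vref, mut) {
    context_spec(cell_line_name = name, biomass = comp,
                 exchanges = rate_table(vref), growth_rate = mu,
                 mutations = mut, atp_maintenance = spec$atp_maintenance,
                 our_cap_mode = "fba_max", add_pseudo_hypoxia = TRUE,
                 add_nadh_oxidase = TRUE, growth_band = spec$growth_band)
  }
  # reactions stoichiometrically forced to move 1:1 with a planted lesion
  # (their rechecked spans contract by the same factor as the lesion itself)
  coupled_map <- list(
    ETC = c("O2t", "EX_o2_e", "DM_h2o"),
    LDH = c("LACt", "EX_lac_e"),
    TCA = "SINK_co2")
  coupled <- unique(unlist(coupled_map[intersect(pe$reaction, names(coupled_map))]))
  truth <- list(
    seed = spec$seed,
    reference_flux_a = vref_a, reference_flux_b = vref_b,
    rates_a = rate_table(vref_a), rates_b = rate_table(vref_b),
    contracted_expected = pe$reaction,
    coupled_contracted = coupled,
    our_a = -unname(vref_a["EX_o2_e"]), our_b = -unname(vref_b["EX_o2_e"]),
    growth_mu_a = spec$growth_mu_a, growth_mu_b = spec$growth_mu_b)
  list(template = template,
       spec_a = mk_spec("cellline_A", comp_a, spec$growth_mu_a, vref_a, mut_a),
       spec_b = mk_spec("cellline_B", comp_b, spec$growth_mu_b, vref_b, mut_b),
       truth = truth)
}

#' Generate growth curves and concentration time courses
#'
#' Emulates the sampling design of the wet experiment: cell counts and
#' extracellular concentrations at 24-h intervals from 0 to 96 h (5 points)
#' for both cell lines, with optional multiplicative noise. Counts follow a
#' Gompertz curve (inoculum 1e4 cells, carrying capacity 1.2e6); each
#' metabolite concentration integrates its planted specific rate against the
#' growth curve (`dC/dt = rate * X(t) / V`). Initial concentrations of
#' consumed metabolites are set to 1.3x the 96-h drawdown - media formulated
#' near demand, so the concentration change is well above measurement noise
#' and nothing goes negative.
#'
#' @param spec A [scenario_spec()]; `spec$noise_cv` controls the noise.
#' @param culture_volume Liters (default 0.5 mL assay volume).
#' @param dry_weight_per_cell gDW per cell (default 400 pg).
#' @return List `growth` (tibble `cell_line`, `time_h`, `count`),
#'   `concentrations` (tibble `cell_line`, `metabolite`, `time_h`,
#'   `concentration`) and `truth` (planted growth parameters and rates).
#' @export
make_timecourses <- function(spec = scenario_spec(), culture_volume = 5e-4,
                             dry_weight_per_cell = 4e-10) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  scen <- make_paired_scenario(spec)
  times <- seq(0, 96, by = 24)
  n0 <- 1e4; K <- 1.2e6
  gomp <- function(mu, tt) K * exp(log(n0 / K) * exp(-mu * tt))
  gomp_integral <- function(mu, upper) {
    stats::integrate(function(s) gomp(mu, s), 0, upper, rel.tol = 1e-10)$value
  }
  noisy <- function(x) {
    if (spec$noise_cv == 0) return(x)
    pmax(x * (1 + spec$noise_cv * rnorm(length(x))), 0)
  }
  one_line <- function(line, mu, rates) {
    counts <- gomp(mu, times)
    growth <- tibble(cell_line = line, time_h = times, count = noisy(counts))
    rates <- dplyr::bind_rows(
      rates[, c("metabolite", "rate")],
      tibble(metabolite = spec$zero_rate_metabolites, rate = 0))
    conc <- lapply(seq_len(nrow(rates)), function(i) {
      r <- rates$rate[i]
      cum <- vapply(times, function(tt) gomp_integral(mu, tt), numeric(1))
      delta <- r * dry_weight_per_cell * cum / culture_volume
      c0 <- max(default_c0(rates$metabolite[i]), 1.3 * max(0, -min(delta)))
      tibble(cell_line = line, metabolite = rates$metabolite[i],
             time_h = times, concentration = noisy(c0 + delta))
    })
    list(growth = growth, conc = dplyr::bind_rows(conc))
  }
  a <- one_line("cellline_A", spec$growth_mu_a, scen$truth$rates_a)
  b <- one_line("cellline_B", spec$growth_mu_b, scen$truth$rates_b)
  list(growth = dplyr::bind_rows(a$growth, b$growth),
       concentrations = dplyr::bind_rows(a$conc, b$conc),
       truth = list(n0 = n0, carrying_capacity = K,
                    growth_mu_a = spec$growth_mu_a, growth_mu_b = spec$growth_mu_b,
                    rates_a = scen$truth$rates_a, rates_b = scen$truth$rates_b,
                    culture_volume = culture_volume,
                    dry_weight_per_cell = dry_weight_per_cell,
                    times = times, noise_cv = spec$noise_cv))
}

default_c0 <- function(metabolite) {
  if (grepl("^lac", metabolite)) 1 else 0.05
}
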