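test_that("biomass composition enforces its invariants and ploidy scaling", {
  comp <- biomass_composition()
  expect_equal(comp$protein_fraction, 0.70)
  expect_equal(comp$protein_fraction + comp$dna_fraction + comp$rna_fraction +
                 comp$lipid_fraction, 1, tolerance = 1e-12)
  expect_error(biomass_composition(protein = 0.8), "sum to 1")
  # 44 chromosomes: DNA fraction scales by 44/46, RNA+lipid absorb the rest
  c44 <- biomass_composition(chromosome_count = 44L)
  expect_equal(c44$dna_fraction, 0.02 * 44 / 46, tolerance = 1e-12)
  expect_equal(c44$protein_fraction, 0.70)
  spare <- 1 - 0.70 - 0.02 * 44 / 46
  expect_equal(c44$rna_fraction, spare * 0.08 / 0.28, tolerance = 1e-12)
  expect_equal(c44$lipid_fraction, spare * 0.20 / 0.28, tolerance = 1e-12)
  expect_equal(c44$protein_fraction + c44$dna_fraction + c44$rna_fraction +
                 c44$lipid_fraction, 1, tolerance = 1e-12)
})

test_that("biomass reactions carry the composition as precursor coefficients", {
  scen <- make_paired_scenario(scenario_spec())
  comp <- biomass_composition()
  br <- build_biomass(comp, scen$template)
  expect_equal(unname(br$stoichiometry["prot_c"]), -0.70)
  expect_equal(sum(br$stoichiometry), -1, tolerance = 1e-12)
  # linearity: doubling a fraction doubles the coefficient
  comp2 <- biomass_composition(protein = 0.35, dna = 0.01, rna = 0.04,
                               lipid = 0.60)
  br2 <- build_biomass(comp2, scen$template)
  expect_equal(br2$stoichiometry["prot_c"] / br$stoichiometry["prot_c"],
               c(prot_c = 0.5))
  expect_error(build_biomass(comp, make_toy_network("branch")$model),
               "prot_c")
})

test_that("exchange constraints re-bound exactly the named exchanges", {
  scen <- make_paired_scenario(scenario_spec())
  m <- scen$template
  tab <- scen$spec_a$exchanges
  expect_equal(nrow(tab), 21)
  m2 <- apply_exchange_constraints(m, tab)
  expect_equal(attr(m2, "n_rebounded"), 21)
  # glucose with zero band is pinned exactly
  tab0 <- tibble::tibble(metabolite = "glc_e", rate = -0.5, tolerance_band = 0)
  m3 <- apply_exchange_constraints(m, tab0)
  j <- match("EX_glc_e", m3$reactions$id)
  expect_equal(m3$reactions$lower_bound[j], -0.5)
  expect_equal(m3$reactions$upper_bound[j], -0.5)
  # empty table: unchanged model
  expect_identical(apply_exchange_constraints(m, tab[0, ]), m)
  # unknown metabolite: error listing it
  expect_error(apply_exchange_constraints(
    m, tibble::tibble(metabolite = c("glc_e", "mystery_e"), rate = -1)),
    "mystery_e")
  # other exchanges untouched
  others <- setdiff(find_exchanges(m), "EX_glc_e")
  for (id in others) {
    expect_equal(m3$reactions$lower_bound[match(id, m3$reactions$id)],
                 m$reactions$lower_bound[match(id, m$reactions$id)])
  }
})

test_that("enzymopathy contraction applies the quarter-width rule exactly", {
  scen <- make_paired_scenario(scenario_spec())
  m <- scen$template
  fake_fva <- structure(
    tibble::tibble(reaction_id = c("ETC", "LDH"),
                   min_flux = c(-10, 0), max_flux = c(10, 8), status = "ok"),
    class = c("fva_result", "tbl_df", "tbl", "data.frame"))
  muts <- tibble::tibble(gene = c("NDUFS1", "LDHA"),
                         deleterious_probability = c(0.998, 0.999))
  m2 <- expect_silent(apply_enzymopathies(m, muts, fake_fva))
  # complex subunit (and-rule): impaired; range (-10, 10) -> upper bound -5
  j <- match("ETC", m2$reactions$id)
  expect_equal(m2$reactions$upper_bound[j], -5)
  expect_equal(m2$reactions$lower_bound[j], -10)
  # isozyme (or-rule): LDHA alone does not impair LDH
  k <- match("LDH", m2$reactions$id)
  expect_equal(m2$reactions$upper_bound[k],
               m$reactions$upper_bound[match("LDH", m$reactions$id)])
  expect_equal(attr(m2, "contracted_reactions"), "ETC")
  # range (0, 8) -> new upper bound 2 when both isozymes are lost
  muts2 <- tibble::tibble(gene = c("LDHA", "LDHB"),
                          deleterious_probability = c(0.99, 0.99))
  m3 <- apply_enzymopathies(m, muts2, fake_fva)
  expect_equal(m3$reactions$upper_bound[match("LDH", m3$reactions$id)], 2)
  # benign probabilities below threshold do nothing
  m4 <- apply_enzymopathies(m, tibble::tibble(gene = "NDUFS1",
                                              deleterious_probability = 0.5),
                            fake_fva)
  expect_equal(attr(m4, "contracted_reactions"), character())
  # non-metabolic gene: warning, not error
  expect_warning(
    apply_enzymopathies(m, tibble::tibble(gene = "TP53",
                                          deleterious_probability = 0.99),
                        fake_fva),
    "TP53")
  # symmetric mode keeps the middle quarter
  m5 <- apply_enzymopathies(m, muts, fake_fva, mode = "symmetric")
  j5 <- match("ETC", m5$reactions$id)
  expect_equal(m5$reactions$lower_bound[j5], -2.5)
  expect_equal(m5$reactions$upper_bound[j5], 2.5)
})

test_that("a planted enzymopathy contracts the rechecked FVA span to the factor", {
  scen <- make_paired_scenario(scenario_spec())
  spec_b0 <- scen$spec_b
  spec_b0$mutations <- NULL
  mb_parent <- contextualize_cell_line(scen$template, spec_b0)
  mb <- contextualize_cell_line(scen$template, scen$spec_b)
  expect_equal(attr(mb, "contracted_reactions"), "ETC")
  cmp <- compare_spans(fva(mb_parent, gamma = 0), fva(mb, gamma = 0))
  expect_equal(cmp$span_ratio[cmp$reaction_id == "ETC"], 0.25, tolerance = 1e-6)
})

test_that("probe reactions carry the printed stoichiometries", {
  scen <- make_paired_scenario(scenario_spec())
  m <- add_probe_reactions(scen$template, pseudo_hypoxia = TRUE,
                           nadh_oxidase = TRUE)
  st <- m$reactions$stoichiometry[[match("PSEUDO_HYPOXIA", m$reactions$id)]]
  expect_equal(st[c("nad_c", "h2_c", "nadh_c", "h_c")],
               c(nad_c = -1, h2_c = -1, nadh_c = 1, h_c = 1))
  ox <- m$reactions$stoichiometry[[match("NADH_OXIDASE", m$reactions$id)]]
  expect_equal(ox[c("nadh_c", "h_c", "o2_c", "nad_c", "h2o_c")],
               c(nadh_c = -1, h_c = -1, o2_c = -0.5, nad_c = 1, h2o_c = 1))
  # added capacity cannot remove feasibility
  probe_sol <- solve_lp(rep(0, nrow(m$reactions)), stoich_matrix(m),
                        m$reactions$lower_bound, m$reactions$upper_bound)
  expect_equal(probe_sol$status, "optimal")
  expect_error(add_probe_reactions(make_toy_network("branch")$model),
               "cofactor")
})

test_that("contextualization fixes maintenance, hits the growth rate, and stages errors", {
  scen <- make_paired_scenario(scenario_spec())
  ma <- contextualize_cell_line(scen$template, scen$spec_a)
  j <- match("ATPM", ma$reactions$id)
  expect_equal(ma$reactions$lower_bound[j], 1.07)
  expect_equal(ma$reactions$upper_bound[j], 1.07)
  fa <- fba(ma)
  expect_equal(fa$status, "optimal")
  band <- scen$spec_a$growth_band
  mu <- scen$spec_a$growth_rate
  expect_gte(fa$objective_value, mu * (1 - band) - 1e-9)
  expect_lte(fa$objective_value, mu * (1 + band) + 1e-9)
  # the reference flux from the truth record is feasible in the built model
  vref <- scen$truth$reference_flux_a
  S <- stoich_matrix(ma)
  v <- stats::setNames(rep(0, nrow(ma$reactions)), ma$reactions$id)
  v[names(vref)] <- vref
  expect_lt(max(abs(S %*% v)), 1e-9)
  # an impossible exchange table fails at the named stage
  bad_spec <- scen$spec_a
  bad_spec$exchanges$rate[1] <- -500     # glucose uptake beyond any supply
  bad_spec$exchanges$tolerance_band <- 0
  expect_error(contextualize_cell_line(scen$template, bad_spec),
               "exchange_constraints|growth_rate")
})

test_that("a closed, zero-growth spec yields the all-zero feasible model", {
  scen <- make_paired_scenario(scenario_spec())
  closed <- scen$spec_a
  closed$exchanges$rate <- 0
  closed$exchanges$tolerance_band <- 0
  closed$growth_rate <- 0
  closed$atp_maintenance <- 0
  closed$mutations <- NULL
  closed$add_pseudo_hypoxia <- FALSE
  closed$add_nadh_oxidase <- FALSE
  m <- contextualize_cell_line(scen$template, closed)
  f <- fba(m)
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 0, tolerance = 1e-9)
})

test_that("the sensitive-like line re-oxidizes more NADH and respires more", {
  scen <- make_paired_scenario(scenario_spec())
  ma <- contextualize_cell_line(scen$template, scen$spec_a)
  mb <- contextualize_cell_line(scen$template, scen$spec_b)
  # maximal oxygen uptake: resistant-like line is lower (planted lower
  # respiratory capacity plus complex-I enzymopathy)
  our_a <- maximal_exchange(ma, "EX_o2_e", "uptake")
  our_b <- maximal_exchange(mb, "EX_o2_e", "uptake")
  expect_lt(our_b, our_a)
  # NADH-oxidase probe flux: higher capacity in the high-glycolysis line
  probe_max <- function(m) {
    f <- fba(m, objective = c(NADH_OXIDASE = 1))
    f$objective_value
  }
  expect_gt(probe_max(ma), probe_max(mb))
})

test_that("leave-one-out FBA predicts the planted uptake rates", {
  scen <- make_paired_scenario(scenario_spec())
  acc <- predict_uptake_rates(scen$template, scen$spec_a)
  expect_equal(nrow(acc), 20)           # glucose + 19 amino acids
  expect_true(all(acc$accuracy > 99))
  expect_equal(acc$predicted, acc$measured, tolerance = 1e-6)
})
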