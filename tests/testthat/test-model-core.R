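toy3 <- function() {
  metabolic_model(
    tibble::tibble(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    dplyr::bind_rows(
      tibble::tibble(id = "EX_A", stoichiometry = list(c(A = -1)),
                     lower_bound = -10, upper_bound = 0, gpr = ""),
      tibble::tibble(id = "R1", stoichiometry = list(c(A = -1, B = 1)),
                     lower_bound = 0, upper_bound = 1000, gpr = ""),
      tibble::tibble(id = "EX_B", stoichiometry = list(c(B = -1)),
                     lower_bound = 0, upper_bound = 1000, gpr = "")),
    objective = c(EX_B = 1), name = "toy3")
}

test_that("a well-formed model validates cleanly and reports its structure", {
  m <- toy3()
  expect_equal(nrow(validate_model(m)), 0)
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 3)
  expect_equal(length(m$objective), 1)
  expect_equal(find_exchanges(m), c("EX_A", "EX_B"))
  g <- glance(m)
  expect_equal(g$n_exchanges, 2)
})

test_that("structural violations are reported as data, construction refuses them", {
  m <- toy3()
  # dangling metabolite reference
  bad <- m
  bad$reactions$stoichiometry[[2]] <- c(A = -1, X = 1)
  v <- validate_model(bad)
  expect_true(any(v$rule == "metabolite_resolves"))
  expect_true(any(grepl("X", v$message)))
  expect_error(metabolic_model(bad$metabolites, bad$reactions), "X")
  # inverted bounds
  bad2 <- m
  bad2$reactions$lower_bound[2] <- 5
  bad2$reactions$upper_bound[2] <- 1
  v2 <- validate_model(bad2)
  expect_true(any(v2$rule == "bounds_ordered" & v2$entity == "R1"))
  # validate_model is pure
  before <- m
  invisible(validate_model(m))
  expect_identical(m, before)
})

test_that("models with no single-metabolite reactions have no exchanges", {
  m <- metabolic_model(
    tibble::tibble(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    tibble::tibble(id = "R1", stoichiometry = list(c(A = -1, B = 1)),
                   lower_bound = -10, upper_bound = 10, gpr = ""))
  expect_equal(find_exchanges(m), character())
})

test_that("add_reaction appends a column, copies, and refuses duplicates", {
  m <- toy3()
  m2 <- add_reaction(m, "PSEUDO_HYPOXIA",
                     c(nad_c = -1, h2_c = -1, nadh_c = 1, h_c = 1),
                     new_metabolites = tibble::tibble(
                       id = c("nad_c", "h2_c", "nadh_c", "h_c"),
                       compartment = "c"))
  expect_equal(nrow(m2$reactions), 4)
  expect_equal(nrow(m$reactions), 3)  # original untouched
  st <- m2$reactions$stoichiometry[[match("PSEUDO_HYPOXIA", m2$reactions$id)]]
  expect_equal(st[c("nad_c", "h2_c", "nadh_c", "h_c")],
               c(nad_c = -1, h2_c = -1, nadh_c = 1, h_c = 1))
  # pre-existing columns bit-identical
  expect_identical(m2$reactions$stoichiometry[1:3], m$reactions$stoichiometry)
  expect_error(add_reaction(m, "R1", c(A = 1)), "already present")
  # feasibility is preserved when capacity is added
  expect_equal(fba(m2)$status, "optimal")
})

test_that("JSON round-trip preserves stoichiometry, bounds, GPR and objective", {
  scen <- make_paired_scenario(scenario_spec())
  m <- scen$template
  path <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(m, path)
  m2 <- read_metabolic_model(path)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$gpr, m$reactions$gpr)
  expect_equal(m2$objective, m$objective)
  for (j in seq_len(nrow(m$reactions))) {
    a <- m$reactions$stoichiometry[[j]]
    b <- m2$reactions$stoichiometry[[j]]
    expect_equal(b[names(a)], a)
  }
})

test_that("TSV round-trip preserves the model", {
  m <- make_toy_network("branch")$model
  dir <- withr::local_tempdir()
  write_metabolic_model(m, dir, format = "tsv")
  m2 <- read_metabolic_model(dir)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$objective, m$objective)
  S1 <- stoich_matrix(m); S2 <- stoich_matrix(m2)
  expect_equal(S2[rownames(S1), colnames(S1)], S1)
})

test_that("COBRA-dialect JSON import matches an independent reader", {
  path <- system.file("extdata", "mini_core_synthetic.json", package = "gbmflux")
  m <- read_metabolic_model(path, format = "json")
  raw <- jsonlite::read_json(path)   # independent parse of the same file
  expect_equal(nrow(m$metabolites), length(raw$metabolites))
  expect_equal(nrow(m$reactions), length(raw$reactions))
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(length(raw$metabolites), length(raw$reactions)))
  for (r in raw$reactions) {
    j <- match(r$id, m$reactions$id)
    expect_equal(m$reactions$lower_bound[j], r$lower_bound)
    expect_equal(m$reactions$upper_bound[j], r$upper_bound)
    for (met in names(r$metabolites)) {
      expect_equal(S[met, j], r$metabolites[[met]])
    }
  }
  expect_equal(m$objective, c(EX_lac__L_e = 1))
  # and the imported model is solvable: lactate export limited by uptake
  expect_equal(fba(m)$objective_value, 20, tolerance = 1e-9)
})

test_that("JSON with a dangling metabolite reference raises a naming error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id":"bad","metabolites":[{"id":"A","compartment":"c"}],
    "reactions":[{"id":"R1","metabolites":{"A":-1,"X":1},
    "lower_bound":0,"upper_bound":10}]}', path)
  expect_error(read_metabolic_model(path), "X")
})

test_that("SBML level-3 FBC import recovers species, bounds, GPR and objective", {
  path <- system.file("extdata", "mini_chain_synthetic.xml", package = "gbmflux")
  m <- read_metabolic_model(path, format = "sbml")
  expect_equal(nrow(m$metabolites), 3)
  expect_equal(sort(m$reactions$id), c("At", "AtoB", "EX_A", "EX_B"))
  j <- match("EX_A", m$reactions$id)
  expect_equal(m$reactions$lower_bound[j], -10)
  expect_equal(m$reactions$upper_bound[j], 0)
  expect_equal(sort(gpr_genes(m$reactions$gpr[match("At", m$reactions$id)])),
               c("G1", "G2"))
  expect_equal(m$objective, c(EX_B = 1))
  expect_equal(fba(m)$objective_value, 10, tolerance = 1e-9)
})

test_that("GPR rules evaluate complexes and isozymes correctly", {
  expect_true(gpr_active("", "anything"))
  expect_false(gpr_active("NDUFS1 and SDHA", "NDUFS1"))
  expect_true(gpr_active("LDHA or LDHB", "LDHB"))
  expect_false(gpr_active("LDHA or LDHB", c("LDHA", "LDHB")))
  expect_true(gpr_active("(A and B) or C", c("A")))
  expect_false(gpr_active("(A and B) or C", c("A", "C")))
  expect_equal(sort(gpr_genes("(A and B) or C")), c("A", "B", "C"))
  expect_equal(gpr_genes(""), character())
})
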