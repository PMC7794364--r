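test_that("warmup points are feasible, distinct where possible, and span vertices", {
  # pinned polytope: every warmup point carries the forced conversion flux
  ch <- make_toy_network("chain", 3)$model
  ch <- set_bounds(ch, "EX_A", lower_bound = -10, upper_bound = -10)
  w <- generate_warmup(ch, sampler_config(n_warmup = 8, seed = 1))
  expect_equal(nrow(w$matrix), 8)
  expect_true(all(abs(w$matrix[, "R1"] - 10) < 1e-7))
  # two free dimensions: distinct rows
  sx <- make_toy_network("simplex", 3)$model
  w2 <- generate_warmup(sx, sampler_config(n_warmup = 4, seed = 2))
  expect_equal(nrow(unique(round(w2$matrix, 9))), 4)
  # triangle polytope: all three vertices present, so the convex hull of the
  # warmup cloud contains the analytic centroid (10/3, 10/3, 10/3)
  w3 <- generate_warmup(sx, sampler_config(n_warmup = 10, seed = 3))
  V <- w3$matrix[, c("V1", "V2", "V3")]
  for (vertex in list(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))) {
    expect_true(any(apply(V, 1, function(r) max(abs(r - vertex)) < 1e-7)))
  }
  # interior fill points satisfy the simplex equation too
  expect_true(all(abs(rowSums(V) - 10) < 1e-7))
  # infeasible model refuses before sampling
  bad <- set_bounds(make_toy_network("chain", 3)$model, "EX_A",
                    lower_bound = -10, upper_bound = -5)
  bad <- set_bounds(bad, "R1", upper_bound = 1)
  expect_error(generate_warmup(bad), "infeasible")
})

test_that("hit-and-run samples are uniform on analytic polytopes", {
  # 1-d interval: a free reaction in [0, 1]
  m <- metabolic_model(
    tibble::tibble(id = "A", name = "A", compartment = "c"),
    dplyr::bind_rows(
      tibble::tibble(id = "SRC", stoichiometry = list(c(A = 1)),
                     lower_bound = 0, upper_bound = 1, gpr = ""),
      tibble::tibble(id = "SNK", stoichiometry = list(c(A = -1)),
                     lower_bound = 0, upper_bound = 1000, gpr = "")),
    name = "interval")
  s <- achr_sample(m, config = sampler_config(n_warmup = 10, n_samples = 5000,
                                              thinning = 2, seed = 4))
  expect_equal(mean(s$matrix[, "SRC"]), 0.5, tolerance = 0.02)
  # segment v1 + v2 = 10: P(v1 < 2.5) = 0.25
  sx <- make_toy_network("simplex", 2)$model
  s2 <- achr_sample(sx, config = sampler_config(n_warmup = 10, n_samples = 10000,
                                                thinning = 2, seed = 5))
  expect_equal(mean(s2$matrix[, "V1"] < 2.5), 0.25, tolerance = 0.02)
  # pinned coordinate stays exactly pinned
  ch <- set_bounds(make_toy_network("chain", 3)$model, "EX_A",
                   lower_bound = -10, upper_bound = -10)
  s3 <- achr_sample(ch, config = sampler_config(n_warmup = 6, n_samples = 200,
                                                thinning = 5, seed = 6))
  expect_true(all(abs(s3$matrix[, "R1"] - 10) < 1e-6))
})

test_that("every stored sample is feasible and runs are bit-reproducible", {
  scen <- make_paired_scenario(scenario_spec())
  m <- contextualize_cell_line(scen$template, scen$spec_a)
  cfg <- sampler_config(n_warmup = 60, n_samples = 400, thinning = 20, seed = 7)
  s <- achr_sample(m, config = cfg)
  # hard feasibility: the constructor asserts, re-check here explicitly
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% t(s$matrix))), 1e-6)
  expect_true(all(t(s$matrix) >= m$reactions$lower_bound - 1e-6))
  expect_true(all(t(s$matrix) <= m$reactions$upper_bound + 1e-6))
  s2 <- achr_sample(m, config = cfg)
  expect_identical(s$matrix, s2$matrix)
  # a different seed gives a different chain
  cfg3 <- cfg; cfg3$seed <- 8L
  expect_false(identical(achr_sample(m, config = cfg3)$matrix, s$matrix))
})

test_that("sampled ranges stay inside and converge toward FVA ranges", {
  sx <- make_toy_network("simplex", 3)$model
  v <- fva(sx, gamma = 0)
  s <- achr_sample(sx, config = sampler_config(n_warmup = 12, n_samples = 10000,
                                               thinning = 2, seed = 9))
  for (j in seq_len(nrow(v))) {
    id <- v$reaction_id[j]
    lo <- min(s$matrix[, id]); hi <- max(s$matrix[, id])
    expect_gte(lo, v$min_flux[j] - 1e-6)
    expect_lte(hi, v$max_flux[j] + 1e-6)
    width <- v$max_flux[j] - v$min_flux[j]
    if (width > 1e-6) expect_gte((hi - lo) / width, 0.9)
  }
})

test_that("flux histograms partition the samples", {
  sx <- make_toy_network("simplex", 2)$model
  s <- achr_sample(sx, config = sampler_config(n_warmup = 10, n_samples = 10000,
                                               thinning = 2, seed = 10))
  h <- flux_histograms(s, bins = 10)
  counts <- dplyr::summarise(dplyr::group_by(h, reaction_id),
                             total = sum(count), nbin = dplyr::n())
  expect_true(all(counts$total == 10000))
  # constant reaction occupies one bin
  expect_equal(counts$nbin[counts$reaction_id == "EX_A"], 1)
  # uniform coordinate: each of 10 bins holds 1000 +/- 150 (binomial, ~5 sigma)
  hv1 <- h[h$reaction_id == "V1", ]
  expect_equal(nrow(hv1), 10)
  expect_true(all(abs(hv1$count - 1000) <= 150))
  expect_error(flux_histograms(s, bins = 1e6), "samples")
})

test_that("correlated sets recover coupling signs and match a brute-force scan", {
  b <- make_toy_network("branch")$model
  s <- achr_sample(b, config = sampler_config(n_warmup = 10, n_samples = 1500,
                                              thinning = 5, seed = 11))
  cs <- correlated_sets(s, r_threshold = 0.99)
  # series coupling: AB and EX_B move identically (r = +1)
  e1 <- cs$edges[cs$edges$from == "AB" & cs$edges$to == "EX_B" |
                   cs$edges$from == "EX_B" & cs$edges$to == "AB", ]
  expect_equal(nrow(e1), 1)
  expect_equal(e1$r, 1, tolerance = 1e-9)
  # parallel routes splitting a fixed input: r = -1
  e2 <- cs$edges[(cs$edges$from == "AB" & cs$edges$to == "AC") |
                   (cs$edges$from == "AC" & cs$edges$to == "AB"), ]
  expect_equal(e2$r, -1, tolerance = 1e-9)
  # constant-flux EX_A excluded
  expect_false("EX_A" %in% cs$sets$reaction_id)
  # brute-force oracle: exhaustive pairwise correlations give the same sets
  M <- s$matrix[, apply(s$matrix, 2, sd) > 1e-10]
  R <- cor(M)
  adj <- abs(R) >= 0.99
  grp <- seq_len(ncol(M))          # naive union-find by repeated sweeps
  repeat {
    changed <- FALSE
    for (i in seq_len(ncol(M))) for (j in seq_len(ncol(M))) {
      if (adj[i, j] && grp[j] != grp[i]) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  want <- split(colnames(M), grp)
  want <- lapply(want[lengths(want) >= 2], sort)
  got <- split(cs$sets$reaction_id, cs$sets$set_id)
  got <- lapply(got, sort)
  expect_setequal(unname(lapply(want, paste, collapse = ",")),
                  unname(lapply(got, paste, collapse = ",")))
  expect_error(correlated_sets(s, r_threshold = 0), "r_threshold")
})
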