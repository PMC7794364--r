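# Independent LP oracle built on pracma::linprog (a pure-R Big-M simplex,
# entirely separate from the package's compiled backend). Variables are
# shifted to x = v - lb >= 0 so the oracle also exercises a different
# formulation of the same problem.
oracle_lp <- function(obj, S, lb, ub, A = NULL, rhs = NULL, maximize = TRUE) {
  n <- length(obj)
  Ain <- rbind(diag(n), A)
  bin <- c(ub - lb, if (is.null(A)) NULL else rhs - as.vector(A %*% lb))
  beq <- as.vector(-S %*% lb)
  out <- tryCatch(
    pracma::linprog(obj, A = Ain, b = bin, Aeq = S, beq = beq,
                    maximize = maximize, maxiter = 5000),
    error = function(e) NULL)
  if (is.null(out) || out$errno != 1) {
    return(list(status = "failed", flux = NULL, objective = NA_real_))
  }
  list(status = "optimal", flux = out$x + lb,
       objective = sum(obj * (out$x + lb)))
}

# per-reaction min/max by the oracle: the brute-force FVA reference
oracle_fva <- function(model, gamma = 0) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  A <- NULL; rhs <- NULL
  if (gamma > 0) {
    cvec <- rep(0, ncol(S))
    cvec[match(names(model$objective), model$reactions$id)] <- model$objective
    z0 <- oracle_lp(cvec, S, lb, ub, maximize = TRUE)$objective
    A <- matrix(-cvec, nrow = 1); rhs <- -gamma * z0
  }
  n <- ncol(S)
  do.call(rbind, lapply(seq_len(n), function(j) {
    e <- rep(0, n); e[j] <- 1
    lo <- oracle_lp(e, S, lb, ub, A, rhs, maximize = FALSE)
    hi <- oracle_lp(e, S, lb, ub, A, rhs, maximize = TRUE)
    data.frame(reaction_id = model$reactions$id[j],
               min_flux = lo$objective, max_flux = hi$objective)
  }))
}

# random flux-consistent model for property tests (built directly, not via
# the package's generator, so generator and solver are probed independently)
random_lp_model <- function(seed, n_rxn = 8, n_met = 4) {
  set.seed(seed)
  repeat {
    S <- matrix(sample(-2:2, n_met * n_rxn, replace = TRUE), n_met, n_rxn)
    if (all(colSums(abs(S)) > 0)) break
  }
  vref <- runif(n_rxn, -3, 3)
  S <- cbind(S, -as.vector(S %*% vref))
  vref <- c(vref, 1)
  n <- n_rxn + 1
  mets <- sprintf("M%d", seq_len(n_met))
  rownames(S) <- mets
  rx <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
    st <- S[, j]; st <- st[st != 0]
    if (length(st) == 0) st <- stats::setNames(1, mets[1])
    tibble::tibble(id = sprintf("R%d", j), stoichiometry = list(st),
                   lower_bound = vref[j] - runif(1, 0.5, 4),
                   upper_bound = vref[j] + runif(1, 0.5, 4),
                   gpr = "", subsystem = NA_character_)
  }))
  metabolic_model(tibble::tibble(id = mets, name = mets, compartment = "c"),
                  rx, name = sprintf("oracle_random_%d", seed))
}

expect_ranges_equal <- function(got, want, tol = 1e-6) {
  m <- merge(as.data.frame(got), as.data.frame(want),
             by = "reaction_id", suffixes = c("", "_want"))
  expect_equal(nrow(m), nrow(as.data.frame(want)))
  expect_lt(max(abs(m$min_flux - m$min_flux_want)), tol)
  expect_lt(max(abs(m$max_flux - m$max_flux_want)), tol)
}
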