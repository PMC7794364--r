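#' Sampler configuration
#'
#' Defaults follow the protocol used for the cell-line models: 1000 warmup
#' points combining orthogonal (FVA-extreme) and random-objective solutions,
#' 50,000 stored samples with 1000 hit-and-run steps between consecutive
#' stored points.
#'
#' @param n_warmup Number of warmup points (>= 2).
#' @param n_samples Number of stored samples (>= 1).
#' @param thinning Steps between stored points (>= 1).
#' @param seed Integer seed; required for reproducible runs.
#' @param tolerance Feasibility tolerance for stored points.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_warmup = 1000, n_samples = 50000, thinning = 1000,
                           seed = 1L, tolerance = 1e-6) {
  stopifnot(n_warmup >= 2, n_samples >= 1, thinning >= 1)
  structure(list(n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 tolerance = tolerance),
            class = "sampler_config")
}

new_flux_sample_set <- function(matrix, reaction_ids, config, model_name,
                                kind = "achr", diagnostics = list()) {
  colnames(matrix) <- reaction_ids
  structure(list(matrix = matrix, reaction_ids = reaction_ids,
                 config = config, model_name = model_name, kind = kind,
                 diagnostics = diagnostics),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %s: %d points x %d reactions (%s, seed %d)\n",
              x$model_name, nrow(x$matrix), length(x$reaction_ids), x$kind,
              x$config$seed))
  invisible(x)
}

#' @export
tidy.flux_sample_set <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x$matrix), .draw = seq_len(nrow(x$matrix))),
    -".draw", names_to = "reaction_id", values_to = "flux")
}

#' @export
glance.flux_sample_set <- function(x, ...) {
  tibble(model = x$model_name, n_samples = nrow(x$matrix),
         n_reactions = length(x$reaction_ids), kind = x$kind,
         seed = x$config$seed,
         degenerate_steps = x$diagnostics$degenerate_steps %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_feasible_rows <- function(model, M, tol) {
  S <- stoich_matrix(model)
  resid <- max(abs(S %*% t(M)))
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  bound_viol <- max(max(sweep(M, 2, ub, FUN = "-")),   # above upper bound
                    max(sweep(M, 2, lb, FUN = "-") * -1))  # below lower bound
  if (resid > tol || bound_viol > tol) {
    abort(sprintf("stored points violate feasibility: |Sv| max %.3g, bound overshoot %.3g (tol %g)",
                  resid, bound_viol, tol))
  }
  invisible(TRUE)
}

#' Generate warmup points for hit-and-run sampling
#'
#' Warmup combines "orthogonal" points - the FVA-extreme solutions obtained
#' by minimizing and maximizing each single reaction flux (up to
#' `2 * n_reactions` of them, duplicates skipped) - with random points drawn
#' as convex combinations of those extreme points (flat Dirichlet weights),
#' filling up to `n_warmup`. Every returned point is a feasible flux vector.
#'
#' @param model A feasible [metabolic_model()].
#' @param config A [sampler_config()].
#' @return A `flux_sample_set` with `n_warmup` rows.
#' @export
generate_warmup <- function(model, config = sampler_config()) {
  p <- lp_parts(model)
  n <- length(p$ids)
  probe <- solve_lp(rep(0, n), p$S, p$lb, p$ub)
  if (probe$status != "optimal") {
    abort(sprintf("model '%s' is %s; cannot generate warmup points",
                  model$name, probe$status))
  }
  set.seed(config$seed)
  pts <- matrix(NA_real_, nrow = config$n_warmup, ncol = n)
  k <- 0
  is_dup <- function(x) {
    k > 0 && any(apply(abs(pts[seq_len(k), , drop = FALSE] -
                             matrix(x, k, n, byrow = TRUE)), 1, max) < 1e-9)
  }
  # orthogonal points: +/- unit objectives in deterministic reaction order;
  # duplicate vertices (degenerate polytope directions) are skipped so the
  # cloud spans the polytope
  for (j in seq_len(n)) {
    for (dir in c(TRUE, FALSE)) {
      if (k >= config$n_warmup) break
      e <- rep(0, n); e[j] <- 1
      r <- solve_lp(e, p$S, p$lb, p$ub, maximize = dir)
      if (r$status == "optimal" && !is_dup(r$flux)) { k <- k + 1; pts[k, ] <- r$flux }
    }
  }
  # random points: random convex combinations (flat Dirichlet weights) of
  # the extreme points, feasible by convexity and spread over the interior
  k0 <- max(k, 1)
  if (k == 0) {                  # no orthogonal point accepted: solve one LP
    r <- solve_lp(rep(0, n), p$S, p$lb, p$ub)
    k <- 1; pts[1, ] <- r$flux
  }
  while (k < config$n_warmup) {
    w <- stats::rexp(k0)
    k <- k + 1
    pts[k, ] <- as.vector(t(pts[seq_len(k0), , drop = FALSE]) %*% (w / sum(w)))
  }
  assert_feasible_rows(model, pts, config$tolerance)
  new_flux_sample_set(pts, p$ids, config, model$name, kind = "warmup")
}

#' Artificial-centering hit-and-run sampling of the flux polytope
#'
#' Runs the ACHR Markov chain from the warmup cloud: each step picks a random
#' warmup point, takes its difference from the running center (updated after
#' every step) as the direction, projects it onto the null space of `S` so
#' steady state holds by construction, and jumps to a uniform point on the
#' feasible chord. Every `thinning`-th point is stored.
#'
#' @param model A [metabolic_model()].
#' @param warmup A warmup `flux_sample_set` from [generate_warmup()]; built
#'   automatically when `NULL`.
#' @param config A [sampler_config()]; `config$seed` makes the run
#'   bit-reproducible.
#' @return A `flux_sample_set` with `n_samples` feasible rows and
#'   diagnostics (`degenerate_steps`, `clamped_steps`).
#' @export
achr_sample <- function(model, warmup = NULL, config = sampler_config()) {
  if (is.null(warmup)) warmup <- generate_warmup(model, config)
  stopifnot(inherits(warmup, "flux_sample_set"))
  p <- lp_parts(model)
  if (!identical(warmup$reaction_ids, p$ids)) {
    abort("warmup set and model disagree on reaction ids")
  }
  Nb <- nullspace_basis(p$S)
  if (ncol(Nb) == 0) {
    # polytope is a single point (or empty); every sample equals that point
    x <- rep(0, length(p$ids))
    M <- matrix(rep(x, config$n_samples), nrow = config$n_samples, byrow = TRUE)
    assert_feasible_rows(model, M, config$tolerance)
    return(new_flux_sample_set(M, p$ids, config, model$name,
                               diagnostics = list(degenerate_steps = 0, clamped_steps = 0)))
  }
  W <- t(warmup$matrix)                      # n x n_warmup
  center <- rowMeans(W)
  x0 <- center
  set.seed(config$seed)
  res <- .achr_walk_cpp(W, Nb, p$lb, p$ub, x0, center,
                        ncol(W), config$n_samples, config$thinning,
                        config$tolerance)
  M <- res$samples
  assert_feasible_rows(model, M, config$tolerance)
  new_flux_sample_set(M, p$ids, config, model$name,
                      diagnostics = list(degenerate_steps = res$degenerate_steps,
                                         clamped_steps = res$clamped_steps))
}

# orthonormal basis of null(S) via SVD
nullspace_basis <- function(S, tol = NULL) {
  n <- ncol(S)
  sv <- svd(S, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  if (is.null(tol)) tol <- max(dim(S)) * max(d, 0) * .Machine$double.eps
  sv$v[, d <= tol, drop = FALSE]
}

#' Per-reaction histograms of sampled flux
#'
#' @param samples A `flux_sample_set`.
#' @param bins Number of bins (n_samples must be >= bins).
#' @return A tibble with columns `reaction_id`, `bin_left`, `bin_right`,
#'   `count`; per reaction the counts sum to `n_samples` and the edges span
#'   the sampled min/max. A constant-flux reaction occupies a single bin.
#' @export
flux_histograms <- function(samples, bins = 30) {
  M <- samples$matrix
  if (nrow(M) < bins) abort(sprintf("need at least %d samples for %d bins", bins, bins))
  out <- lapply(samples$reaction_ids, function(id) {
    v <- M[, id]
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) {
      return(tibble(reaction_id = id, bin_left = lo, bin_right = hi,
                    count = length(v)))
    }
    edges <- seq(lo, hi, length.out = bins + 1)
    cnt <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), bins),
                    nbins = bins)
    tibble(reaction_id = id, bin_left = edges[-length(edges)],
           bin_right = edges[-1], count = cnt)
  })
  dplyr::bind_rows(out)
}

#' Correlated reaction sets from sampled fluxes
#'
#' Builds the graph on reactions whose pairwise Pearson correlation over the
#' samples satisfies `|r| >= r_threshold` and reports its connected
#' components; constant-flux reactions (undefined correlation) are excluded.
#' Sets of trans-acting reactions that move together across the polytope are
#' the sampling analogue of co-regulated modules.
#'
#' @param samples A `flux_sample_set` with at least 100 rows.
#' @param r_threshold Correlation threshold in (0, 1].
#' @return A `correlated_sets` object: `sets` (tibble `set_id`,
#'   `reaction_id`) and `edges` (tibble `from`, `to`, `r`, `sign`).
#' @export
correlated_sets <- function(samples, r_threshold = 0.99) {
  if (nrow(samples$matrix) < 100) abort("correlated_sets needs >= 100 samples")
  if (r_threshold <= 0 || r_threshold > 1) abort("r_threshold must be in (0, 1]")
  M <- samples$matrix
  keep <- apply(M, 2, function(v) stats::sd(v) > 1e-10)
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 2) {
    return(structure(list(sets = tibble(set_id = integer(), reaction_id = character()),
                          edges = tibble(from = character(), to = character(),
                                         r = numeric(), sign = character())),
                     class = "correlated_sets"))
  }
  R <- stats::cor(M)
  idx <- which(abs(R) >= r_threshold & upper.tri(R), arr.ind = TRUE)
  edges <- tibble(from = colnames(M)[idx[, 1]], to = colnames(M)[idx[, 2]],
                  r = R[idx],
                  sign = ifelse(R[idx] >= 0, "+", "-"))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = colnames(M))
  comp <- igraph::components(g)
  member <- tibble(reaction_id = names(comp$membership),
                   set_id = unname(comp$membership))
  # only components with >= 2 reactions are informative sets
  sizes <- table(member$set_id)
  member <- member[member$set_id %in% names(sizes)[sizes >= 2], ]
  member$set_id <- as.integer(factor(member$set_id))
  structure(list(sets = member[order(member$set_id, member$reaction_id),
                               c("set_id", "reaction_id")],
                 edges = edges),
            class = "correlated_sets")
}

#' @export
print.correlated_sets <- function(x, ...) {
  cat(sprintf("<correlated_sets> %d sets, %d edges\n",
              length(unique(x$sets$set_id)), nrow(x$edges)))
  invisible(x)
}
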