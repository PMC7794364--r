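direction_class <- function(lo, hi, tol = 1e-9) {
  dplyr::case_when(
    hi - lo < tol & abs(lo) < tol ~ "zero",
    lo >= -tol & hi > tol ~ "forward",
    hi <= tol & lo < -tol ~ "reverse",
    lo < -tol & hi > tol ~ "bidirectional",
    TRUE ~ "fixed"
  )
}

#' Compare flux spans between two FVA results
#'
#' Joins two flux variability results on reaction id and reports, per
#' reaction, both span widths, the width ratio `b / a`, the overlap length
#' of the two ranges and a direction-flip classification (e.g. a reaction
#' bidirectional in one model but forced unidirectionally in the other).
#'
#' @param fva_a,fva_b [fva()] results for the two models.
#' @param join `"inner"` (shared reactions, default) or `"outer"` (union,
#'   with NA rows flagged).
#' @param tol Width below which a span counts as zero.
#' @return A tibble: `reaction_id`, `min_a`, `max_a`, `min_b`, `max_b`,
#'   `span_a`, `span_b`, `span_ratio`, `overlap`, `direction_a`,
#'   `direction_b`, `direction_flip`, `flip_type`.
#' @export
compare_spans <- function(fva_a, fva_b, join = c("inner", "outer"), tol = 1e-9) {
  join <- match.arg(join)
  a <- as_tibble(fva_a)[, c("reaction_id", "min_flux", "max_flux")]
  b <- as_tibble(fva_b)[, c("reaction_id", "min_flux", "max_flux")]
  shared <- intersect(a$reaction_id, b$reaction_id)
  if (length(shared) == 0) abort("the two FVA results share no reactions")
  joiner <- if (join == "inner") dplyr::inner_join else dplyr::full_join
  tab <- joiner(a, b, by = "reaction_id", suffix = c("_a", "_b"))
  tab |>
    dplyr::rename(min_a = "min_flux_a", max_a = "max_flux_a",
                  min_b = "min_flux_b", max_b = "max_flux_b") |>
    dplyr::mutate(
      span_a = .data$max_a - .data$min_a,
      span_b = .data$max_b - .data$min_b,
      span_ratio = dplyr::case_when(
        .data$span_a < tol & .data$span_b < tol ~ 1,
        .data$span_a < tol ~ Inf,
        TRUE ~ .data$span_b / .data$span_a
      ),
      overlap = pmax(0, pmin(.data$max_a, .data$max_b) -
                        pmax(.data$min_a, .data$min_b)),
      direction_a = direction_class(.data$min_a, .data$max_a, tol),
      direction_b = direction_class(.data$min_b, .data$max_b, tol),
      direction_flip = .data$direction_a != .data$direction_b &
        !(.data$direction_a %in% c("zero", "fixed") &
            .data$direction_b %in% c("zero", "fixed")),
      flip_type = dplyr::if_else(.data$direction_flip,
                                 paste0(.data$direction_a, "->", .data$direction_b),
                                 "none")
    )
}

#' Compare sampled flux distributions between two models
#'
#' For each shared reaction computes a shift statistic in `[0, 1]`: by
#' default `1 -` the histogram overlap coefficient on bin edges shared by
#' the two samples (`sum(pmin(p_a, p_b))` over common bins), which is 0 for
#' identical distributions and 1 for disjoint supports, and is symmetric in
#' its arguments. `statistic = "ks"` reports the two-sample
#' Kolmogorov-Smirnov statistic instead.
#'
#' @param samples_a,samples_b `flux_sample_set`s for the two models.
#' @param bins Number of shared bins for the overlap coefficient.
#' @param statistic `"overlap"` (default) or `"ks"`.
#' @return A tibble `reaction_id`, `shift`, `median_a`, `median_b`.
#' @export
compare_distributions <- function(samples_a, samples_b, bins = 30,
                                  statistic = c("overlap", "ks")) {
  statistic <- match.arg(statistic)
  shared <- intersect(samples_a$reaction_ids, samples_b$reaction_ids)
  if (length(shared) == 0) abort("the two sample sets share no reactions")
  out <- lapply(shared, function(id) {
    va <- samples_a$matrix[, id]; vb <- samples_b$matrix[, id]
    shift <- if (statistic == "ks") {
      if (stats::sd(va) < 1e-12 && stats::sd(vb) < 1e-12) {
        if (abs(stats::median(va) - stats::median(vb)) < 1e-9) 0 else 1
      } else {
        unname(suppressWarnings(stats::ks.test(va, vb)$statistic))
      }
    } else {
      lo <- min(va, vb); hi <- max(va, vb)
      if (hi - lo < 1e-12) {
        0  # both constant and identical
      } else {
        edges <- seq(lo, hi, length.out = bins + 1)
        pa <- tabulate(pmin(findInterval(va, edges, rightmost.closed = TRUE), bins),
                       nbins = bins) / length(va)
        pb <- tabulate(pmin(findInterval(vb, edges, rightmost.closed = TRUE), bins),
                       nbins = bins) / length(vb)
        1 - sum(pmin(pa, pb))
      }
    }
    tibble(reaction_id = id, shift = shift,
           median_a = stats::median(va), median_b = stats::median(vb))
  })
  dplyr::bind_rows(out)
}

#' Subsystem-level rollup of a differential report table
#'
#' @param report_table Per-reaction table carrying `reaction_id` and any of
#'   `span_ratio` and `shift` (e.g. the `per_reaction` table of
#'   [diff_models()]).
#' @param subsystem_map Data frame `reaction_id`, `subsystem` (or a named
#'   character vector); unmapped reactions are grouped under `"unassigned"`.
#' @param shift_threshold Shift above which a reaction counts as shifted.
#' @return A tibble per subsystem: `n`, `median_span_ratio`,
#'   `frac_shifted`.
#' @export
pathway_rollup <- function(report_table, subsystem_map, shift_threshold = 0.2) {
  if (!is.data.frame(subsystem_map)) {
    subsystem_map <- tibble(reaction_id = names(subsystem_map),
                            subsystem = unname(subsystem_map))
  }
  tab <- dplyr::left_join(as_tibble(report_table), as_tibble(subsystem_map),
                          by = "reaction_id")
  tab$subsystem[is.na(tab$subsystem)] <- "unassigned"
  tab |>
    dplyr::group_by(.data$subsystem) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_span_ratio = if ("span_ratio" %in% names(tab)) {
        stats::median(.data$span_ratio[is.finite(.data$span_ratio)], na.rm = TRUE)
      } else NA_real_,
      frac_shifted = if ("shift" %in% names(tab)) {
        mean(.data$shift > shift_threshold, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Full differential comparison of two contextualized models
#'
#' Runs flux variability analysis and hit-and-run sampling on both models,
#' joins spans and distribution shifts per reaction, rolls results up by
#' subsystem, and extracts correlated reaction sets from both sample
#' clouds - the computational twin of a paired flux-span/flux-distribution
#' figure for two cell lines.
#'
#' @param model_a,model_b Two [metabolic_model()]s sharing reaction ids.
#' @param gamma FVA sub-optimality level (see [fva()]).
#' @param config A [sampler_config()]; model B is sampled with
#'   `seed + 1` so the two chains are independent.
#' @param subsystem_map Optional `reaction_id` to `subsystem` map; defaults
#'   to the models' own `subsystem` annotations.
#' @param r_threshold Correlation threshold for [correlated_sets()].
#' @param shift_threshold Passed to [pathway_rollup()].
#' @return A `differential_report`: `per_reaction` tibble (spans, ratios,
#'   shifts, direction flips), `pathway_rollup`, `correlated_sets_a/b`,
#'   `metadata`.
#' @export
diff_models <- function(model_a, model_b, gamma = NULL,
                        config = sampler_config(n_warmup = 100, n_samples = 2000,
                                                thinning = 100),
                        subsystem_map = NULL, r_threshold = 0.99,
                        shift_threshold = 0.2) {
  fva_a <- fva(model_a, gamma = gamma)
  fva_b <- fva(model_b, gamma = gamma)
  spans <- compare_spans(fva_a, fva_b)
  samples_a <- achr_sample(model_a, config = config)
  config_b <- config; config_b$seed <- config$seed + 1L
  samples_b <- achr_sample(model_b, config = config_b)
  shifts <- compare_distributions(samples_a, samples_b)
  per_reaction <- dplyr::left_join(spans, shifts, by = "reaction_id")
  if (is.null(subsystem_map)) {
    subsystem_map <- tibble(reaction_id = model_a$reactions$id,
                            subsystem = model_a$reactions$subsystem)
    subsystem_map$subsystem[is.na(subsystem_map$subsystem)] <- "unassigned"
  }
  rollup <- pathway_rollup(per_reaction, subsystem_map, shift_threshold)
  sets_a <- if (nrow(samples_a$matrix) >= 100) correlated_sets(samples_a, r_threshold) else NULL
  sets_b <- if (nrow(samples_b$matrix) >= 100) correlated_sets(samples_b, r_threshold) else NULL
  structure(list(per_reaction = per_reaction, pathway_rollup = rollup,
                 correlated_sets_a = sets_a, correlated_sets_b = sets_b,
                 metadata = list(model_a = model_a$name, model_b = model_b$name,
                                 gamma = attr(fva_a, "gamma"),
                                 seed_a = config$seed, seed_b = config_b$seed,
                                 n_samples = config$n_samples,
                                 thinning = config$thinning)),
            class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<differential_report> %s vs %s (%d reactions, gamma %.2g)\n",
              md$model_a, md$model_b, nrow(x$per_reaction), md$gamma))
  top <- dplyr::arrange(x$per_reaction, dplyr::desc(.data$shift))
  cat("  top shifted reactions:\n")
  print(utils::head(top[, c("reaction_id", "span_a", "span_b", "span_ratio", "shift")], 5))
  invisible(x)
}

#' @export
tidy.differential_report <- function(x, ...) x$per_reaction

#' @export
glance.differential_report <- function(x, ...) {
  tibble(model_a = x$metadata$model_a, model_b = x$metadata$model_b,
         n_reactions = nrow(x$per_reaction),
         n_flips = sum(x$per_reaction$direction_flip, na.rm = TRUE),
         max_shift = max(x$per_reaction$shift, na.rm = TRUE))
}
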