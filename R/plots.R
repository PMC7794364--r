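#' Plot flux variability ranges
#'
#' One horizontal segment per reaction from `min_flux` to `max_flux`.
#'
#' @param object An [fva()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fva_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(y = stats::reorder(.data$reaction_id, .data$span))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_flux, xend = .data$max_flux,
                                       yend = stats::reorder(.data$reaction_id, .data$span)),
                          linewidth = 1.2, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "feasible flux (mmol/gDW/h)", y = NULL,
                  title = sprintf("Flux variability (gamma = %.2g)", attr(object, "gamma"))) +
    ggplot2::theme_minimal()
}

#' Plot sampled flux distributions
#'
#' Frequency histograms of the sampled flux for a subset of reactions.
#'
#' @param object A `flux_sample_set`.
#' @param reactions Reactions to show (default: the 9 widest).
#' @param bins Bins per panel.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flux_sample_set <- function(object, reactions = NULL, bins = 30, ...) {
  if (is.null(reactions)) {
    spread <- apply(object$matrix, 2, function(v) diff(range(v)))
    reactions <- names(sort(spread, decreasing = TRUE))[seq_len(min(9, length(spread)))]
  }
  d <- tidy(object) |> dplyr::filter(.data$reaction_id %in% reactions)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flux)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~reaction_id, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = "frequency",
                  title = sprintf("Sampled flux distributions (%s)", object$model_name)) +
    ggplot2::theme_minimal()
}

#' Plot a paired differential report
#'
#' Span segments of both models per reaction, ordered by distribution shift;
#' the visual counterpart of a differential flux-span figure for two cell
#' lines.
#'
#' @param object A [diff_models()] report.
#' @param top Number of most-shifted reactions to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.differential_report <- function(object, top = 20, ...) {
  d <- object$per_reaction |>
    dplyr::arrange(dplyr::desc(.data$shift)) |>
    utils::head(top)
  long <- dplyr::bind_rows(
    tibble(reaction_id = d$reaction_id, min = d$min_a, max = d$max_a,
           model = object$metadata$model_a),
    tibble(reaction_id = d$reaction_id, min = d$min_b, max = d$max_b,
           model = object$metadata$model_b))
  ggplot2::ggplot(long, ggplot2::aes(y = .data$reaction_id, colour = .data$model)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min, xend = .data$max,
                                       yend = .data$reaction_id),
                          linewidth = 1.4, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "feasible flux (mmol/gDW/h)", y = NULL, colour = NULL,
                  title = "Differential flux spans") +
    ggplot2::theme_minimal()
}

#' Plot a Gompertz growth fit
#'
#' @param object A [fit_gompertz()] result.
#' @param ... Unused.
#' @return A ggplot with the data points and fitted curve.
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  tt <- seq(min(object$data$time_h), max(object$data$time_h), length.out = 200)
  curve <- tibble(time_h = tt, count = predict(object, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "viable cells",
                  title = sprintf("Gompertz fit: mu = %.3g /h", object$mu_max)) +
    ggplot2::theme_minimal()
}
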