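# ggplot2 displays for the main result types

#' @describeIn trial_means heatmap of per-trial responses.
#' @param object a `trial_responses` object.
#' @export
autoplot.trial_responses <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$trial, .data$neuron,
                                 fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dF/F0 (%)") +
    ggplot2::labs(x = "trial", y = "neuron",
                  title = "Per-trial mean responses")
}

#' Plot a neuron's tuning curve and fitted model
#'
#' @param tuning a `tuning_result` from [tune_neurons()].
#' @param neuron neuron index.
#' @return a ggplot.
#' @export
plot_tuning_curve <- function(tuning, neuron) {
  dmeans <- attr(tuning, "direction_means")
  dirs <- attr(tuning, "directions")
  row <- tuning[tuning$neuron == neuron, ]
  df <- tibble(direction = dirs, response = dmeans[neuron, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "grating direction (deg)", y = "mean dF/F0 (%)",
                  title = sprintf("neuron %d (%s)", neuron,
                                  row$tuning_class))
  if (!is.na(row$b) && !is.na(row$theta_p_deg)) {
    grid <- tibble(direction = seq(0, 360, by = 2))
    grid$fit <- acg_model(grid$direction, row$b, row$a1, row$a2,
                          row$sigma_deg, row$theta_p_deg)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$fit),
                                colour = "steelblue")
  }
  p
}

#' @describeIn directed_clustering boxplots of per-node coefficients by
#'   motif.
#' @param object a `clustering_profile`.
#' @param ... unused.
#' @export
autoplot.clustering_profile <- function(object, ...) {
  as_tibble(object) |>
    pivot_longer(all_of(motif_names), names_to = "motif",
                 values_to = "clustering") |>
    filter(!is.na(.data$clustering)) |>
    ggplot2::ggplot(ggplot2::aes(.data$motif, .data$clustering)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "clustering coefficient",
                  title = "Directed triplet-motif clustering")
}

#' @describeIn reconstruct_population histogram of per-neuron variance
#'   explained.
#' @param object a `recon_result`.
#' @export
autoplot.recon_result <- function(object, ...) {
  ggplot2::ggplot(object$neurons, ggplot2::aes(.data$ve)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(x = "variance explained", y = "neurons",
                  title = sprintf("Reconstruction (population VE = %.2f)",
                                  object$population_ve))
}

#' Plot edge-removal MSE curves
#'
#' @param curves tibble from [edge_removal_curves()], optionally
#'   row-bound with an `order` column distinguishing removal orders.
#' @param x which x axis to use.
#' @return a ggplot.
#' @export
plot_removal_curves <- function(curves,
                                x = c("frac_removed", "cum_weight_frac")) {
  x <- match.arg(x)
  aes <- if ("order" %in% names(curves)) {
    ggplot2::aes(.data[[x]], .data$dmse_norm, colour = .data$order)
  } else {
    ggplot2::aes(.data[[x]], .data$dmse_norm)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (x == "frac_removed") "fraction of edges removed"
                  else "cumulative |weight| fraction removed",
                  y = "normalized MSE increase")
}

#' @describeIn running_by_activity running probability by activity
#'   quantile.
#' @param object tibble from [running_by_activity()].
#' @param ... unused.
#' @export
autoplot_running <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$quantile, .data$p_running)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "population fluorescence quantile",
                  y = "P(running)")
}
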