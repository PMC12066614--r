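#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs facet_wrap theme_minimal scale_x_log10
NULL

#' Plot an activating-function profile
#'
#' @param object An `af_profile` from [activating_function()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.af_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$arclength_um, y = .data$af_mv_um2)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2c7fb8") +
    labs(x = "arclength along axon (µm)",
         y = expression(AF ~ (mV / mu * m^2)),
         title = "Activating function") +
    theme_minimal()
}

#' Plot membrane-potential traces
#'
#' @param object A `simulation_trace`.
#' @param nodes Node ids to draw (default: the 4 nodes with the largest
#'   excursion from rest).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.simulation_trace <- function(object, nodes = NULL, ...) {
  df <- tidy(object)
  if (is.null(nodes)) {
    rng <- apply(object$vm_mv, 1, function(v) diff(range(v)))
    nodes <- object$segments$node_id[order(-rng)][seq_len(min(4,
                                                              length(rng)))]
  }
  df <- df[df$node_id %in% nodes, ]
  df$node <- factor(paste0(df$kind, " #", df$node_id))
  ggplot(df, aes(x = .data$time_ms, y = .data$vm_mv, colour = .data$node)) +
    geom_line() +
    labs(x = "time (ms)", y = expression(V[m] ~ (mV)), colour = NULL) +
    theme_minimal()
}

#' Plot the trace of a titration result
#'
#' @param object A `titration_result`.
#' @param ... Passed to `autoplot.simulation_trace()`.
#' @export
autoplot.titration_result <- function(object, ...) {
  nodes <- unique(c(object$initiation_node,
                    object$trace$segments$node_id[
                      object$trace$segments$kind == "axon"][1]))
  nodes <- nodes[!is.na(nodes)]
  p <- autoplot(object$trace, nodes = if (length(nodes)) nodes, ...)
  sub <- if (object$success) {
    sprintf("AC = %.4g, outcome: %s", object$ac, object$outcome)
  } else {
    sprintf("no success up to cap; outcome at cap: %s", object$outcome)
  }
  p + labs(title = "Titration", subtitle = sub)
}

#' Plot a potential profile along the axon
#'
#' @param profile Tibble from [axon_potential_profile()], or several
#'   stacked with a `label` column.
#' @return A ggplot.
#' @export
plot_potential_profile <- function(profile) {
  p <- ggplot(profile, aes(x = .data$arclength_um, y = .data$v_mv))
  if ("label" %in% names(profile)) {
    p <- p + geom_line(aes(colour = .data$label))
  } else {
    p <- p + geom_line(colour = "#2c7fb8")
  }
  p + labs(x = "arclength along axon (µm)", y = "V (mV)",
           colour = NULL) +
    theme_minimal()
}

#' Plot a frequency sweep result
#'
#' @param result Tibble from [run_frequency_sweep()].
#' @return A ggplot (AC vs frequency, log-x, coloured by first-spike
#'   location).
#' @export
plot_frequency_sweep <- function(result) {
  ggplot(result, aes(x = .data$frequency_hz, y = .data$ac)) +
    geom_line(colour = "grey60") +
    geom_point(aes(colour = .data$first_spike), size = 2.5) +
    scale_x_log10() +
    labs(x = "frequency (Hz)", y = "amplification coefficient",
         colour = "first spike") +
    theme_minimal()
}

#' Plot a bias sweep result
#'
#' @param result Tibble from [run_bias_sweep()].
#' @return A ggplot (AC vs bias per combination).
#' @export
plot_bias_sweep <- function(result) {
  ggplot(result, aes(x = .data$bias_mv, y = .data$ac,
                     colour = .data$combination)) +
    geom_line() +
    geom_point(aes(shape = .data$first_spike), size = 2.5) +
    labs(x = "static bias (mV)", y = "amplification coefficient",
         colour = NULL, shape = "first spike") +
    theme_minimal()
}
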