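# ggplot2 helpers for profiles, designs and QC comparisons.

#' Plot a positional amino-acid profile
#'
#' Stacked per-position amino-acid frequencies for one CDR-H3 length -- the
#' positional composition the simulator draws from (a bar-chart analogue of
#' a sequence logo).
#'
#' @param profile an `h3_profile`.
#' @param length which CDR length to show (default: the modal length).
#' @return a ggplot object.
#' @export
plot_positional_profile <- function(profile, length = NULL) {
  if (is.null(length)) {
    length <- as.integer(names(which.max(profile$length_dist)))
  }
  df <- tidy.h3_profile(profile) |> dplyr::filter(.data$length == !!length)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$frequency,
                                   fill = .data$residue)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "CDR-H3 position", y = "frequency",
                  title = paste0("Positional composition, length ", length)) +
    ggplot2::theme_minimal()
}

#' Plot designed vs observed CDR length distributions
#'
#' @param comparison a `design_comparison` from [compare_design()].
#' @return a ggplot object faceted by region.
#' @export
plot_length_comparison <- function(comparison) {
  ggplot2::ggplot(comparison$length_dist,
                  ggplot2::aes(x = factor(.data$length), y = .data$freq,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = "CDR length", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot design-fidelity frequency scatter
#'
#' Designed vs observed relative frequency of each designed sequence seen
#' in the data, faceted by region, with the squared Pearson correlation in
#' the facet label data.
#'
#' @param comparison a `design_comparison` from [compare_design()].
#' @return a ggplot object.
#' @export
plot_design_fidelity <- function(comparison) {
  ggplot2::ggplot(comparison$freq_pairs,
                  ggplot2::aes(x = .data$designed_freq, y = .data$observed_freq)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~region, scales = "free") +
    ggplot2::labs(x = "designed frequency", y = "observed frequency") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.design_comparison <- function(object, ...) plot_design_fidelity(object)

#' @exportS3Method ggplot2::autoplot
autoplot.h3_profile <- function(object, ...) plot_positional_profile(object)

#' Plot the redundancy spectrum of functional domain sequences
#'
#' @param report a `qc_report` from [summarize_library()].
#' @return a ggplot object.
#' @export
plot_redundancy <- function(report) {
  ggplot2::ggplot(report$redundancy,
                  ggplot2::aes(x = factor(.data$times_seen), y = .data$n_sequences)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "times a unique domain sequence was seen (n)",
                  y = "number of sequences") +
    ggplot2::theme_minimal()
}
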