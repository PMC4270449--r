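#' Plot a compressed spectral array
#'
#' Epoch-by-frequency power raster of the CSA, the plot under which the
#' salient patterns (stable alpha, pre-alpha shift, low-frequency
#' degradation) are read.
#'
#' @param object A `csa_matrix`.
#' @param max_freq Upper frequency limit for display (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csa_matrix
#' @export
autoplot.csa_matrix <- function(object, max_freq = 15, ...) {
  d <- as_tibble(object)
  d <- d[d$freq <= max_freq, ]
  ggplot(d, aes(x = .data$freq, y = .data$epoch, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c(name = "power (µV²)") +
    labs(x = "frequency (Hz)", y = "epoch",
         title = paste("CSA:", attr(object, "channel"))) +
    theme_minimal()
}

#' Plot a dominant-frequency trajectory
#'
#' @param df_per_epoch Numeric vector of per-epoch dominant frequencies, or a
#'   `csa_descriptors` row (its `df_per_epoch` column is used).
#' @param bands Band scheme drawn as horizontal guides.
#' @return A ggplot object.
#' @export
plot_df_trajectory <- function(df_per_epoch, bands = band_scheme()) {
  if (inherits(df_per_epoch, "csa_descriptors")) {
    df_per_epoch <- df_per_epoch$df_per_epoch[[1]]
  }
  d <- tibble(epoch = seq_along(df_per_epoch), df = df_per_epoch)
  ggplot(d, aes(x = .data$epoch, y = .data$df)) +
    geom_hline(yintercept = c(bands$lower, max(bands$upper)),
               colour = "grey80", linetype = 2) +
    geom_line(colour = "grey50") +
    geom_point(size = 0.8) +
    labs(x = "epoch", y = "dominant frequency (Hz)") +
    theme_minimal()
}

#' Plot cohort pattern composition by group
#'
#' @param cohort Cohort tibble with `group` and `pattern` columns.
#' @return A ggplot stacked bar chart.
#' @export
plot_cohort_patterns <- function(cohort) {
  d <- dplyr::count(cohort, .data$group, .data$pattern)
  ggplot(d, aes(x = .data$group, y = .data$n, fill = .data$pattern)) +
    ggplot2::geom_col() +
    labs(x = NULL, y = "subjects", fill = "CSA pattern") +
    theme_minimal()
}
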