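#' Heatmap of hourly traffic rates or daily hourly proportions
#'
#' Dates on the y axis, UTC clock hours on the x axis; missing hours are
#' drawn grey, true zeros in the fill scale's low colour.
#'
#' @param matrix_long tibble from [hourly_proportion_matrix()] (one site, or
#'   pass `site`).
#' @param value `"prop"` or `"mtr"`.
#' @param site site id to plot.
#' @return a ggplot object.
#' @export
plot_diel_heatmap <- function(matrix_long, value = c("prop", "mtr"),
                              site = NULL) {
  value <- match.arg(value)
  if (!is.null(site)) {
    matrix_long <- matrix_long[matrix_long$site_id == site, , drop = FALSE]
  }
  ggplot2::ggplot(matrix_long,
                  ggplot2::aes(x = .data$hour, y = .data$date,
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(
      x = "hour (UTC)", y = NULL,
      fill = if (value == "prop") "daily share" else "MTR (km⁻¹ h⁻¹)",
      title = unique(matrix_long$site_id)
    ) +
    ggplot2::theme_minimal()
}

#' Monthly mean proportions by diel phase
#'
#' One panel per site, months on the x axis, stacked monthly mean
#' proportional migration intensity or traffic per diel phase.
#'
#' @param monthly tibble from [monthly_phase_summary()].
#' @param measure `"intensity"` or `"traffic"`.
#' @return a ggplot object.
#' @export
plot_monthly_proportions <- function(monthly,
                                     measure = c("intensity", "traffic")) {
  measure <- match.arg(measure)
  col <- paste0("mean_prop_", measure)
  dat <- monthly[!is.na(monthly[[col]]), , drop = FALSE]
  dat$phase <- factor(dat$phase, levels = diel_phase_levels())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$month, y = .data[[col]],
                                    fill = .data$phase)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~site_id) +
    ggplot2::labs(x = NULL, fill = "diel phase",
                  y = paste("monthly mean proportional migration", measure)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Pairwise post-hoc effect sizes
#'
#' Absolute differences of fitted site mean proportions per diel phase, with
#' Holm-significant pairs highlighted.
#'
#' @param posthoc posthoc tibble from [diel_site_anova()].
#' @return a ggplot object.
#' @export
plot_effect_sizes <- function(posthoc) {
  dat <- dplyr::mutate(posthoc,
                       phase = factor(.data$phase,
                                      levels = diel_phase_levels()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase,
                                    y = abs(.data$effect_size),
                                    colour = .data$significant)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "|difference of fitted mean proportions|",
                  colour = "Holm p < 0.05") +
    ggplot2::theme_minimal()
}
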