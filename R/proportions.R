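#' Daily proportional migration intensity and traffic
#'
#' For each site and diel day, expresses each phase's mean traffic rate as a
#' share of the summed mean rates of all phases of that day (proportional
#' migration intensity), and each phase's total traffic as a share of the
#' day's total traffic (proportional migration traffic). Both sets of shares
#' lie in \[0, 1\] and sum to 1. A day is incomplete — all shares `NA` — when
#' any of its phase aggregates is `NA`; a day whose phases are all zero has
#' undefined shares and is likewise `NA`. High-latitude summer days without
#' a night phase are complete with their three phases.
#'
#' @param phase_agg tibble from [phase_aggregates()].
#' @return tibble `site_id, anchor_date, phase, prop_intensity,
#'   prop_traffic, complete`.
#' @export
daily_proportions <- function(phase_agg) {
  if (any(phase_agg$mean_rate < 0, na.rm = TRUE)) {
    stop("negative mean_rate in phase aggregates", call. = FALSE)
  }
  phase_agg |>
    dplyr::group_by(.data$site_id, .data$anchor_date) |>
    dplyr::mutate(
      complete = !anyNA(.data$mean_rate) && sum(.data$mean_rate) > 0,
      prop_intensity = dplyr::if_else(
        .data$complete, .data$mean_rate / sum(.data$mean_rate), NA_real_),
      prop_traffic = dplyr::if_else(
        .data$complete, .data$total_traffic / sum(.data$total_traffic),
        NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "anchor_date", "phase",
                  "prop_intensity", "prop_traffic", "complete")
}

#' Compress proportions away from the boundary
#'
#' Applies `y' = (y (N - 1) + 0.5) / N`, the standard shrinkage that maps
#' proportions in \[0, 1\] into the open interval (0, 1) so a beta
#' likelihood is finite; `N` is the sample size (number of days with values
#' for the phase being analysed). The transform fixes 0.5, is strictly
#' increasing in `y`, and tends to the identity as `N` grows.
#'
#' @param y proportions in \[0, 1\].
#' @param n sample size, integer >= 1.
#' @return compressed proportions in (0, 1).
#' @examples
#' compress_proportion(c(0, 0.5, 1), 100)
#' @export
compress_proportion <- function(y, n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("y must lie in [0, 1]", call. = FALSE)
  }
  (y * (n - 1) + 0.5) / n
}
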