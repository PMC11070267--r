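#' Daily proportional hourly traffic-rate matrix
#'
#' For each site and calendar day, divides every non-missing hourly traffic
#' rate by the day's summed rate, giving values in \[0, 1\] that show how
#' much of that day's insect traffic occurred in each clock hour. All-zero
#' days stay zero (distinct from missing); days with no data at all are
#' missing. Hours are UTC clock hours.
#'
#' @param hourly tibble from [hourly_mtr()].
#' @return tibble `site_id, date, hour, mtr, prop, missing` (long form; one
#'   row per site-day-hour). Use [heatmap_wide()] for the dates-by-hours
#'   matrix layout.
#' @export
hourly_proportion_matrix <- function(hourly) {
  hourly |>
    dplyr::mutate(date = as.Date(.data$hour_start_utc, tz = "UTC"),
                  hour = lubridate::hour(.data$hour_start_utc)) |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::mutate(
      day_sum = sum(.data$mtr, na.rm = TRUE),
      any_data = any(!is.na(.data$mtr)),
      prop = dplyr::case_when(
        is.na(.data$mtr) ~ NA_real_,
        .data$day_sum > 0 ~ .data$mtr / .data$day_sum,
        TRUE ~ 0
      ),
      missing = is.na(.data$mtr)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "date", "hour", "mtr", "prop", "missing")
}

#' Pivot a heatmap table to a dates-by-hours matrix
#'
#' @param matrix_long tibble from [hourly_proportion_matrix()].
#' @param value `"prop"` or `"mtr"`.
#' @param site site id to extract (default: the only one present).
#' @return tibble with a `date` column and one column per clock hour
#'   (`h00` ... `h23`).
#' @export
heatmap_wide <- function(matrix_long, value = c("prop", "mtr"),
                         site = NULL) {
  value <- match.arg(value)
  if (!is.null(site)) {
    matrix_long <- matrix_long[matrix_long$site_id == site, , drop = FALSE]
  }
  stopifnot(length(unique(matrix_long$site_id)) == 1)
  matrix_long |>
    dplyr::mutate(hour = sprintf("h%02d", .data$hour)) |>
    dplyr::select("date", "hour", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "hour", values_from = dplyr::all_of(value),
                       names_sort = TRUE)
}

#' Monthly summaries per site, month and diel phase
#'
#' Combines three monthly statistics per site, month and diel phase:
#' the arithmetic means of the daily proportional migration intensity and
#' traffic; the relative mean radar cross section (the phase's mean RCSmax
#' divided by the sum of the phase means, so shares add to 1 per site and
#' month); and the monthly mean of the daily median flight altitude of
#' phase-assigned insect echoes (metres above the radar). When a phase has
#' no echoes in a month its RCS share (and those of its siblings) is `NA`
#' rather than renormalized.
#'
#' @param daily_props tibble from [daily_proportions()].
#' @param echoes insect-filtered echo tibble.
#' @param phase_intervals tibble from [diel_phases()].
#' @return tibble `site_id, month, phase, mean_prop_intensity,
#'   mean_prop_traffic, rcs_share, mean_daily_median_alt_m, n_days`.
#' @export
monthly_phase_summary <- function(daily_props, echoes, phase_intervals) {
  props <- daily_props |>
    dplyr::filter(.data$complete) |>
    dplyr::mutate(month = format(.data$anchor_date, "%Y-%m")) |>
    dplyr::group_by(.data$site_id, .data$month, .data$phase) |>
    dplyr::summarise(
      mean_prop_intensity = mean(.data$prop_intensity),
      mean_prop_traffic = mean(.data$prop_traffic),
      n_days = dplyr::n(), .groups = "drop"
    )

  labelled <- purrr::map_dfr(unique(echoes$site_id), function(sid) {
    sub <- echoes[echoes$site_id == sid, , drop = FALSE]
    ph <- phase_intervals[phase_intervals$site_id == sid, , drop = FALSE]
    lab <- assign_phase(sub$timestamp_utc, ph)
    dplyr::bind_cols(sub, lab[, c("phase", "anchor_date")])
  })
  echo_stats <- labelled |>
    dplyr::mutate(month = format(.data$anchor_date, "%Y-%m")) |>
    dplyr::group_by(.data$site_id, .data$month, .data$phase) |>
    dplyr::summarise(
      mean_rcs = mean(.data$rcs_max_cm2),
      mean_daily_median_alt_m = mean(
        tapply(.data$altitude_agl_m, .data$anchor_date, median)),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$site_id, .data$month) |>
    dplyr::mutate(
      n_phases = dplyr::n(),
      expected = length(intersect(
        diel_phase_levels(),
        phase_intervals$phase[phase_intervals$site_id == .data$site_id[1]])),
      rcs_share = dplyr::if_else(.data$n_phases == .data$expected,
                                 .data$mean_rcs / sum(.data$mean_rcs),
                                 NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "month", "phase", "rcs_share",
                  "mean_daily_median_alt_m")

  dplyr::full_join(props, echo_stats,
                   by = c("site_id", "month", "phase")) |>
    dplyr::arrange(.data$site_id, .data$month,
                   match(.data$phase, diel_phase_levels())) |>
    dplyr::select("site_id", "month", "phase", "mean_prop_intensity",
                  "mean_prop_traffic", "rcs_share",
                  "mean_daily_median_alt_m", "n_days")
}

#' Run the full diel-migration pipeline
#'
#' Executes the whole analysis on in-memory inputs: insect/altitude-band
#' filtering, diel-phase computation, hourly traffic rates, phase
#' aggregates, daily proportions, beta-ANOVA omnibus and Holm-corrected
#' post-hoc tests for both measures, monthly summaries, and heatmap
#' matrices. Optionally writes every table plus a machine-readable run log
#' to `out_dir`.
#'
#' @param sites tibble from [read_sites()].
#' @param echoes tibble from [read_echo_table()] (unfiltered).
#' @param intervals tibble from [read_intervals()].
#' @param config a [dielflux_config()].
#' @param exclude_sites site ids excluded from the ANOVA stage only (sites
#'   whose coverage does not span the analysis period).
#' @param out_dir optional output directory.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return list with `insects`, `phases`, `hourly`, `phase_agg`,
#'   `daily_props`, `anova_intensity`, `anova_traffic`, `monthly`,
#'   `heatmap`.
#' @export
run_pipeline <- function(sites, echoes, intervals,
                         config = dielflux_config(),
                         exclude_sites = character(),
                         out_dir = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  insects <- stage("filter", filter_insects(echoes, config))
  phases <- stage("phases", diel_phases(
    sites, seq(config$period[1], config$period[2], by = "day"), config))
  hourly <- stage("hourly_mtr", hourly_mtr(insects, intervals, sites, config))
  phase_agg <- stage("phase_aggregates",
                     phase_aggregates(insects, phases, intervals, config))
  daily <- stage("daily_proportions", daily_proportions(phase_agg))
  an_int <- stage("anova_intensity",
                  diel_site_anova(daily, "intensity", config, exclude_sites))
  an_tra <- stage("anova_traffic",
                  diel_site_anova(daily, "traffic", config, exclude_sites))
  monthly <- stage("monthly_summary",
                   monthly_phase_summary(daily, insects, phases))
  heatmap <- stage("heatmap", hourly_proportion_matrix(hourly))
  out <- list(insects = insects, phases = phases, hourly = hourly,
              phase_agg = phase_agg, daily_props = daily,
              anova_intensity = an_int, anova_traffic = an_tra,
              monthly = monthly, heatmap = heatmap)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config, seed)
  out
}

write_pipeline_outputs <- function(out, out_dir, config, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
  }
  wcsv(dplyr::mutate(out$phases,
                     dplyr::across(dplyr::where(lubridate::is.POSIXct),
                                   format_utc)), "phases.csv")
  wcsv(dplyr::mutate(out$hourly,
                     hour_start_utc = format_utc(.data$hour_start_utc)),
       "hourly_mtr.csv")
  wcsv(out$phase_agg, "phase_agg.csv")
  wcsv(out$daily_props, "daily_props.csv")
  wcsv(dplyr::bind_rows(out$anova_intensity$omnibus,
                        out$anova_traffic$omnibus), "omnibus.csv")
  wcsv(dplyr::bind_rows(out$anova_intensity$posthoc,
                        out$anova_traffic$posthoc), "posthoc.csv")
  wcsv(out$monthly, "monthly_summary.csv")
  for (sid in unique(out$heatmap$site_id)) {
    wcsv(heatmap_wide(out$heatmap, "mtr", sid),
         paste0("heatmap_mtr_", sid, ".csv"))
    wcsv(heatmap_wide(out$heatmap, "prop", sid),
         paste0("heatmap_prop_", sid, ".csv"))
  }
  log <- list(
    package = "dielflux",
    seed = seed,
    config = list(
      altitude_band = config$altitude_band,
      p_insect_min = config$p_insect_min,
      min_monitoring_fraction = config$min_monitoring_fraction,
      twilight_threshold_deg = config$twilight_threshold_deg,
      period = format(config$period),
      twilight_split = config$twilight_split,
      holm_family = config$holm_family
    ),
    rows = lapply(out[c("insects", "phases", "hourly", "phase_agg",
                        "daily_props", "monthly")], nrow)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
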