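#' Analysis configuration
#'
#' Bundles the tunable parameters of the diel-migration pipeline. Defaults
#' follow the standard protocol for vertical-looking entomological radar:
#' insect echoes between 50 and 500 m above the radar, an insect class
#' probability above 0.4 (and above every competing class), 1 h traffic-rate
#' bins treated as missing when less than 20% of the hour was monitored, and
#' crepuscular phases bounded by the geometric sun centre at 0 and -12
#' degrees elevation.
#'
#' @param altitude_band numeric length-2, metres above the radar; echoes
#'   outside `[min, max]` are discarded.
#' @param p_insect_min minimum insect class probability (exclusive).
#' @param min_monitoring_fraction fraction of a time bin that must be
#'   monitored for its rate to be reported; bins below it become `NA`.
#' @param twilight_threshold_deg solar elevation (degrees, negative below the
#'   horizon) bounding nautical twilight; -12 gives nautical dawn/dusk.
#' @param period length-2 `Date` vector, inclusive analysis period.
#' @param twilight_split how to split the sunset-to-next-sunrise span on
#'   high-latitude dates with no nautical night: `"clock_midpoint"` splits at
#'   the clock-time midpoint.
#' @param holm_family family for the Holm correction of pairwise post-hoc
#'   tests: `"per_phase"` adjusts within each diel phase's set of site pairs,
#'   `"pooled"` across all phases of a measure.
#'
#' @return A list of class `dielflux_config`.
#' @examples
#' cfg <- dielflux_config()
#' cfg$altitude_band
#' @export
dielflux_config <- function(altitude_band = c(50, 500),
                            p_insect_min = 0.4,
                            min_monitoring_fraction = 0.2,
                            twilight_threshold_deg = -12,
                            period = as.Date(c("2021-03-01", "2021-10-31")),
                            twilight_split = c("clock_midpoint"),
                            holm_family = c("per_phase", "pooled")) {
  stopifnot(
    length(altitude_band) == 2, altitude_band[1] < altitude_band[2],
    p_insect_min >= 0, p_insect_min <= 1,
    min_monitoring_fraction >= 0, min_monitoring_fraction <= 1,
    twilight_threshold_deg >= -18, twilight_threshold_deg <= 0
  )
  period <- as.Date(period)
  stopifnot(length(period) == 2, period[1] <= period[2])
  structure(
    list(
      altitude_band = as.numeric(altitude_band),
      p_insect_min = p_insect_min,
      min_monitoring_fraction = min_monitoring_fraction,
      twilight_threshold_deg = twilight_threshold_deg,
      period = period,
      twilight_split = match.arg(twilight_split),
      holm_family = match.arg(holm_family)
    ),
    class = "dielflux_config"
  )
}

#' @export
print.dielflux_config <- function(x, ...) {
  cat("<dielflux_config>\n")
  cat("  altitude band:        ", x$altitude_band[1], "-", x$altitude_band[2], "m AGL\n")
  cat("  p(insect) >           ", x$p_insect_min, "\n")
  cat("  min monitoring frac:  ", x$min_monitoring_fraction, "\n")
  cat("  twilight threshold:   ", x$twilight_threshold_deg, "deg\n")
  cat("  period:               ", format(x$period[1]), "to", format(x$period[2]), "\n")
  cat("  twilight split:       ", x$twilight_split, "\n")
  cat("  Holm family:          ", x$holm_family, "\n")
  invisible(x)
}

#' The four diel phase labels, in diel-day order
#'
#' A diel day runs from nautical dawn to the next nautical dawn, so the
#' phases occur in the order crepuscular morning, day, crepuscular evening,
#' night.
#' @return character vector of length 4.
#' @export
diel_phase_levels <- function() {
  c("crepuscular_morning", "day", "crepuscular_evening", "night")
}
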