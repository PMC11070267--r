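#' Filter echoes to insects within the altitude band
#'
#' Keeps echoes whose insect class probability exceeds the configured
#' minimum (default 0.4) and exceeds every competing class probability, then
#' restricts to the configured altitude band (default 50-500 m above the
#' radar).
#'
#' @param echoes echo tibble (see [read_echo_table()]).
#' @param config a [dielflux_config()].
#' @return filtered echo tibble, row order preserved.
#' @export
filter_insects <- function(echoes, config = dielflux_config()) {
  dplyr::filter(
    echoes,
    .data$p_insect > config$p_insect_min,
    .data$p_insect > .data$p_bird,
    .data$p_insect > .data$p_nonbio,
    .data$altitude_agl_m >= config$altitude_band[1],
    .data$altitude_agl_m <= config$altitude_band[2]
  )
}

# half-angle of the nominal -3 dB beam (degrees)
BEAM_HALF_ANGLE_DEG <- 17.5 / 2

#' Transect width sampled by the radar beam at a given altitude
#'
#' The vertical beam has a nominal -3 dB width of 17.5 degrees, so at
#' altitude `h` (metres above the radar) a target crossing the beam is
#' observed over a horizontal transect of width `2 h tan(17.5/2 deg)`.
#' Weighting each echo by the reciprocal of this width converts echo counts
#' into a traffic rate per km of transect.
#'
#' @param altitude_agl_m altitude above the radar in metres, > 0.
#' @return transect width in kilometres; strictly increasing and linear in
#'   altitude.
#' @examples
#' transect_width(200) # ~0.0616 km
#' @export
transect_width <- function(altitude_agl_m) {
  if (any(altitude_agl_m <= 0)) stop("altitude must be > 0", call. = FALSE)
  2 * altitude_agl_m * tan(BEAM_HALF_ANGLE_DEG * pi / 180) / 1000
}

#' Minutes of a time window covered by monitoring intervals
#'
#' @param intervals normalized interval tibble (see [read_intervals()]);
#'   only rows with `kind == "protocol_shortpulse"` for `site` count.
#' @param site site id.
#' @param window_start,window_end `POSIXct` bounds of the window.
#' @return minutes of overlap, a scalar in `[0, window length]`.
#' @export
effective_minutes <- function(intervals, site, window_start, window_end) {
  overlap_seconds(
    intervals[intervals$site_id == site &
                intervals$kind == "protocol_shortpulse", , drop = FALSE],
    window_start, window_end
  ) / 60
}

# total seconds of [start, end) covered by the (disjoint) interval rows
overlap_seconds <- function(iv, start, end) {
  if (nrow(iv) == 0) return(0)
  s <- pmax(as.numeric(iv$start_utc), as.numeric(start))
  e <- pmin(as.numeric(iv$end_utc), as.numeric(end))
  sum(pmax(0, e - s))
}

#' Hourly migration traffic rates
#'
#' Converts filtered insect echoes into a non-directional migration traffic
#' rate (insects per km per hour) for every clock hour of the analysis
#' period: each echo contributes the reciprocal of the transect width at its
#' altitude, the sum is scaled to the effective monitoring time of the hour,
#' and hours with less than `min_monitoring_fraction` (default 20%, i.e.
#' 12 min) of monitoring are set to `NA`. Echoes falling inside rain
#' intervals are excluded from the sum while the time remains monitored, so
#' rain contributes zero traffic rather than missing data.
#'
#' @param echoes insect-filtered echo tibble for one or more sites.
#' @param intervals normalized interval tibble (protocol + rain).
#' @param sites tibble with at least `site_id`; hours are computed per site.
#' @param config a [dielflux_config()].
#' @param w_fn transect-width function of altitude (metres) returning km;
#'   override (e.g. `function(h) 1`) decouples arithmetic from beam
#'   geometry in tests.
#' @return tibble `site_id, hour_start_utc, mtr, n_echoes, effective_min`
#'   covering every hour of the configured period for every site.
#' @export
hourly_mtr <- function(echoes, intervals, sites, config = dielflux_config(),
                       w_fn = transect_width) {
  hours <- seq(
    as.POSIXct(paste(config$period[1], "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(config$period[2], "23:00:00"), tz = "UTC"),
    by = 3600
  )
  purrr::map_dfr(unique(sites$site_id), function(sid) {
    sub <- echoes[echoes$site_id == sid, , drop = FALSE]
    keep <- !in_rain(sub$timestamp_utc, intervals, sid)
    sub <- sub[keep, , drop = FALSE]
    w <- if (nrow(sub) > 0) w_fn(sub$altitude_agl_m) else numeric(0)
    hr <- floor(as.numeric(sub$timestamp_utc) / 3600) * 3600
    contrib <- vapply(split(1 / w, hr), sum, numeric(1))
    counts <- vapply(split(w, hr), length, numeric(1))
    prot <- intervals[intervals$site_id == sid &
                        intervals$kind == "protocol_shortpulse", , drop = FALSE]
    eff <- vapply(seq_along(hours), function(i) {
      overlap_seconds(prot, hours[i], hours[i] + 3600) / 60
    }, numeric(1))
    key <- as.character(as.numeric(hours))
    s <- unname(contrib[key])
    s[is.na(s)] <- 0
    n <- unname(counts[key])
    n[is.na(n)] <- 0
    mtr <- ifelse(eff >= 60 * config$min_monitoring_fraction,
                  s * 60 / eff, NA_real_)
    tibble::tibble(site_id = sid, hour_start_utc = hours, mtr = mtr,
                   n_echoes = as.integer(n), effective_min = eff)
  })
}

# which timestamps fall inside a site's rain intervals
in_rain <- function(timestamps, intervals, site) {
  rain <- intervals[intervals$site_id == site & intervals$kind == "rain", ,
                    drop = FALSE]
  if (nrow(rain) == 0 || length(timestamps) == 0) {
    return(rep(FALSE, length(timestamps)))
  }
  rain <- dplyr::arrange(rain, .data$start_utc)
  idx <- findInterval(as.numeric(timestamps), as.numeric(rain$start_utc))
  idx > 0 & as.numeric(timestamps) < as.numeric(rain$end_utc)[pmax(idx, 1)]
}

#' Phase-wise traffic aggregates per diel day
#'
#' For every site, diel day and phase: the mean traffic rate (insects per km
#' per hour, echo contributions summed over the phase and divided by the
#' effective monitoring hours) and the total traffic (mean rate times the
#' phase duration, i.e. insects per km passing during the whole phase).
#' Aggregates are computed at echo level against the exact phase boundaries,
#' not by resampling hourly bins. A phase monitored for less than
#' `min_monitoring_fraction` of its duration is `NA`. Rain follows the same
#' zero-traffic rule as [hourly_mtr()].
#'
#' @param echoes insect-filtered echo tibble.
#' @param phase_intervals tibble from [diel_phases()] for the same sites.
#' @param intervals normalized interval tibble.
#' @param config a [dielflux_config()].
#' @inheritParams hourly_mtr
#' @return tibble `site_id, anchor_date, phase, mean_rate, total_traffic,
#'   duration_h, effective_h`.
#' @export
phase_aggregates <- function(echoes, phase_intervals, intervals,
                             config = dielflux_config(),
                             w_fn = transect_width) {
  purrr::map_dfr(unique(phase_intervals$site_id), function(sid) {
    ph <- phase_intervals[phase_intervals$site_id == sid, , drop = FALSE]
    sub <- echoes[echoes$site_id == sid, , drop = FALSE]
    sub <- sub[!in_rain(sub$timestamp_utc, intervals, sid), , drop = FALSE]
    w <- if (nrow(sub) > 0) w_fn(sub$altitude_agl_m) else numeric(0)
    tnum <- as.numeric(sub$timestamp_utc)
    prot <- intervals[intervals$site_id == sid &
                        intervals$kind == "protocol_shortpulse", , drop = FALSE]
    res <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
      s0 <- as.numeric(ph$start_utc[i]); e0 <- as.numeric(ph$end_utc[i])
      inside <- tnum >= s0 & tnum < e0
      contrib <- sum(1 / w[inside])
      duration_h <- (e0 - s0) / 3600
      effective_h <- overlap_seconds(prot, ph$start_utc[i], ph$end_utc[i]) / 3600
      if (effective_h < config$min_monitoring_fraction * duration_h ||
          effective_h <= 0) {
        mean_rate <- NA_real_
        total <- NA_real_
      } else {
        mean_rate <- contrib / effective_h
        total <- mean_rate * duration_h
      }
      tibble::tibble(
        site_id = sid, anchor_date = ph$anchor_date[i], phase = ph$phase[i],
        mean_rate = mean_rate, total_traffic = total,
        duration_h = duration_h, effective_h = effective_h
      )
    })
    res
  })
}
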