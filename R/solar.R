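#' Geometric solar elevation
#'
#' Elevation of the geometric sun centre (no atmospheric refraction) using a
#' standard low-accuracy ephemeris (NOAA/Meeus class: apparent solar
#' longitude, corrected obliquity, equation of time). Absolute error is well
#' under 0.2 degrees for years 1950-2100, which is ample for diel-phase
#' boundaries that span tens of minutes.
#'
#' @param lat,lon decimal degrees; longitude east positive.
#' @param time `POSIXct` (UTC) instant(s); vectorized.
#' @return numeric vector of elevations in degrees, negative below the
#'   horizon.
#' @examples
#' solar_elevation(47, 8, as.POSIXct("2021-06-21 12:00:00", tz = "UTC"))
#' @export
solar_elevation <- function(lat, lon, time) {
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  s <- sun_position(time)
  rad <- pi / 180
  minutes <- (as.numeric(time) %% 86400) / 60
  tst <- (minutes + s$eot_min + 4 * lon) %% 1440
  ha <- tst / 4 - 180 # degrees; negative before solar noon
  sin_el <- sin(lat * rad) * sin(s$decl * rad) +
    cos(lat * rad) * cos(s$decl * rad) * cos(ha * rad)
  asin(pmin(1, pmax(-1, sin_el))) / rad
}

# declination (deg) and equation of time (min) at UTC instants
sun_position <- function(time) {
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525
  l0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  c <- sin(m * rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * m * rad) * (0.019993 - 0.000101 * t) +
    sin(3 * m * rad) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * rad)
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * rad)
  decl <- asin(sin(eps * rad) * sin(app_long * rad)) / rad
  y <- tan(eps * rad / 2)^2
  eot <- 4 / rad * (y * sin(2 * l0 * rad) - 2 * ecc * sin(m * rad) +
                      4 * ecc * y * sin(m * rad) * cos(2 * l0 * rad) -
                      0.5 * y^2 * sin(4 * l0 * rad) -
                      1.25 * ecc^2 * sin(2 * m * rad))
  list(decl = decl, eot_min = eot)
}

# UTC instant of local solar noon on a calendar date (iterated once so the
# equation of time is evaluated near the answer)
solar_noon_utc <- function(lon, date) {
  approx <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - lon * 240
  for (i in 1:2) {
    s <- sun_position(approx)
    approx <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
      60 * (720 - s$eot_min - 4 * lon)
  }
  approx
}

#' Solar elevation threshold crossings within one diel cycle
#'
#' Finds the instants at which the solar elevation crosses `threshold_deg`
#' upward (morning side, between the preceding solar midnight and solar noon
#' of `anchor_date`) and downward (evening side, between solar noon and the
#' following solar midnight). Elevation is monotone on each half-cycle away
#' from the poles, so each crossing is unique. Accuracy is better than one
#' second of time (root refinement on the ephemeris).
#'
#' @param lat,lon decimal degrees.
#' @param anchor_date `Date`, the diel cycle whose noon anchors the search.
#' @param threshold_deg elevation threshold in degrees; a threshold the sun
#'   never reaches on that side yields `NA`.
#' @return one-row tibble with `POSIXct` columns `up` and `down`; `NA` when
#'   the threshold is not crossed on that side.
#' @export
crossing_times <- function(lat, lon, anchor_date, threshold_deg) {
  stopifnot(threshold_deg >= -90, threshold_deg <= 90)
  noon <- solar_noon_utc(lon, anchor_date)
  f <- function(t) solar_elevation(lat, lon, utc_time(t)) - threshold_deg
  find <- function(a, b) {
    fa <- f(a); fb <- f(b)
    if (is.na(fa) || is.na(fb) || fa * fb > 0) return(NA_real_)
    stats::uniroot(f, c(a, b), tol = 0.5)$root
  }
  n <- as.numeric(noon)
  up <- find(n - 43200, n)
  down <- find(n, n + 43200)
  tibble::tibble(up = utc_time(up), down = utc_time(down))
}

#' Solar events for one site and date
#'
#' Nautical dawn/dusk (sun centre crossing `twilight_threshold_deg`, default
#' -12 degrees) and sunrise/sunset (geometric sun centre at 0 degrees) on
#' `anchor_date`, plus flags: `no_night` when the sun stays above the
#' twilight threshold through the following night (high-latitude summer),
#' `polar_day` / `polar_night` when it never sets below or rises above the
#' horizon.
#'
#' @inheritParams crossing_times
#' @param twilight_threshold_deg twilight boundary elevation, degrees.
#' @return one-row tibble: `anchor_date`, `nautical_dawn`, `sunrise`,
#'   `sunset`, `nautical_dusk`, `noon`, `no_night`, `polar_day`,
#'   `polar_night`.
#' @export
solar_events <- function(lat, lon, anchor_date, twilight_threshold_deg = -12) {
  horiz <- crossing_times(lat, lon, anchor_date, 0)
  twil <- crossing_times(lat, lon, anchor_date, twilight_threshold_deg)
  noon <- solar_noon_utc(lon, anchor_date)
  noon_el <- solar_elevation(lat, lon, noon)
  polar_day <- is.na(horiz$up) && noon_el > 0
  polar_night <- is.na(horiz$up) && noon_el <= 0
  no_night <- !is.na(horiz$down) && is.na(twil$down)
  tibble::tibble(
    anchor_date = anchor_date,
    nautical_dawn = twil$up, sunrise = horiz$up,
    sunset = horiz$down, nautical_dusk = twil$down,
    noon = noon,
    no_night = no_night, polar_day = polar_day, polar_night = polar_night
  )
}

#' Diel-phase intervals per site and diel day
#'
#' Partitions each diel day (nautical dawn to the next nautical dawn) into
#' crepuscular morning (nautical dawn to sunrise), day (sunrise to sunset),
#' crepuscular evening (sunset to nautical dusk) and night (nautical dusk to
#' the next nautical dawn). On high-latitude dates with no nautical night
#' the sunset-to-next-sunrise span is all twilight; it is split at its clock
#' midpoint into crepuscular evening then crepuscular morning (of the next
#' diel day) and no night interval is emitted. Polar day yields a single
#' `day` interval spanning the diel cycle.
#'
#' Intervals are half-open `[start, end)`: a boundary instant belongs to the
#' later phase. Per site the intervals of consecutive anchor dates chain
#' exactly, so their union partitions the whole period.
#'
#' @param sites tibble with `site_id, lat_deg, lon_deg` (one or more rows).
#' @param dates `Date` vector of anchor dates.
#' @param config a [dielflux_config()]; supplies the twilight threshold.
#' @return tibble `site_id, anchor_date, phase, start_utc, end_utc,
#'   duration_s`, ordered morning, day, evening, night within each diel day.
#' @examples
#' sites <- tibble::tibble(site_id = "ch", lat_deg = 47, lon_deg = 8)
#' diel_phases(sites, as.Date("2021-04-15"))
#' @export
diel_phases <- function(sites, dates, config = dielflux_config()) {
  dates <- sort(unique(as.Date(dates)))
  thr <- config$twilight_threshold_deg
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    lat <- sites$lat_deg[i]
    lon <- sites$lon_deg[i]
    # events for each anchor date plus its neighbours (diel-day boundaries)
    all_dates <- sort(unique(c(dates - 1, dates, dates + 1)))
    ev <- purrr::map_dfr(all_dates, function(d) solar_events(lat, lon, d, thr))
    purrr::map_dfr(dates, function(d) {
      ep <- ev[ev$anchor_date == d - 1, ]
      e0 <- ev[ev$anchor_date == d, ]
      e1 <- ev[ev$anchor_date == d + 1, ]
      ph <- diel_phases_one(ep, e0, e1)
      if (nrow(ph) == 0) return(ph)
      tibble::tibble(
        site_id = sites$site_id[i], anchor_date = d,
        phase = ph$phase, start_utc = ph$start, end_utc = ph$end,
        duration_s = as.numeric(ph$end) - as.numeric(ph$start)
      )
    })
  })
}

# phase intervals of one diel day from the previous, current and next day's
# solar events; start(d) and end(d) = start(d+1) are computed by the same
# rule from the same events, so consecutive diel days chain exactly
diel_phases_one <- function(ep, e0, e1) {
  iv <- function(phase, start, end) {
    tibble::tibble(phase = phase, start = start, end = end)
  }
  day_start <- diel_day_start(ep, e0)
  day_end <- diel_day_start(e0, e1)
  if (e0$polar_day) {
    return(iv("day", day_start, day_end))
  }
  if (e0$polar_night && is.na(e0$nautical_dawn)) {
    return(iv("night", day_start, day_end))
  }
  out <- list()
  if (e0$polar_night) {
    # crepuscular-only day (sun between the twilight threshold and the
    # horizon): split the twilight span at its midpoint
    mid <- midpoint(e0$nautical_dawn, e0$nautical_dusk)
    out <- list(iv("crepuscular_morning", day_start, mid),
                iv("crepuscular_evening", mid, e0$nautical_dusk),
                iv("night", e0$nautical_dusk, day_end))
    return(dplyr::bind_rows(out))
  }
  out[[1]] <- iv("crepuscular_morning", day_start, e0$sunrise)
  out[[2]] <- iv("day", e0$sunrise, e0$sunset)
  if (e0$no_night) {
    # sun stays above the twilight threshold all night: the evening half of
    # the sunset -> next-sunrise span; its second half opens the next diel
    # day as crepuscular morning (day_end is that same midpoint)
    out[[3]] <- iv("crepuscular_evening", e0$sunset, day_end)
  } else {
    out[[3]] <- iv("crepuscular_evening", e0$sunset, e0$nautical_dusk)
    out[[4]] <- iv("night", e0$nautical_dusk, day_end)
  }
  dplyr::bind_rows(out)
}

# where the diel day anchored on e$anchor_date begins: nautical dawn; or the
# clock midpoint of the previous sunset -> sunrise twilight span when that
# night never reached the twilight threshold; or solar midnight in polar
# regimes
diel_day_start <- function(e_prev, e) {
  if (!is.na(e$nautical_dawn)) return(e$nautical_dawn)
  if (!is.na(e$sunrise) && nrow(e_prev) == 1 && !is.na(e_prev$sunset)) {
    return(midpoint(e_prev$sunset, e$sunrise))
  }
  midpoint(e$noon - 86400, e$noon)
}

midpoint <- function(a, b) utc_time((as.numeric(a) + as.numeric(b)) / 2)

#' Assign diel phase labels to timestamps
#'
#' Labels each timestamp with the phase and anchor date of the half-open
#' interval `[start, end)` containing it.
#'
#' @param timestamps `POSIXct` vector.
#' @param phase_intervals tibble from [diel_phases()] (one site).
#' @return tibble `timestamp_utc, phase, anchor_date`; errors if any
#'   timestamp is not covered.
#' @export
assign_phase <- function(timestamps, phase_intervals) {
  pi_ <- dplyr::arrange(phase_intervals, .data$start_utc)
  idx <- findInterval(as.numeric(timestamps), as.numeric(pi_$start_utc))
  bad <- idx == 0 | (idx > 0 & as.numeric(timestamps) >=
                       as.numeric(pi_$end_utc)[pmax(idx, 1)])
  if (any(bad)) {
    stop(sum(bad), " timestamp(s) outside the supplied diel-phase intervals",
         call. = FALSE)
  }
  tibble::tibble(
    timestamp_utc = timestamps,
    phase = pi_$phase[idx],
    anchor_date = pi_$anchor_date[idx]
  )
}
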