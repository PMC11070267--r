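# Independent oracles and fixture builders used across the suite.

# random echo tibble (valid rows) for round-trip tests
random_echoes <- function(n, seed = 1) {
  set.seed(seed)
  p_ins <- runif(n, 0.05, 0.95)
  rest <- (1 - p_ins) * runif(n)
  tibble::tibble(
    site_id = sample(c("aa", "bb"), n, replace = TRUE),
    timestamp_utc = as.POSIXct("2021-06-01", tz = "UTC") +
      round(runif(n, 0, 86400 * 30)),
    altitude_agl_m = runif(n, 10, 900),
    p_insect = p_ins,
    p_bird = rest,
    p_nonbio = (1 - p_ins) - rest,
    rcs_max_cm2 = rlnorm(n, log(0.2), 1)
  )
}

# minute-set oracle: total covered whole-minute duration of intervals
minute_set_minutes <- function(start_utc, end_utc) {
  mins <- unique(unlist(mapply(
    function(s, e) seq(floor(s / 60), ceiling(e / 60) - 1),
    as.numeric(start_utc), as.numeric(end_utc), SIMPLIFY = FALSE
  )))
  length(mins)
}

# independent solar elevation via right ascension and Greenwich sidereal
# time -- a different route to the hour angle than the package's
# equation-of-time shortcut
sidereal_elevation <- function(lat, lon, time) {
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525
  l0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  c <- sin(m * rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * m * rad) * (0.019993 - 0.000101 * t) +
    sin(3 * m * rad) * 0.000289
  omega <- 125.04 - 1934.136 * t
  lam <- (l0 + c - 0.00569 - 0.00478 * sin(omega * rad)) * rad
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega * rad)) * rad
  ra <- atan2(cos(eps) * sin(lam), cos(lam)) / rad
  decl <- asin(sin(eps) * sin(lam))
  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545) +
             0.000387933 * t^2 - t^3 / 38710000) %% 360
  ha <- ((gmst + lon - ra + 540) %% 360 - 180) * rad
  asin(sin(lat * rad) * sin(decl) +
         cos(lat * rad) * cos(decl) * cos(ha)) / rad
}

# coarse independent check: Spencer (1971) Fourier-series declination and
# equation of time (accurate to a few tenths of a degree)
spencer_elevation <- function(lat, lon, time) {
  doy <- as.POSIXlt(time, tz = "UTC")$yday
  frac_day <- (as.numeric(time) %% 86400) / 86400
  g <- 2 * pi / 365 * (doy + frac_day - 0.5)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot_min <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                         0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- ((as.numeric(time) %% 86400) / 60 + eot_min + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)) * 180 / pi
}

# 1 s brute-force threshold crossing around a given noon (numeric seconds)
brute_crossings <- function(lat, lon, noon_num, threshold,
                            elev_fn = dielflux::solar_elevation) {
  half <- 43200
  up_t <- down_t <- NA_real_
  for (side in c("up", "down")) {
    rng <- if (side == "up") c(noon_num - half, noon_num) else
      c(noon_num, noon_num + half)
    tt <- seq(rng[1], rng[2], by = 1)
    e <- elev_fn(lat, lon, as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"))
    cross <- if (side == "up") which(e[-1] >= threshold & e[-length(e)] < threshold)
    else which(e[-1] < threshold & e[-length(e)] >= threshold)
    val <- if (length(cross) > 0) tt[cross[1] + 1] else NA_real_
    if (side == "up") up_t <- val else down_t <- val
  }
  c(up = up_t, down = down_t)
}

# elevation-based diel phase oracle for sites/dates with a real night:
# day if e >= 0, night if e < -12, else crepuscular by rising/setting side
oracle_phase <- function(lat, lon, time) {
  e <- dielflux::solar_elevation(lat, lon, time)
  e2 <- dielflux::solar_elevation(lat, lon, time + 30)
  rising <- e2 > e
  dplyr::case_when(
    e >= 0 ~ "day",
    e < -12 ~ "night",
    rising ~ "crepuscular_morning",
    TRUE ~ "crepuscular_evening"
  )
}

# exhaustive Holm step-down: sort, multiply, enforce monotone, restore order
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# small site tables
mid_lat_site <- function() {
  tibble::tibble(site_id = "ch", name = "Mid", lat_deg = 47, lon_deg = 8,
                 elev_m = 450)
}
north_site <- function() {
  tibble::tibble(site_id = "hel", name = "North", lat_deg = 60.17,
                 lon_deg = 24.94, elev_m = 10)
}

# full-coverage protocol interval for a site over a date span
full_protocol <- function(site_id, from, to) {
  tibble::tibble(
    site_id = site_id, kind = "protocol_shortpulse",
    start_utc = as.POSIXct(paste(from, "00:00:00"), tz = "UTC") - 86400,
    end_utc = as.POSIXct(paste(to, "00:00:00"), tz = "UTC") + 2 * 86400
  )
}

# echo rows at given times/altitudes for traffic arithmetic tests
echo_rows <- function(site_id, times, altitude = 200) {
  n <- length(times)
  tibble::tibble(
    site_id = site_id, timestamp_utc = times,
    altitude_agl_m = rep_len(altitude, n),
    p_insect = 0.9, p_bird = 0.05, p_nonbio = 0.05, rcs_max_cm2 = 0.2
  )
}
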