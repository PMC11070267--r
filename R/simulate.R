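#' Parameters of the synthetic radar-echo generator
#'
#' Defaults emulate the diel and seasonal structure of mid-European insect
#' migration as seen by a vertical-looking radar: a daytime component
#' peaking at local noon, a pronounced peak during evening twilight around
#' a solar elevation of -6 degrees, a smaller dawn peak, a low nocturnal
#' plateau, a Gaussian seasonal envelope peaking in mid July, lognormal
#' radar cross sections with a heavier night component, gamma-distributed
#' flight altitudes shifted upward at night, a small fraction of bird and
#' non-biological contaminant echoes, and occasional rain and monitoring
#' outages.
#'
#' @param peak_flux seasonal peak of the true linear flux density, insects
#'   per km per hour, scaling the daytime component.
#' @param base_flux season-independent floor of the flux density.
#' @param season_center_doy,season_width_days centre (day of year) and SD of
#'   the Gaussian seasonal envelope.
#' @param a_day,a_dusk,a_dawn,a_night relative weights of the diel
#'   components (all >= 0).
#' @param day_exponent exponent on `sin(elevation)` for the day component.
#' @param twilight_peak_elev_deg,twilight_peak_width_deg centre and SD (in
#'   solar-elevation degrees) of the Gaussian dusk/dawn peaks.
#' @param rcs_meanlog,rcs_sdlog lognormal RCS parameters (cm^2) of the day
#'   regime.
#' @param rcs_night_multiplier multiplicative shift of the night-regime RCS
#'   median (> 1 makes night echoes larger).
#' @param alt_shape gamma shape of the altitude distribution.
#' @param alt_mean_day_m,alt_night_shift_m day-regime mean altitude (m above
#'   the radar) and the additive night shift.
#' @param rain_per_day expected rain intervals per day (Poisson).
#' @param rain_duration_min mean rain-interval duration (exponential).
#' @param outage_per_day expected monitoring outages per day (Poisson).
#' @param outage_duration_min mean outage duration (exponential).
#' @param contam_bird_frac,contam_nonbio_frac contaminant echo counts as a
#'   fraction of the insect echo count.
#' @param seed integer seed; may also be supplied to [simulate_site()].
#' @return list of class `dielflux_sim_params`.
#' @export
sim_params <- function(peak_flux = 300,
                       base_flux = 5,
                       season_center_doy = 196,
                       season_width_days = 60,
                       a_day = 1, a_dusk = 1.2, a_dawn = 0.3, a_night = 0.25,
                       day_exponent = 1,
                       twilight_peak_elev_deg = -6,
                       twilight_peak_width_deg = 3,
                       rcs_meanlog = log(0.1), rcs_sdlog = 1,
                       rcs_night_multiplier = 3,
                       alt_shape = 6,
                       alt_mean_day_m = 160, alt_night_shift_m = 40,
                       rain_per_day = 0.15, rain_duration_min = 90,
                       outage_per_day = 0.05, outage_duration_min = 180,
                       contam_bird_frac = 0.05, contam_nonbio_frac = 0.05,
                       seed = NULL) {
  stopifnot(a_day >= 0, a_dusk >= 0, a_dawn >= 0, a_night >= 0,
            peak_flux >= 0, base_flux >= 0, rcs_night_multiplier > 0,
            alt_shape > 0, alt_mean_day_m > 0)
  structure(as.list(environment()), class = "dielflux_sim_params")
}

#' True diel flux density of the generator
#'
#' The inhomogeneous rate the generator samples from, in insects per km per
#' hour: a seasonal Gaussian envelope times a mixture of a daytime component
#' (`a_day * max(0, sin e)^k`), Gaussian dusk and dawn peaks in solar
#' elevation (applied on the setting and rising side respectively), and a
#' nocturnal plateau below -12 degrees.
#'
#' @param lat,lon site coordinates, decimal degrees.
#' @param times `POSIXct` (UTC) instants; vectorized.
#' @param params a [sim_params()].
#' @return numeric vector, insects per km per hour.
#' @export
diel_intensity <- function(lat, lon, times, params = sim_params()) {
  e <- solar_elevation(lat, lon, times)
  s <- sun_position(times)
  minutes <- (as.numeric(times) %% 86400) / 60
  ha <- ((minutes + s$eot_min + 4 * lon) %% 1440) / 4 - 180
  setting <- as.numeric(ha > 0)
  rising <- 1 - setting
  doy <- lubridate::yday(lubridate::as_date(times))
  seasonal <- params$base_flux + params$peak_flux *
    exp(-(doy - params$season_center_doy)^2 / (2 * params$season_width_days^2))
  gpk <- exp(-(e - params$twilight_peak_elev_deg)^2 /
               (2 * params$twilight_peak_width_deg^2))
  shape <- params$a_day * pmax(0, sin(e * pi / 180))^params$day_exponent +
    params$a_dusk * gpk * setting +
    params$a_dawn * gpk * rising +
    params$a_night * (e < -12)
  seasonal * shape
}

#' Simulate one site's radar echoes with ground truth
#'
#' Echo times are drawn from an inhomogeneous Poisson process whose rate is
#' [diel_intensity()] held piecewise-constant over 1 min steps, thinned by
#' the altitude-dependent detection transect `w(h)` — the same
#' [transect_width()] the traffic estimator divides by, so the estimator is
#' unbiased for the true flux by construction. Altitudes are truncated-gamma
#' within the altitude band (night regime shifted upward), RCS is lognormal
#' (night regime scaled up), insect class probabilities are noisy but stay
#' above the filter threshold, and bird / non-biological contaminants are
#' added below it. Rain intervals and monitoring outages are generated as
#' marked intervals; outages remove both echoes and protocol coverage.
#'
#' Per-phase ground truth (expected total traffic and mean rate) is the
#' exact integral of the piecewise-constant rate over each diel-phase
#' interval, plus the detection-weighted true RCS medians and altitude
#' means per regime.
#'
#' @param site one-row tibble with `site_id, lat_deg, lon_deg`.
#' @param dates `Date` vector of simulated anchor dates (diel days).
#' @param params a [sim_params()].
#' @param seed integer seed (falls back to `params$seed`); mandatory.
#' @param config a [dielflux_config()] (altitude band, twilight threshold).
#' @return list with tibbles `echoes` (echo-table schema plus
#'   `truth_label`), `intervals` (protocol + rain + outage rows) and `truth`
#'   (`site_id, anchor_date, phase, true_total_traffic, true_mean_rate,
#'   duration_h, true_rcs_median, true_alt_mean`).
#' @export
simulate_site <- function(site, dates, params = sim_params(),
                          seed = params$seed, config = dielflux_config()) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(nrow(site) == 1)
  set.seed(as.integer(seed %% .Machine$integer.max))
  dates <- sort(as.Date(dates))
  lat <- site$lat_deg[1]; lon <- site$lon_deg[1]
  band <- config$altitude_band

  # diel-day span: phases chain from the first to the last anchor date
  phases <- diel_phases(site, dates, config)
  span0 <- min(phases$start_utc)
  span1 <- max(phases$end_utc)

  # piecewise-constant rate on a 1 min grid (evaluated at step midpoints)
  grid <- seq(as.numeric(span0), as.numeric(span1) - 1, by = 60)
  lam <- diel_intensity(lat, lon, utc_time(grid + 30), params)

  # candidate events at rate lambda * w_max, thinned by w(h) / w_max
  w_max <- transect_width(band[2])
  n_cand <- rpois(length(grid), lam * w_max / 60)
  cand_t <- rep(grid, n_cand) + runif(sum(n_cand)) * 60
  e_cand <- solar_elevation(lat, lon, utc_time(cand_t))
  night <- e_cand < -12
  alt <- sample_trunc_gamma(length(cand_t), params$alt_shape,
                            mean_m = params$alt_mean_day_m +
                              params$alt_night_shift_m * night,
                            lower = band[1], upper = band[2])
  keep <- runif(length(cand_t)) < transect_width(alt) / w_max
  t_ins <- cand_t[keep]; alt_ins <- alt[keep]; night_ins <- night[keep]
  n_ins <- length(t_ins)
  rcs_ins <- rlnorm(n_ins, params$rcs_meanlog +
                      log(params$rcs_night_multiplier) * night_ins,
                    params$rcs_sdlog)
  # classifier noise that never drops a true insect below the filter
  p_ins <- runif(n_ins, 0.55, 0.98)
  rest <- (1 - p_ins) * runif(n_ins, 0.2, 0.8)
  insects <- tibble::tibble(
    site_id = site$site_id[1], timestamp_utc = utc_time(t_ins),
    altitude_agl_m = alt_ins, p_insect = p_ins, p_bird = rest,
    p_nonbio = (1 - p_ins) - rest, rcs_max_cm2 = rcs_ins,
    truth_label = "insect"
  )
  contam <- simulate_contaminants(site$site_id[1], span0, span1, n_ins,
                                  band, params)
  echoes <- dplyr::arrange(dplyr::bind_rows(insects, contam),
                           .data$timestamp_utc)

  # rain and outage intervals; protocol = span minus outages
  rain <- random_intervals(site$site_id[1], "rain", span0, span1,
                           params$rain_per_day, params$rain_duration_min)
  outage <- random_intervals(site$site_id[1], "outage", span0, span1,
                             params$outage_per_day,
                             params$outage_duration_min)
  protocol <- subtract_span(site$site_id[1], "protocol_shortpulse",
                            span0, span1, outage)
  intervals <- merge_intervals(dplyr::bind_rows(protocol, rain, outage))
  # echoes are not recorded during outages
  off <- rep(FALSE, nrow(echoes))
  out_iv <- intervals[intervals$kind == "outage", , drop = FALSE]
  for (i in seq_len(nrow(out_iv))) {
    off <- off | (echoes$timestamp_utc >= out_iv$start_utc[i] &
                    echoes$timestamp_utc < out_iv$end_utc[i])
  }
  echoes <- echoes[!off, , drop = FALSE]

  truth <- truth_records(site, phases, grid, lam, params, band)
  list(echoes = echoes, intervals = intervals, truth = truth)
}

# exact per-phase integral of the piecewise-constant rate, plus regime truth
truth_records <- function(site, phases, grid, lam, params, band) {
  cum <- c(0, cumsum(lam / 60)) # insects/km after each whole minute
  g0 <- grid[1]
  integral <- function(a, b) {
    # integral of the step rate over [a, b] in insects/km
    ia <- (as.numeric(a) - g0) / 60
    ib <- (as.numeric(b) - g0) / 60
    fa <- pmin(pmax(ia, 0), length(lam)); fb <- pmin(pmax(ib, 0), length(lam))
    step_int <- function(x) {
      k <- floor(x)
      cum[k + 1] + (x - k) * lam[pmin(k + 1, length(lam))] / 60
    }
    step_int(fb) - step_int(fa)
  }
  alt_truth <- function(is_night) {
    detection_weighted_alt_mean(params$alt_shape,
                                params$alt_mean_day_m +
                                  params$alt_night_shift_m * is_night,
                                band[1], band[2])
  }
  phases |>
    dplyr::mutate(
      true_total_traffic = purrr::map2_dbl(.data$start_utc, .data$end_utc,
                                           integral),
      duration_h = .data$duration_s / 3600,
      true_mean_rate = .data$true_total_traffic / .data$duration_h,
      true_rcs_median = exp(params$rcs_meanlog +
                              log(params$rcs_night_multiplier) *
                              (.data$phase == "night")),
      true_alt_mean = ifelse(.data$phase == "night", alt_truth(TRUE),
                             alt_truth(FALSE))
    ) |>
    dplyr::select("site_id", "anchor_date", "phase", "true_total_traffic",
                  "true_mean_rate", "duration_h", "true_rcs_median",
                  "true_alt_mean")
}

# gamma truncated to [lower, upper] by inverse-CDF sampling; mean_m may be a
# vector (per-draw regime)
sample_trunc_gamma <- function(n, shape, mean_m, lower, upper) {
  if (n == 0) return(numeric(0))
  rate <- shape / mean_m
  plo <- stats::pgamma(lower, shape, rate)
  phi <- stats::pgamma(upper, shape, rate)
  stats::qgamma(plo + runif(n) * (phi - plo), shape, rate)
}

# E[h | detected] under w(h)-proportional detection of a truncated gamma
detection_weighted_alt_mean <- function(shape, mean_m, lower, upper) {
  rate <- shape / mean_m
  f <- function(h) stats::dgamma(h, shape, rate)
  num <- stats::integrate(function(h) h * h * f(h), lower, upper)$value
  den <- stats::integrate(function(h) h * f(h), lower, upper)$value
  num / den
}

simulate_contaminants <- function(sid, span0, span1, n_ins, band, params) {
  n_bird <- rpois(1, n_ins * params$contam_bird_frac)
  n_non <- rpois(1, n_ins * params$contam_nonbio_frac)
  if (n_bird + n_non == 0) {
    return(tibble::tibble(
      site_id = character(), timestamp_utc = utc_time(numeric()),
      altitude_agl_m = numeric(), p_insect = numeric(),
      p_bird = numeric(), p_nonbio = numeric(), rcs_max_cm2 = numeric(),
      truth_label = character()
    ))
  }
  t_all <- as.numeric(span0) +
    runif(n_bird + n_non) * (as.numeric(span1) - as.numeric(span0))
  p_self <- runif(n_bird + n_non, 0.5, 0.95)
  p_ins <- (1 - p_self) * runif(n_bird + n_non, 0.1, 0.6)
  is_bird <- rep(c(TRUE, FALSE), c(n_bird, n_non))
  tibble::tibble(
    site_id = sid, timestamp_utc = utc_time(t_all),
    altitude_agl_m = runif(n_bird + n_non, band[1], band[2] * 1.2),
    p_insect = p_ins,
    p_bird = ifelse(is_bird, p_self, (1 - p_self) - p_ins),
    p_nonbio = ifelse(is_bird, (1 - p_self) - p_ins, p_self),
    rcs_max_cm2 = rlnorm(n_bird + n_non, log(5), 1),
    truth_label = ifelse(is_bird, "bird", "nonbio")
  )
}

random_intervals <- function(sid, kind, span0, span1, per_day, mean_min) {
  days <- (as.numeric(span1) - as.numeric(span0)) / 86400
  n <- rpois(1, per_day * days)
  if (n == 0) {
    return(tibble::tibble(site_id = character(), kind = character(),
                          start_utc = utc_time(numeric()),
                          end_utc = utc_time(numeric())))
  }
  start <- as.numeric(span0) + runif(n) * (as.numeric(span1) -
                                             as.numeric(span0))
  dur <- stats::rexp(n, 1 / (mean_min * 60))
  tibble::tibble(site_id = sid, kind = kind, start_utc = utc_time(start),
                 end_utc = utc_time(pmin(start + dur, as.numeric(span1))))
}

# the full span minus the union of the given intervals
subtract_span <- function(sid, kind, span0, span1, remove) {
  rem <- merge_intervals(remove)
  bounds <- c(as.numeric(span0),
              rbind(as.numeric(rem$start_utc), as.numeric(rem$end_utc)),
              as.numeric(span1))
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  tibble::tibble(site_id = sid, kind = kind,
                 start_utc = utc_time(starts[keep]),
                 end_utc = utc_time(ends[keep]))
}

#' Simulate a network of radar sites
#'
#' Runs [simulate_site()] for every row of `sites` with an independent
#' per-site random stream derived deterministically from the master seed and
#' the site id, so adding or reordering sites does not perturb the others.
#' Optionally writes the combined `echoes.csv`, `intervals.csv`,
#' `sites.csv` and `truth.csv` to a directory.
#'
#' @param sites tibble with `site_id, lat_deg, lon_deg` (unique ids).
#' @param dates `Date` vector of anchor dates.
#' @param params a [sim_params()], or a named list of one per site id.
#' @param seed master integer seed.
#' @param config a [dielflux_config()].
#' @param out_dir optional output directory.
#' @return list with combined `echoes`, `intervals`, `truth` tibbles (and
#'   `sites`).
#' @export
simulate_network <- function(sites, dates, params = sim_params(), seed,
                             config = dielflux_config(), out_dir = NULL) {
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id", call. = FALSE)
  res <- purrr::map(seq_len(nrow(sites)), function(i) {
    p <- if (inherits(params, "dielflux_sim_params")) params else
      params[[sites$site_id[i]]]
    simulate_site(sites[i, ], dates, p,
                  seed = site_seed(seed, sites$site_id[i]), config = config)
  })
  out <- list(
    echoes = purrr::map_dfr(res, "echoes"),
    intervals = purrr::map_dfr(res, "intervals"),
    truth = purrr::map_dfr(res, "truth"),
    sites = sites
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_echo_table(out$echoes, file.path(out_dir, "echoes.csv"))
    write_intervals(out$intervals, file.path(out_dir, "intervals.csv"))
    readr::write_csv(sites, file.path(out_dir, "sites.csv"), progress = FALSE)
    readr::write_csv(
      dplyr::mutate(out$truth,
                    anchor_date = format(.data$anchor_date)),
      file.path(out_dir, "truth.csv"), progress = FALSE)
  }
  out
}

# deterministic 31-bit sub-seed from master seed and site id
site_seed <- function(seed, site_id) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(site_id)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}
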