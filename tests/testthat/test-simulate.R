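sim_dates <- function(n = 3, from = "2021-07-01") {
  seq(as.Date(from), by = "day", length.out = n)
}

test_that("diel intensity follows its components and integrates to truth", {
  p0 <- sim_params(a_day = 0, a_dusk = 0, a_dawn = 0, a_night = 0)
  tt <- as.POSIXct("2021-07-01 12:00:00", tz = "UTC") + 0:23 * 3600
  expect_equal(diel_intensity(47, 8, tt, p0), rep(0, 24))

  p1 <- sim_params(a_day = 1, a_dusk = 0, a_dawn = 0, a_night = 0)
  noon <- dielflux:::solar_noon_utc(8, as.Date("2021-07-01"))
  expect_gt(diel_intensity(47, 8, noon, p1), 0)
  # night-time day-component is zero
  expect_equal(diel_intensity(47, 8, noon + 12 * 3600, p1), 0)

  # 1 s Riemann sums over each phase reproduce the stored truth totals
  site <- mid_lat_site()
  cfg <- dielflux_config(period = as.Date(c("2021-07-01", "2021-07-01")))
  p <- sim_params(rain_per_day = 0, outage_per_day = 0)
  sim <- simulate_site(site, sim_dates(1), p, seed = 5, config = cfg)
  for (i in seq_len(nrow(sim$truth))) {
    ph <- sim$truth[i, ]
    iv <- diel_phases(site, sim_dates(1), cfg)
    row <- iv[iv$phase == ph$phase, ]
    tt <- seq(as.numeric(row$start_utc), as.numeric(row$end_utc) - 1, by = 1)
    riemann <- sum(diel_intensity(47, 8,
                                  as.POSIXct(tt + 0.5, tz = "UTC",
                                             origin = "1970-01-01"), p)) / 3600
    expect_equal(ph$true_total_traffic, riemann,
                 tolerance = 3e-3)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  site <- mid_lat_site()
  p <- sim_params()
  a <- simulate_site(site, sim_dates(2), p, seed = 42)
  b <- simulate_site(site, sim_dates(2), p, seed = 42)
  expect_identical(a, b)
  c <- simulate_site(site, sim_dates(2), p, seed = 43)
  expect_false(identical(a$echoes, c$echoes))

  sites <- dplyr::bind_rows(mid_lat_site(), north_site())
  n1 <- simulate_network(sites, sim_dates(2), p, seed = 7)
  n2 <- simulate_network(sites, sim_dates(2), p, seed = 7)
  expect_identical(n1, n2)
  expect_error(simulate_network(dplyr::bind_rows(site, site), sim_dates(1),
                                p, seed = 1), "duplicate")
})

test_that("zero flux yields no insect echoes but outputs stay parse-valid", {
  p <- sim_params(peak_flux = 0, base_flux = 0)
  sim <- simulate_site(mid_lat_site(), sim_dates(2), p, seed = 3)
  expect_equal(sum(sim$echoes$truth_label == "insect"), 0)
  expect_true(all(sim$truth$true_total_traffic == 0))

  # network round-trips through the io layer
  dir <- withr::local_tempdir()
  sites <- dplyr::bind_rows(mid_lat_site(), north_site())
  simulate_network(sites, sim_dates(2), sim_params(), seed = 11,
                   out_dir = dir)
  echoes <- read_echo_table(file.path(dir, "echoes.csv"))
  intervals <- read_intervals(file.path(dir, "intervals.csv"))
  back <- read_sites(file.path(dir, "sites.csv"))
  expect_setequal(unique(echoes$site_id), sites$site_id)
  expect_true(all(c("protocol_shortpulse") %in% intervals$kind))
  expect_equal(nrow(back), 2)
})

test_that("night echoes carry larger RCS and fly higher", {
  site <- mid_lat_site()
  cfg <- dielflux_config(period = as.Date(c("2021-07-01", "2021-07-06")))
  p <- sim_params(rain_per_day = 0, outage_per_day = 0, a_night = 1,
                  a_day = 1)
  sim <- simulate_site(site, sim_dates(6), p, seed = 13, config = cfg)
  ins <- filter_insects(sim$echoes, cfg)
  ph <- diel_phases(site, sim_dates(6), cfg)
  lab <- assign_phase(ins$timestamp_utc, ph)
  night <- lab$phase == "night"
  day <- lab$phase == "day"
  expect_gt(sum(night), 30)
  expect_gt(median(ins$rcs_max_cm2[night]), median(ins$rcs_max_cm2[day]))
  expect_gt(mean(ins$altitude_agl_m[night]), mean(ins$altitude_agl_m[day]))
})

test_that("the traffic estimator is unbiased against generator truth", {
  # constant flux: day_exponent 0 makes the day component 1 everywhere,
  # and a huge seasonal width freezes the envelope
  p <- sim_params(peak_flux = 0, base_flux = 120, a_day = 1,
                  day_exponent = 0, a_dusk = 0, a_dawn = 0, a_night = 0,
                  season_width_days = 1e6, rain_per_day = 0,
                  outage_per_day = 0, contam_bird_frac = 0,
                  contam_nonbio_frac = 0)
  tt <- as.POSIXct("2021-07-01 00:00:00", tz = "UTC") + seq(0, 86399, 600)
  expect_equal(diel_intensity(47, 8, tt, p), rep(120, length(tt)))

  site <- mid_lat_site()
  cfg <- dielflux_config(period = as.Date(c("2021-07-01", "2021-07-10")))
  sim <- simulate_site(site, sim_dates(10), p, seed = 21, config = cfg)
  hourly <- hourly_mtr(filter_insects(sim$echoes, cfg), sim$intervals,
                       site, cfg)
  ok <- !is.na(hourly$mtr)
  se <- stats::sd(hourly$mtr[ok]) / sqrt(sum(ok))
  expect_gt(sum(ok), 200)
  expect_lt(abs(mean(hourly$mtr[ok]) - 120), 3 * se)

  # per-phase totals agree with integrated truth within 3 sigma
  ph <- diel_phases(site, sim_dates(10), cfg)
  agg <- phase_aggregates(filter_insects(sim$echoes, cfg), ph,
                          sim$intervals, cfg)
  cmp <- dplyr::inner_join(agg, sim$truth,
                           by = c("site_id", "anchor_date", "phase"))
  dev <- (cmp$total_traffic - cmp$true_total_traffic)
  rel <- dev / pmax(cmp$true_total_traffic, 1)
  expect_lt(abs(mean(rel)), 3 * stats::sd(rel) / sqrt(nrow(cmp)))
})
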