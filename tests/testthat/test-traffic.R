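test_that("insect filtering applies the probability and band rules", {
  mk <- function(p_insect, p_bird, p_nonbio, alt) {
    tibble::tibble(site_id = "a",
                   timestamp_utc = as.POSIXct("2021-06-01 12:00:00", tz = "UTC"),
                   altitude_agl_m = alt, p_insect = p_insect, p_bird = p_bird,
                   p_nonbio = p_nonbio, rcs_max_cm2 = 0.1)
  }
  cfg <- dielflux_config()
  expect_equal(nrow(filter_insects(mk(0.5, 0.3, 0.2, 200), cfg)), 1)
  # not the argmax -> dropped even though above 0.4
  expect_equal(nrow(filter_insects(mk(0.45, 0.5, 0.05, 200), cfg)), 0)
  # at the threshold -> dropped (strictly greater required)
  expect_equal(nrow(filter_insects(mk(0.4, 0.3, 0.3, 200), cfg)), 0)
  # below the altitude band -> dropped
  expect_equal(nrow(filter_insects(mk(0.9, 0.05, 0.05, 30), cfg)), 0)
  expect_equal(nrow(filter_insects(mk(0.9, 0.05, 0.05, 501), cfg)), 0)
})

test_that("transect width follows the -3 dB beam geometry", {
  expect_equal(transect_width(200), 2 * 200 * tan(8.75 * pi / 180) / 1000)
  expect_equal(transect_width(200), 0.06157, tolerance = 1e-4)
  expect_equal(transect_width(400), 2 * transect_width(200))
  expect_equal(transect_width(500) / transect_width(50), 10)
  expect_error(transect_width(0), "altitude")
})

test_that("effective minutes equal a minute-set oracle", {
  iv <- tibble::tibble(
    site_id = "a", kind = "protocol_shortpulse",
    start_utc = as.POSIXct(c("2021-06-01 08:00:00"), tz = "UTC"),
    end_utc = as.POSIXct(c("2021-06-01 08:10:00"), tz = "UTC")
  )
  h0 <- as.POSIXct("2021-06-01 08:00:00", tz = "UTC")
  expect_equal(effective_minutes(iv, "a", h0, h0 + 3600), 10)
  full <- full_protocol("a", "2021-06-01", "2021-06-01")
  expect_equal(effective_minutes(full, "a", h0, h0 + 3600), 60)

  set.seed(7)
  n <- 50
  start <- as.POSIXct("2021-06-01", tz = "UTC") + sample(0:1380, n, TRUE) * 60
  rnd <- merge_intervals(tibble::tibble(
    site_id = "a", kind = "protocol_shortpulse",
    start_utc = start, end_utc = start + sample(1:90, n, TRUE) * 60
  ))
  day0 <- as.POSIXct("2021-06-01", tz = "UTC")
  got <- sum(vapply(0:23, function(h) {
    effective_minutes(rnd, "a", day0 + h * 3600, day0 + (h + 1) * 3600)
  }, numeric(1)))
  expect_equal(got, minute_set_minutes(
    pmax(as.numeric(rnd$start_utc), as.numeric(day0)),
    pmin(as.numeric(rnd$end_utc), as.numeric(day0) + 86400)))
})

test_that("hourly MTR arithmetic, NA rule and altitude weighting", {
  cfg <- dielflux_config(period = as.Date(c("2021-06-01", "2021-06-01")))
  sites <- tibble::tibble(site_id = "a")
  h0 <- as.POSIXct("2021-06-01 10:00:00", tz = "UTC")
  echoes <- echo_rows("a", h0 + c(100, 200, 300))
  full <- full_protocol("a", "2021-06-01", "2021-06-01")

  # constant-width test hook decouples the arithmetic from beam geometry
  res <- hourly_mtr(echoes, full, sites, cfg, w_fn = function(h) rep(1, length(h)))
  expect_equal(res$mtr[res$hour_start_utc == h0], 3)
  expect_equal(res$n_echoes[res$hour_start_utc == h0], 3L)
  expect_equal(res$effective_min, rep(60, 24))
  expect_true(all(res$mtr[res$hour_start_utc != h0] == 0))

  # real geometry: one echo at 200 m over a full hour
  res2 <- hourly_mtr(echo_rows("a", h0 + 10), full, sites, cfg)
  expect_equal(res2$mtr[res2$hour_start_utc == h0], 1 / transect_width(200))
  expect_equal(res2$mtr[res2$hour_start_utc == h0], 16.24, tolerance = 1e-3)

  # 10 monitored minutes < 12 min floor -> NA
  short <- tibble::tibble(site_id = "a", kind = "protocol_shortpulse",
                          start_utc = h0, end_utc = h0 + 600)
  res3 <- hourly_mtr(echo_rows("a", h0 + 10), short, sites, cfg)
  expect_true(is.na(res3$mtr[res3$hour_start_utc == h0]))
  # 12 min exactly -> reported, scaled by 60/12
  ok12 <- tibble::tibble(site_id = "a", kind = "protocol_shortpulse",
                         start_utc = h0, end_utc = h0 + 720)
  res4 <- hourly_mtr(echo_rows("a", h0 + 10), ok12, sites, cfg,
                     w_fn = function(h) rep(1, length(h)))
  expect_equal(res4$mtr[res4$hour_start_utc == h0], 5)
})

test_that("rain removes echo contributions but not monitoring time", {
  cfg <- dielflux_config(period = as.Date(c("2021-06-01", "2021-06-01")))
  sites <- tibble::tibble(site_id = "a")
  h0 <- as.POSIXct("2021-06-01 10:00:00", tz = "UTC")
  echoes <- echo_rows("a", h0 + c(60, 120, 1800, 3000))
  iv <- dplyr::bind_rows(
    full_protocol("a", "2021-06-01", "2021-06-01"),
    tibble::tibble(site_id = "a", kind = "rain",
                   start_utc = h0, end_utc = h0 + 300)
  )
  base <- hourly_mtr(echoes, full_protocol("a", "2021-06-01", "2021-06-01"),
                     sites, cfg, w_fn = function(h) rep(1, length(h)))
  wet <- hourly_mtr(echoes, iv, sites, cfg, w_fn = function(h) rep(1, length(h)))
  i <- which(base$hour_start_utc == h0)
  expect_equal(base$mtr[i], 4)
  expect_equal(wet$mtr[i], 2) # two echoes fell inside the rain interval
  expect_equal(wet$effective_min[i], base$effective_min[i])
})

test_that("phase aggregates recover totals and respect the monitoring rule", {
  site <- mid_lat_site()
  dates <- as.Date("2021-06-10")
  cfg <- dielflux_config(period = as.Date(c("2021-06-10", "2021-06-10")))
  ph <- diel_phases(site, dates, cfg)
  full <- full_protocol("ch", "2021-06-09", "2021-06-11")

  day_iv <- ph[ph$phase == "day", ]
  dur_h <- day_iv$duration_s / 3600
  # 24 echoes evenly through the day phase, constant width 1
  tt <- day_iv$start_utc + (seq_len(24) - 0.5) / 24 * day_iv$duration_s
  agg <- phase_aggregates(echo_rows("ch", tt), ph, full, cfg,
                          w_fn = function(h) rep(1, length(h)))
  day_row <- agg[agg$phase == "day", ]
  expect_equal(day_row$total_traffic, 24)
  expect_equal(day_row$mean_rate, 24 / dur_h)
  expect_equal(day_row$duration_h, dur_h)
  # fully monitored, zero echoes -> zero, not NA
  night_row <- agg[agg$phase == "night", ]
  expect_equal(night_row$mean_rate, 0)
  expect_equal(night_row$total_traffic, 0)
  # total_traffic = mean_rate * duration_h
  expect_equal(agg$total_traffic, agg$mean_rate * agg$duration_h,
               tolerance = 1e-9)

  # monitoring below the fraction makes the phase NA
  part <- tibble::tibble(
    site_id = "ch", kind = "protocol_shortpulse",
    start_utc = day_iv$start_utc,
    end_utc = day_iv$start_utc + 0.1 * day_iv$duration_s
  )
  agg2 <- phase_aggregates(echo_rows("ch", tt), ph, part, cfg,
                           w_fn = function(h) rep(1, length(h)))
  expect_true(is.na(agg2$mean_rate[agg2$phase == "day"]))
})

test_that("phase totals are consistent with the echo-level total", {
  site <- mid_lat_site()
  dates <- as.Date("2021-06-10") + 0:1
  cfg <- dielflux_config(period = as.Date(c("2021-06-10", "2021-06-11")))
  ph <- diel_phases(site, dates, cfg)
  full <- full_protocol("ch", "2021-06-09", "2021-06-12")
  set.seed(9)
  tt <- min(ph$start_utc) +
    runif(200) * (as.numeric(max(ph$end_utc)) - as.numeric(min(ph$start_utc)))
  alt <- runif(200, 60, 480)
  echoes <- echo_rows("ch", tt, alt)
  agg <- phase_aggregates(echoes, ph, full, cfg)
  # for fully monitored diel days, summed phase totals = echo-level sum 1/w
  expect_equal(sum(agg$total_traffic), sum(1 / transect_width(alt)),
               tolerance = 1e-9)
})
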