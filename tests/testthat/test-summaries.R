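test_that("daily hourly proportions normalize, keeping zero distinct from NA", {
  h0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  hourly <- tibble::tibble(
    site_id = "a", hour_start_utc = h0 + 0:47 * 3600,
    mtr = 0, n_echoes = 0L, effective_min = 60
  )
  hourly$mtr[hourly$hour_start_utc == h0 + 12 * 3600] <- 30
  hourly$mtr[hourly$hour_start_utc == h0 + 19 * 3600] <- 30
  # day 2: all zero except two missing hours
  hourly$mtr[25:26] <- NA
  m <- hourly_proportion_matrix(hourly)
  d1 <- m[m$date == as.Date("2021-06-01"), ]
  expect_equal(d1$prop[d1$hour == 12], 0.5)
  expect_equal(d1$prop[d1$hour == 19], 0.5)
  expect_equal(sum(d1$prop), 1)
  d2 <- m[m$date == as.Date("2021-06-02"), ]
  expect_true(all(d2$prop[!d2$missing] == 0))
  expect_true(all(is.na(d2$prop[d2$missing])))
  expect_equal(sum(d2$missing), 2)

  # random day normalizes to 1
  set.seed(14)
  hourly$mtr <- runif(48)
  m2 <- hourly_proportion_matrix(hourly)
  sums <- as.numeric(tapply(m2$prop, m2$date, sum))
  expect_equal(sums, c(1, 1), tolerance = 1e-9)

  wide <- heatmap_wide(m2, "prop")
  expect_equal(dim(wide), c(2, 25))
  expect_equal(names(wide)[1:2], c("date", "h00"))
})

test_that("monthly summaries average days and share out RCS", {
  site <- mid_lat_site()
  cfg <- dielflux_config(period = as.Date(c("2021-06-10", "2021-06-11")))
  dates <- as.Date("2021-06-10") + 0:1
  ph <- diel_phases(site, dates, cfg)

  dp <- tidyr::expand_grid(site_id = "ch", anchor_date = dates,
                           phase = diel_phase_levels()) |>
    dplyr::mutate(prop_intensity = rep(c(0.1, 0.6, 0.2, 0.1), 2),
                  prop_traffic = rep(c(0.05, 0.75, 0.1, 0.1), 2),
                  complete = TRUE)
  # one echo per phase with equal RCS -> equal shares
  echoes <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
    echo_rows("ch", ph$start_utc[i] + ph$duration_s[i] / 2, altitude = 200)
  })
  ms <- monthly_phase_summary(dp, echoes, ph)
  expect_equal(nrow(ms), 4)
  expect_equal(ms$mean_prop_intensity[match(diel_phase_levels(), ms$phase)],
               c(0.1, 0.6, 0.2, 0.1))
  expect_equal(ms$rcs_share, rep(0.25, 4))
  expect_equal(sum(ms$rcs_share), 1, tolerance = 1e-9)
  expect_true(all(ms$mean_daily_median_alt_m == 200))
  expect_true(all(ms$n_days == 2))
})

test_that("the pipeline runs end to end, deterministically, with all outputs", {
  sites <- dplyr::bind_rows(
    mid_lat_site(),
    tibble::tibble(site_id = "fr", lat_deg = 44, lon_deg = 2),
    tibble::tibble(site_id = "de", lat_deg = 52, lon_deg = 10)
  )
  cfg <- dielflux_config(period = as.Date(c("2021-07-01", "2021-07-14")))
  dates <- seq(cfg$period[1], cfg$period[2], by = "day")
  net <- simulate_network(sites, dates, sim_params(), seed = 31, config = cfg)

  dir1 <- withr::local_tempdir()
  res <- run_pipeline(sites, net$echoes, net$intervals, cfg,
                      out_dir = dir1, seed = 31)
  expect_equal(nrow(res$anova_intensity$posthoc), 4 * choose(3, 2))
  expect_equal(nrow(res$anova_traffic$posthoc), 4 * choose(3, 2))
  expect_equal(nrow(res$anova_intensity$omnibus), 4)
  for (f in c("phases.csv", "hourly_mtr.csv", "phase_agg.csv",
              "daily_props.csv", "omnibus.csv", "posthoc.csv",
              "monthly_summary.csv", "run_log.json", "heatmap_prop_ch.csv",
              "heatmap_mtr_fr.csv")) {
    expect_true(file.exists(file.path(dir1, f)), label = f)
  }
  log <- jsonlite::read_json(file.path(dir1, "run_log.json"))
  expect_equal(log$seed, 31)

  # rerun: identical outputs
  res2 <- run_pipeline(sites, net$echoes, net$intervals, cfg)
  expect_identical(res$daily_props, res2$daily_props)
  expect_identical(res$anova_intensity$posthoc, res2$anova_intensity$posthoc)

  # failure in a stage names the stage
  bad <- dplyr::mutate(net$echoes, p_insect = NA_real_)
  expect_error(run_pipeline(sites, bad, net$intervals, cfg), "stage")
})

test_that("plot builders return ggplot objects", {
  h0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  hourly <- tibble::tibble(site_id = "a", hour_start_utc = h0 + 0:23 * 3600,
                           mtr = runif(24), n_echoes = 1L,
                           effective_min = 60)
  m <- hourly_proportion_matrix(hourly)
  expect_s3_class(plot_diel_heatmap(m, "prop"), "ggplot")
  monthly <- tibble::tibble(site_id = "a", month = "2021-06",
                            phase = diel_phase_levels(),
                            mean_prop_intensity = c(0.1, 0.6, 0.2, 0.1),
                            mean_prop_traffic = c(0.05, 0.75, 0.1, 0.1),
                            rcs_share = 0.25,
                            mean_daily_median_alt_m = 180, n_days = 10)
  expect_s3_class(plot_monthly_proportions(monthly), "ggplot")
  posthoc <- tibble::tibble(measure = "intensity", phase = "day",
                            site_a = "a", site_b = "b", effect_size = 0.1,
                            p_raw = 0.01, p_holm = 0.03, significant = TRUE)
  expect_s3_class(plot_effect_sizes(posthoc), "ggplot")
})
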