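# Heat Ratio Method processing chain

test_that("heat-pulse velocity follows the HRM formula", {
  geom <- probe_geometry(k = 0.0025, x = 0.6)
  expect_identical(heat_pulse_velocity(1, geom), 0)
  # (0.0025 / 0.6) * log(1.2) * 3600 = 15 * 0.18232156, by hand
  expect_equal(heat_pulse_velocity(1.2, geom), 2.7348234, tolerance = 1e-6)
  expect_equal(heat_pulse_velocity(1 / 1.2, geom), -2.7348234,
               tolerance = 1e-6)
})

test_that("velocity is antisymmetric under ratio inversion", {
  set.seed(1)
  r <- exp(runif(1000, -2, 2))
  expect_equal(heat_pulse_velocity(r), -heat_pulse_velocity(1 / r))
})

test_that("non-positive ratios raise a domain error naming the sample", {
  ts <- as.POSIXct("2015-01-13 10:00:00", tz = "UTC") + 0:2 * 60
  expect_error(heat_pulse_velocity(c(1, -0.2, 1.1), timestamps = ts),
               "10:01", class = "sapflux_domain_error")
  expect_error(heat_pulse_velocity(0), "position")
})

test_that("zero-offset correction subtracts the baseline mean", {
  ts <- as.POSIXct("2015-01-13", tz = "UTC") + 0:2 * 3600
  win <- c(ts[1], ts[2])  # first two samples, mean 1.5
  expect_equal(as.numeric(zero_offset_correction(c(1, 2, 3), ts, win)),
               c(-0.5, 0.5, 1.5))
  const <- zero_offset_correction(rep(0.5, 3), ts, c(ts[1], ts[3]))
  expect_equal(as.numeric(const), rep(0, 3))
  # idempotent: re-applying with the same window changes nothing
  once <- zero_offset_correction(c(1, 2, 3), ts, win)
  twice <- zero_offset_correction(as.numeric(once), ts, win)
  expect_equal(as.numeric(once), as.numeric(twice))
  expect_error(zero_offset_correction(1, ts[1], c(ts[1] + 10, ts[1] + 20)),
               "no samples", class = "sapflux_domain_error")
})

test_that("wound correction is the configured polynomial", {
  expect_identical(wound_correction(5, c(1, 0, 0)), 5)
  expect_equal(wound_correction(2, c(1.1, 0, 0)), 2.2)
  expect_identical(wound_correction(0, c(1.7, 0.3, -0.1)), 0)
  expect_equal(wound_correction(2, c(1, 0.5, 0.25)), 2 + 2 + 2)
})

test_that("flow conversion is linear, sign-preserving and unit-correct", {
  unit <- sapwood_properties(rho_b = 1000, rho_s = 1000, m_c = 1e-12,
                             C_w = 4186, C_s = 4186, S = 1000)
  expect_equal(sap_flow_rate(1, unit), 1 + 1e-12 * 40 / 40,
               tolerance = 1e-9)
  wood <- sapwood_properties(rho_b = 500, rho_s = 1000, m_c = 1,
                             C_w = 1200, C_s = 4186, S = 40)
  # 0.5 * (1 + 1200/4186) * 2.7348 * 40 / 1000, by hand
  expect_equal(sap_flow_rate(2.7348, wood), 0.0703761, tolerance = 1e-4)
  expect_identical(sap_flow_rate(0, wood), 0)
  set.seed(2)
  vh <- rnorm(100); a <- rnorm(100)
  expect_equal(sap_flow_rate(a * vh, wood), a * sap_flow_rate(vh, wood))
  expect_true(all(sign(sap_flow_rate(vh, wood)) == sign(vh)))
})

test_that("sapwood and probe validation reject bad values", {
  expect_error(sapwood_properties(rho_b = -1), "positive")
  expect_error(probe_geometry(k = 0), "> 0")
  expect_error(probe_geometry(depths = c(20, 5)), "increasing")
  # rho_b > rho_s is physically odd but not forbidden
  expect_s3_class(sapwood_properties(rho_b = 1200, rho_s = 1000),
                  "sapwood_properties")
})

test_that("depth combination is a weighted mean over matching keys", {
  expect_identical(combine_depths(c(`5` = 2, `20` = 2)), 2)
  expect_identical(combine_depths(c(`5` = 3, `20` = 1)), 2)
  expect_identical(combine_depths(c(`5` = 3, `20` = 1),
                                  c(`5` = 1, `20` = 0)), 3)
  expect_error(combine_depths(c(`5` = 3, `20` = 1), c(`5` = 1, `25` = 1)),
               "do not match")
  expect_error(combine_depths(c(`5` = 1, `20` = 1), c(`5` = 0, `20` = 0)),
               "positive sum")
})

test_that("daily cumulative flow integrates per calendar day", {
  ts <- seq(as.POSIXct("2015-01-13 00:00:00", tz = "UTC"),
            by = 60, length.out = 24 * 60 + 1)
  out <- daily_cumulative(ts, rep(0.1, length(ts)))
  expect_equal(out$total_l[out$date == as.Date("2015-01-13")], 2.4,
               tolerance = 1e-9)
  ts2 <- seq(as.POSIXct("2015-01-13 00:00:00", tz = "UTC"),
             by = 60, length.out = 12 * 60 + 1)
  out2 <- daily_cumulative(ts2, rep(-0.04, length(ts2)))
  expect_equal(out2$total_l, -0.48, tolerance = 1e-9)
  expect_false(any(out2$gap_flag))
  # a 2 h hole in the day trips the gap flag; a missing day is absent
  ts3 <- c(ts2[1:100], ts2[101:length(ts2)] + 7200,
           max(ts2) + 2 * 86400 + 1:3 * 60)
  out3 <- daily_cumulative(ts3, rep(0.1, length(ts3)))
  expect_true(out3$gap_flag[1])
  expect_false(as.Date("2015-01-14") %in% out3$date)
  expect_equal(nrow(daily_cumulative(ts2[1], 0.1)), 0)
  expect_error(daily_cumulative(rev(ts2), rep(1, length(ts2))), "sorted",
               class = "sapflux_domain_error")
})

test_that("raw table processing runs the whole chain per plant", {
  ts <- as.POSIXct("2015-01-13 08:00:00", tz = "UTC") + 0:9 * 600
  raw <- expand.grid(timestamp = ts, plant_id = c("a", "b"),
                     depth_mm = c(5, 20))
  raw$ratio <- 1.05
  out <- process_heat_pulse(raw, af = c(a = "H_PAR", b = "L_PAR"))
  expect_equal(nrow(out), 20)
  expect_named(out, c("timestamp", "plant_id", "af", "vh_cm_h", "vs_l_h"))
  expect_equal(unique(out$af[out$plant_id == "a"]), "H_PAR")
  expect_equal(out$vh_cm_h,
               rep(heat_pulse_velocity(1.05), 20), tolerance = 1e-12)
  # t1/t2 columns are accepted in place of the ratio
  raw2 <- raw; raw2$t1_c <- 21 * raw$ratio; raw2$t2_c <- 21
  raw2$ratio <- NULL
  out2 <- process_heat_pulse(raw2, af = c(a = "H_PAR", b = "L_PAR"))
  expect_equal(out2$vs_l_h, out$vs_l_h)
  expect_error(process_heat_pulse(raw[, 1:2]), "missing columns",
               class = "sapflux_schema_error")
})

test_that("CSV interfaces round-trip the processed schema", {
  ts <- as.POSIXct("2015-01-13 08:00:00", tz = "Etc/GMT+5") + 0:3 * 600
  proc <- data.frame(timestamp = ts, plant_id = "p1", af = "H_PAR",
                     vh_cm_h = c(-1, 0, 1, 2), vs_l_h = c(-0.1, 0, 0.1, 0.2))
  f <- tempfile(fileext = ".csv")
  write_sap_flow_csv(proc, f)
  back <- read.csv(f)
  expect_equal(back$vs_l_h, proc$vs_l_h)
  expect_match(back$timestamp[1], "^2015-01-13T08:00:00$")
  raw <- data.frame(timestamp = "2015-01-13T08:00:00", plant_id = "p1",
                    depth_mm = 5, ratio = 1.1)
  f2 <- tempfile(fileext = ".csv")
  write.csv(raw, f2, row.names = FALSE)
  rr <- read_heat_pulse_csv(f2)
  expect_s3_class(rr$timestamp, "POSIXct")
  expect_error(read_heat_pulse_csv(f), class = "sapflux_schema_error")
})
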