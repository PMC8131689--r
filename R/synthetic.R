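# Seedable synthetic campaign generator.  Diurnal microclimate per
# agroforestry system is built from periodic splines through the bundled
# hourly reference means (with dawn/dusk shape knots), given day-to-day and
# minute-scale AR(1) variability, and calibrated so that hourly slot means
# land inside the reference bands.  Sap flow is the bundled linear model
# evaluated on that microclimate plus Gaussian noise and plant/day random
# intercepts.  An inverse-HRM step turns flow back into raw sensor ratios
# so that the whole processing chain can be round-trip tested.

#' Generator configuration
#'
#' Defaults describe the reference campaign: 3 systems x 4 plants x 14 days,
#' 1-minute microclimate, 1389 sap-flow rows per plant (5556 per system:
#' 3816 for fitting plus 1740 for validation under the default chronological
#' split), flow noise SD 0.015 L/h with 0.005 L/h plant and day random
#' intercepts.
#'
#' @param seed integer seed; every stochastic component derives from it.
#' @param n_days number of days.
#' @param interval_min microclimate sampling interval, minutes (must divide
#'   24 h).
#' @param afs systems to simulate.
#' @param n_plants plants per system.
#' @param rows_per_plant sap-flow rows per plant (sub-sampled evenly from
#'   the microclimate grid).
#' @param noise_sd iid Gaussian flow noise SD, L/h.
#' @param plant_effect_sd,day_effect_sd random-intercept SDs, L/h.
#' @param coefficients generating coefficient set (see
#'   [sapflow_coefficients()]).
#' @param start_date first campaign day.
#' @param tz timezone of the generated timestamps (local offset).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 42, n_days = 14, interval_min = 1,
                             afs = af_levels(), n_plants = 4,
                             rows_per_plant = 1389, noise_sd = 0.015,
                             plant_effect_sd = 0.005, day_effect_sd = 0.005,
                             coefficients = sapflow_coefficients("reconciled"),
                             start_date = as.Date("2015-01-13"),
                             tz = "Etc/GMT+5") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if ((24 * 60) %% interval_min != 0)
    stop_sapflux("interval_min must divide 24 h")
  if (noise_sd < 0 || plant_effect_sd < 0 || day_effect_sd < 0)
    stop_sapflux("noise SDs must be >= 0")
  if (!all(afs %in% af_levels()))
    stop_sapflux(paste("unknown AF label(s):",
                       paste(setdiff(afs, af_levels()), collapse = ", ")))
  structure(list(seed = as.integer(seed), n_days = n_days,
                 interval_min = interval_min, afs = afs,
                 n_plants = n_plants, rows_per_plant = rows_per_plant,
                 noise_sd = noise_sd, plant_effect_sd = plant_effect_sd,
                 day_effect_sd = day_effect_sd, coefficients = coefficients,
                 start_date = start_date, tz = tz),
            class = "generator_config")
}

# variability constants of the generator (see the methods vignette):
# day-to-day offsets/factors emulate cloudier and clearer days; minute AR(1)
# jitter emulates turbulent fluctuation and understory sunflecks.  Scales
# are conservative so that hourly slot means stay inside the reference SE
# bands.
.gen_jitter <- list(
  ta  = list(day_sd = 0.08, min_sd = 0.20, rho = 0.85),   # additive, degC
  def = list(day_sd = 0.02, min_sd = 0.08, rho = 0.80),   # lognormal factor
  par = list(day_sd = 0.08, min_sd = 0.25, rho = 0.85))   # lognormal factor

ar1_series <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# lognormal AR(1) factor with unit mean
ln_factor <- function(n, day_sd, min_sd, rho, day_index, n_days) {
  z <- rnorm(n_days, 0, day_sd)[day_index] + ar1_series(n, min_sd, rho)
  exp(z) / exp((day_sd^2 + min_sd^2) / 2)
}

#' Calibrated diurnal anchors for one system
#'
#' Returns the reference slot anchors used by the generator, after the VPD
#' calibration step: the saturation-deficit anchor (100 - RH) of each slot
#' is nudged, within 0.85 reference SE of the humidity mean, toward the
#' deficit that reproduces the reference VPD mean (to within 0.8 of its SE).
#' Temperature anchors are never moved.  Slots whose VPD target cannot be
#' reached within one reference SE from any admissible deficit are left at
#' their centre values and flagged `vpd_consistent = FALSE`: for those
#' cells the tabulated VPD is internally inconsistent with the tabulated
#' temperature and humidity under the instantaneous formula.
#'
#' @param af system label.
#' @return Data frame `hour, t_a, deficit, par, vpd_target, vpd_implied,
#'   vpd_consistent`.
#' @export
microclimate_calibration <- function(af) {
  r <- .microclimate_ref[.microclimate_ref$af == af, ]
  if (!nrow(r)) stop_sapflux(paste("unknown AF label:", af))
  es <- saturation_vapor_pressure(r$t_a_c)
  d0 <- 100 - r$rh_a_pct
  tgt <- r$vpd_kpa
  # deficit that would hit the nearest edge of the +-0.8 SE target band
  lo <- tgt - 0.8 * r$vpd_se
  hi <- tgt + 0.8 * r$vpd_se
  v0 <- es * d0 / 100
  want <- pmin(pmax(v0, lo), hi)            # dead zone: no move if inside
  d_new <- 100 * want / es
  d_new <- pmin(pmax(d_new, d0 - 0.85 * r$rh_se), d0 + 0.85 * r$rh_se)
  v_new <- es * d_new / 100
  # reachable within one printed SE?  (printed-zero SEs use the printing
  # resolution instead)
  tol <- ifelse(r$vpd_se > 0, r$vpd_se, 0.005)
  consistent <- abs(v_new - tgt) <= tol
  d_final <- ifelse(consistent, d_new, d0)
  data.frame(hour = r$hour, t_a = r$t_a_c, deficit = d_final,
             par = r$par_umol_m2_s, vpd_target = tgt,
             vpd_implied = es * d_final / 100, vpd_consistent = consistent)
}

# periodic spline through slot-centre anchors plus shape knots: pre-dawn
# plateau at 06:00 (holds the 04:00 value), day value held to sunset
# (18:00 = 16:00 anchor) and a fast dusk transition knot at 19:18
per_diurnal_curve <- function(hours, values) {
  h <- hours + 0.5
  v4 <- values[hours == 4]
  v16 <- values[hours == 16]
  v20 <- values[hours == 20]
  kh <- c(h, 6.0, 18.0, 19.3)
  kv <- c(values, v4, v16, 0.25 * v16 + 0.75 * v20)
  o <- order(kh); kh <- kh[o]; kv <- kv[o]
  kh <- c(kh, kh[1] + 24); kv <- c(kv, kv[1])
  function(t) spline(kh, kv, xout = (t - kh[1]) %% 24 + kh[1],
                     method = "periodic")$y
}

# truncated day arc for PAR: natural spline pinned to zero at 06/18 local
par_diurnal_curve <- function(hours, values) {
  kh <- c(6, hours + 0.5, 18)
  kv <- c(0, values, 0)
  function(t) {
    y <- spline(kh, kv, xout = t, method = "natural")$y
    y[t <= 6 | t >= 18] <- 0  # inclusive: the endpoints are night
    pmax(y, 0)
  }
}

af_stream_seed <- function(config, af, offset = 0L) {
  config$seed + offset + 101L * match(af, af_levels())
}

#' Generate a synthetic microclimate series for one system
#'
#' Minute-resolution (by default) diurnal series of humidity, temperature,
#' PAR and derived VPD whose hourly slot means at the six reference hours
#' reproduce the bundled reference means (see [microclimate_reference()] and
#' [microclimate_calibration()] for the calibration contract).  Deterministic
#' given `config$seed` and `af`.
#'
#' @param config a [generator_config()].
#' @param af system label.
#' @return Data frame `timestamp, af, day, rh_a_pct, t_a_c, par_umol_m2_s,
#'   vpd_kpa`.
#' @export
generate_microclimate <- function(config, af) {
  stopifnot(inherits(config, "generator_config"))
  if (!af %in% af_levels())
    stop_sapflux(paste("unknown AF label:", af))
  cal <- microclimate_calibration(af)
  f_ta <- per_diurnal_curve(cal$hour, cal$t_a)
  f_d <- per_diurnal_curve(cal$hour, cal$deficit)
  day_cal <- cal[!is.na(cal$par), ]
  f_par <- par_diurnal_curve(day_cal$hour, day_cal$par)

  per_day <- 24 * 60 / config$interval_min
  tod <- rep(seq(0, 24 - config$interval_min / 60,
                 by = config$interval_min / 60), config$n_days)
  n <- length(tod)
  day_index <- rep(seq_len(config$n_days), each = per_day)

  set.seed(af_stream_seed(config, af))
  j <- .gen_jitter
  ta <- f_ta(tod) + rnorm(config$n_days, 0, j$ta$day_sd)[day_index] +
    ar1_series(n, j$ta$min_sd, j$ta$rho)
  deficit <- f_d(tod) *
    ln_factor(n, j$def$day_sd, j$def$min_sd, j$def$rho, day_index,
              config$n_days)
  par <- f_par(tod) *
    ln_factor(n, j$par$day_sd, j$par$min_sd, j$par$rho, day_index,
              config$n_days)
  rh <- pmin(100, pmax(0, 100 - deficit))

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  ts <- t0 + ((day_index - 1) * 24 + tod) * 3600
  data.frame(timestamp = ts, af = af, day = day_index,
             rh_a_pct = rh, t_a_c = ta, par_umol_m2_s = par,
             vpd_kpa = vpd(ta, rh))
}

#' Noiseless sap flow implied by a coefficient set
#'
#' Pointwise linear evaluation of the sap-flow model on a microclimate
#' series.  Shares its implementation with [predict_sapflow()] (and thus
#' with the fitted-model `predict` method); no clipping is applied -
#' negative values are meaningful basipetal flow.
#'
#' @param micro microclimate data frame (`rh_a_pct, t_a_c, par_umol_m2_s,
#'   vpd_kpa`).
#' @param coeffs coefficient data frame (see [sapflow_coefficients()]).
#' @param af system label to evaluate.
#' @return Sap flow vector, L/h.
#' @export
true_sap_flow <- function(micro, coeffs = sapflow_coefficients(), af) {
  micro$af <- af
  predict_sapflow(coeffs, micro)
}

#' Add measurement noise and random plant/day effects to a flow series
#'
#' Adds iid Gaussian noise plus one random intercept per plant and one per
#' day (drawn once per unit).
#'
#' @param truth data frame with columns `vs_true`, `plant_id`, `day`, `af`.
#' @param config a [generator_config()].
#' @return `truth` with an added `vs_l_h` column.
#' @export
add_noise <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  check_columns(truth, c("vs_true", "plant_id", "day", "af"), "add_noise")
  af <- truth$af[1]
  set.seed(af_stream_seed(config, af, offset = 20011L))
  plants <- sort(unique(truth$plant_id))
  days <- sort(unique(truth$day))
  pe <- setNames(rnorm(length(plants), 0, config$plant_effect_sd),
                 plants)
  de <- setNames(rnorm(length(days), 0, config$day_effect_sd),
                 days)
  truth$vs_l_h <- truth$vs_true + pe[as.character(truth$plant_id)] +
    de[as.character(truth$day)] + rnorm(nrow(truth), 0, config$noise_sd)
  truth
}

#' Invert a flow series to raw heat-pulse ratios
#'
#' Inverse of the HRM chain with identity corrections: velocity from the
#' flow conversion factor, then the temperature-rise ratio
#' `exp(vh * x / (3600 * k))`, replicated at each probe depth.  Processing
#' the output with [process_heat_pulse()] reproduces the input flow to
#' floating-point accuracy.
#'
#' @param flow data frame `timestamp, plant_id, vs_l_h` (`af` optional).
#' @param wood a [sapwood_properties()].
#' @param geom a [probe_geometry()].
#' @return Raw heat-pulse data frame `timestamp, plant_id, depth_mm, ratio`.
#' @export
invert_to_heat_pulse <- function(flow, wood = sapwood_properties(),
                                 geom = probe_geometry()) {
  check_columns(flow, c("timestamp", "plant_id", "vs_l_h"),
                "invert_to_heat_pulse")
  vh <- flow$vs_l_h / sap_flow_factor(wood)
  ratio <- exp(vh * geom$x / (3600 * geom$k))
  out <- do.call(rbind, lapply(geom$depths, function(dd) {
    data.frame(timestamp = flow$timestamp, plant_id = flow$plant_id,
               depth_mm = dd, ratio = ratio)
  }))
  out[order(out$timestamp, out$plant_id, out$depth_mm), ]
}

#' Simulate a full synthetic campaign
#'
#' Generates, for every configured system: the minute microclimate series,
#' the noiseless model flow at an even sub-sample of timestamps for each
#' plant, the noisy observed flow, and (optionally) the inverse-HRM raw
#' sensor table.
#'
#' @param config a [generator_config()].
#' @param raw_sensor if `TRUE`, include the inverted raw heat-pulse table.
#' @return An object of class `sapflow_campaign`: a list with data frames
#'   `microclimate`, `model_data` (one row per plant x timestamp with
#'   covariates, `vs_true` and noisy `vs_l_h`), `truth` (per timestamp) and
#'   optionally `raw`, plus the `config`.
#' @export
simulate_campaign <- function(config = generator_config(),
                              raw_sensor = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  micro_l <- list(); model_l <- list(); truth_l <- list(); raw_l <- list()
  for (af in config$afs) {
    m <- generate_microclimate(config, af)
    vs <- true_sap_flow(m, config$coefficients, af)
    idx <- round(seq(1, nrow(m), length.out = config$rows_per_plant))
    base <- data.frame(m[idx, c("timestamp", "af", "day", "rh_a_pct",
                                "t_a_c", "par_umol_m2_s", "vpd_kpa")],
                       vs_true = vs[idx])
    rows <- do.call(rbind, lapply(seq_len(config$n_plants), function(p) {
      cbind(base, plant_id = sprintf("%s_p%d", af, p))
    }))
    rows <- add_noise(rows, config)
    rows <- rows[order(rows$timestamp, rows$plant_id), ]
    micro_l[[af]] <- m
    truth_l[[af]] <- base
    model_l[[af]] <- rows
    if (raw_sensor)
      raw_l[[af]] <- invert_to_heat_pulse(
        data.frame(timestamp = rows$timestamp, plant_id = rows$plant_id,
                   vs_l_h = rows$vs_l_h))
  }
  out <- list(microclimate = do.call(rbind, micro_l),
              model_data = do.call(rbind, model_l),
              truth = do.call(rbind, truth_l),
              raw = if (raw_sensor) do.call(rbind, raw_l),
              config = config)
  rownames(out$microclimate) <- rownames(out$model_data) <-
    rownames(out$truth) <- NULL
  structure(out, class = "sapflow_campaign")
}

#' @export
print.sapflow_campaign <- function(x, ...) {
  cat("Synthetic sap-flow campaign\n")
  cat(sprintf("  systems: %s\n", paste(x$config$afs, collapse = ", ")))
  cat(sprintf("  %d days, %d plants/system, %d model rows/system\n",
              x$config$n_days, x$config$n_plants,
              x$config$n_plants * x$config$rows_per_plant))
  cat(sprintf("  noise SD %.3f L/h (plant %.3f, day %.3f)\n",
              x$config$noise_sd, x$config$plant_effect_sd,
              x$config$day_effect_sd))
  invisible(x)
}
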