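# Heat Ratio Method (HRM) processing: temperature-rise ratios from probes
# equidistant above and below a heater pulse are converted to heat-pulse
# velocity, corrected (zero offset, wound polynomial), merged across
# installation depths and converted to volumetric sap flow.

#' Probe geometry for an HRM sensor
#'
#' @param k thermal diffusivity of fresh (green) wood, cm^2/s.
#' @param x heater-to-thermocouple spacing, cm.
#' @param depths installation depths of the thermocouples behind the
#'   cambium, mm; strictly increasing.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(k = 0.0025, x = 0.6, depths = c(5, 20)) {
  stopifnot(is.numeric(k), length(k) == 1, is.numeric(x), length(x) == 1)
  if (!(k > 0)) stop_sapflux("thermal diffusivity `k` must be > 0")
  if (!(x > 0)) stop_sapflux("probe spacing `x` must be > 0")
  if (length(depths) < 1 || any(depths <= 0) ||
      any(diff(depths) <= 0))
    stop_sapflux("`depths` must be positive and strictly increasing")
  structure(list(k = k, x = x, depths = depths), class = "probe_geometry")
}

#' Sapwood physical properties
#'
#' Parameters of the velocity-to-flow conversion.  The defaults for the wood
#' matrix and sap heat capacities (`C_w` = 1200, `C_s` = 4186 J/kg/K at
#' 20 degC) are standard; basic density, water content and conducting area
#' are site-specific stand-ins used by the synthetic fixtures and should be
#' measured for real material.
#'
#' @param rho_b basic density of dry sapwood, kg/m^3.
#' @param rho_s sap density, kg/m^3 (water).
#' @param m_c water content of fresh sapwood, kg water per kg dry wood.
#' @param C_w specific heat capacity of the dry wood matrix, J/kg/K.
#' @param C_s specific heat capacity of the sap, J/kg/K.
#' @param S cross-sectional area of conducting sapwood, cm^2.
#' @return An object of class `sapwood_properties`.
#' @export
sapwood_properties <- function(rho_b = 500, rho_s = 1000, m_c = 1,
                               C_w = 1200, C_s = 4186, S = 40) {
  vals <- c(rho_b = rho_b, rho_s = rho_s, m_c = m_c,
            C_w = C_w, C_s = C_s, S = S)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_sapflux("all sapwood properties must be positive and finite")
  structure(as.list(vals), class = "sapwood_properties")
}

#' Heat-pulse velocity from a temperature-rise ratio
#'
#' \deqn{V_h = (k/x)\,\ln(T_1/T_2)\,3600}
#'
#' with `k` in cm^2/s and `x` in cm, so that the result is in cm/h.
#' Negative values (ratio < 1) indicate basipetal (downward) flow.
#'
#' @param ratio dimensionless T1/T2 temperature-rise ratio, > 0.
#' @param geom a [probe_geometry()].
#' @param timestamps optional vector parallel to `ratio`; used to name the
#'   offending samples in the error raised for non-positive ratios.
#' @return Heat-pulse velocity, cm/h (vectorised over `ratio`).
#' @export
heat_pulse_velocity <- function(ratio, geom = probe_geometry(),
                                timestamps = NULL) {
  stopifnot(inherits(geom, "probe_geometry"))
  bad <- !is.finite(ratio) | ratio <= 0
  if (any(bad)) {
    where <- if (!is.null(timestamps)) {
      paste0(" at ", paste(format(timestamps[bad]), collapse = ", "))
    } else {
      paste0(" at position(s) ", paste(which(bad), collapse = ", "))
    }
    stop_sapflux(paste0("non-positive temperature ratio", where),
                 class = "sapflux_domain_error")
  }
  (geom$k / geom$x) * log(ratio) * 3600
}

#' Zero-flow offset correction
#'
#' Subtracts the mean velocity observed during a zero-flow baseline window
#' (e.g. after severing the stem below the probes) from the whole series.
#'
#' @param vh velocity series, cm/h.
#' @param timestamps POSIXct vector parallel to `vh`.
#' @param window length-2 vector `c(start, end)`; samples with
#'   `start <= timestamp <= end` define the baseline.
#' @return Corrected velocity series; the baseline offset is attached as
#'   attribute `"offset"`.
#' @export
zero_offset_correction <- function(vh, timestamps, window) {
  stopifnot(length(vh) == length(timestamps), length(window) == 2)
  inw <- timestamps >= window[1] & timestamps <= window[2]
  if (!any(inw))
    stop_sapflux("baseline window contains no samples",
                 class = "sapflux_domain_error")
  off <- mean(vh[inw])
  structure(vh - off, offset = off)
}

#' Wound / misalignment correction polynomial
#'
#' Applies `a*vh + b*vh^2 + c*vh^3`.  The default coefficients `(1, 0, 0)`
#' are the identity: no quantified wound correction is bundled, and users
#' should supply coefficients appropriate for their wound width.
#'
#' @param vh velocity, cm/h.
#' @param coeffs numeric coefficient vector `(a, b, c)`.
#' @return Corrected velocity.
#' @export
wound_correction <- function(vh, coeffs = c(1, 0, 0)) {
  stopifnot(is.numeric(coeffs), length(coeffs) == 3)
  coeffs[1] * vh + coeffs[2] * vh^2 + coeffs[3] * vh^3
}

#' Convert heat-pulse velocity to volumetric sap flow
#'
#' \deqn{V_s = (\rho_b/\rho_s)\,(m_c + C_w/C_s)\,V_h\,S / 1000}
#'
#' The product is in cm^3/h; division by 1000 expresses it in L/h.  The
#' conversion is linear and sign-preserving in `vh`.
#'
#' @param vh heat-pulse velocity, cm/h.
#' @param wood a [sapwood_properties()].
#' @return Sap flow, L/h.
#' @export
sap_flow_rate <- function(vh, wood = sapwood_properties()) {
  stopifnot(inherits(wood, "sapwood_properties"))
  sap_flow_factor(wood) * vh
}

# L/h per cm/h of velocity; shared with invert_to_heat_pulse()
sap_flow_factor <- function(wood) {
  (wood$rho_b / wood$rho_s) * (wood$m_c + wood$C_w / wood$C_s) *
    wood$S / 1000
}

#' Combine per-depth velocities into a plant-level velocity
#'
#' Weighted mean across installation depths; by default all depths weigh
#' equally.
#'
#' @param velocities named numeric vector or a data frame / matrix whose
#'   columns are depths.
#' @param weights optional named nonnegative weights over the same depths.
#' @return The combined velocity (vector if `velocities` has rows).
#' @export
combine_depths <- function(velocities, weights = NULL) {
  if (is.data.frame(velocities)) velocities <- as.matrix(velocities)
  if (is.matrix(velocities)) {
    nms <- colnames(velocities)
  } else {
    nms <- names(velocities)
    velocities <- matrix(velocities, nrow = 1,
                         dimnames = list(NULL, nms))
  }
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(nms)), nms)
  }
  if (is.null(nms) || is.null(names(weights)) ||
      !setequal(nms, names(weights)))
    stop_sapflux("depth keys of `velocities` and `weights` do not match")
  w <- weights[nms]
  if (any(w < 0) || sum(w) <= 0)
    stop_sapflux("weights must be nonnegative with positive sum")
  drop(velocities %*% (w / sum(w)))
}

#' Daily cumulative sap flow
#'
#' Trapezoidal time-integration of the flow series within each calendar day
#' (in the timestamps' own timezone).  Days whose largest sampling gap
#' exceeds `max_gap_min` are flagged rather than silently integrated; days
#' without samples are absent from the output.
#'
#' @param timestamps sorted POSIXct vector.
#' @param flow sap flow, L/h, parallel to `timestamps`.
#' @param max_gap_min gap threshold in minutes.
#' @return Data frame `date, total_l, n, max_gap_min, gap_flag`.
#' @export
daily_cumulative <- function(timestamps, flow, max_gap_min = 30) {
  stopifnot(length(timestamps) == length(flow))
  if (is.unsorted(timestamps, strictly = FALSE))
    stop_sapflux("timestamps must be sorted", class = "sapflux_domain_error")
  if (length(flow) < 2)
    return(data.frame(date = as.Date(character()), total_l = numeric(),
                      n = integer(), max_gap_min = numeric(),
                      gap_flag = logical()))
  # each trapezoidal segment is assigned to the calendar day of its left
  # edge, so a series covering exactly 24 h integrates to the full day
  tz <- attr(timestamps, "tzone") %||% "UTC"
  seg_day <- as.Date(timestamps[-length(timestamps)], tz = tz)
  dt_h <- diff(as.numeric(timestamps)) / 3600
  seg <- dt_h * (head(flow, -1) + tail(flow, -1)) / 2
  out <- lapply(split(seq_along(seg), seg_day), function(ix) {
    data.frame(total_l = sum(seg[ix]), n = length(ix) + 1L,
               max_gap_min = max(dt_h[ix]) * 60,
               gap_flag = max(dt_h[ix]) * 60 > max_gap_min)
  })
  res <- cbind(date = as.Date(names(out)), do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Process a raw heat-pulse table into sap flow
#'
#' Runs the full HRM chain per plant: velocity from the temperature-rise
#' ratio at each depth, optional zero-offset correction (per plant and
#' depth), wound polynomial, depth combination and conversion to L/h.
#'
#' @param raw data frame with columns `timestamp, plant_id, depth_mm` and
#'   either `ratio` or `t1_c` + `t2_c`.
#' @param geom a [probe_geometry()].
#' @param wood a [sapwood_properties()].
#' @param wound wound-correction coefficients, see [wound_correction()].
#' @param baseline_window optional `c(start, end)` POSIXct zero-flow window.
#' @param af optional agroforestry label (single value or named vector by
#'   plant id) propagated to the output.
#' @param weights optional depth weights for [combine_depths()].
#' @return Data frame `timestamp, plant_id, af, vh_cm_h, vs_l_h`, one row
#'   per plant and timestamp.
#' @export
process_heat_pulse <- function(raw, geom = probe_geometry(),
                               wood = sapwood_properties(),
                               wound = c(1, 0, 0), baseline_window = NULL,
                               af = NA_character_, weights = NULL) {
  need <- c("timestamp", "plant_id", "depth_mm")
  if (!all(need %in% names(raw)))
    stop_sapflux(paste("missing columns:",
                       paste(setdiff(need, names(raw)), collapse = ", ")),
                 class = "sapflux_schema_error")
  if (!"ratio" %in% names(raw)) {
    if (!all(c("t1_c", "t2_c") %in% names(raw)))
      stop_sapflux("need either `ratio` or `t1_c` and `t2_c` columns",
                   class = "sapflux_schema_error")
    raw$ratio <- raw$t1_c / raw$t2_c
  }
  pieces <- lapply(split(raw, raw$plant_id), function(d) {
    byd <- lapply(split(d, d$depth_mm), function(dd) {
      dd <- dd[order(dd$timestamp), ]
      vh <- heat_pulse_velocity(dd$ratio, geom, timestamps = dd$timestamp)
      if (!is.null(baseline_window))
        vh <- zero_offset_correction(vh, dd$timestamp, baseline_window)
      data.frame(timestamp = dd$timestamp, vh = as.numeric(vh))
    })
    ts0 <- byd[[1]]$timestamp
    mat <- vapply(byd, function(x) x$vh, numeric(length(ts0)))
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(NULL, names(byd)))
    vh <- combine_depths(mat, weights)
    vh <- wound_correction(vh, wound)
    data.frame(timestamp = ts0, plant_id = d$plant_id[1],
               vh_cm_h = vh, vs_l_h = sap_flow_rate(vh, wood))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$af <- if (length(af) > 1) unname(af[as.character(out$plant_id)])
            else af
  out[order(out$timestamp, out$plant_id),
      c("timestamp", "plant_id", "af", "vh_cm_h", "vs_l_h")]
}

## ---- CSV interfaces ------------------------------------------------------

parse_timestamp <- function(x, tz = "Etc/GMT+5") {
  if (inherits(x, "POSIXct")) return(x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = tz)
  if (anyNA(out))
    stop_sapflux("unparseable timestamps (expected ISO-8601)",
                 class = "sapflux_schema_error")
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")

check_columns <- function(d, need, what) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_sapflux(paste0(what, ": missing column(s) ",
                        paste(miss, collapse = ", ")),
                 class = "sapflux_schema_error")
  invisible(d)
}

#' Read a raw heat-pulse CSV
#'
#' Expected columns: `timestamp, plant_id, depth_mm` plus `ratio` or
#' `t1_c, t2_c`; ISO-8601 timestamps.
#'
#' @param path file path.
#' @param tz timezone of the timestamps (local offset; default UTC-5).
#' @return Data frame with parsed timestamps.
#' @export
read_heat_pulse_csv <- function(path, tz = "Etc/GMT+5") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("timestamp", "plant_id", "depth_mm"), path)
  if (!("ratio" %in% names(d)) && !all(c("t1_c", "t2_c") %in% names(d)))
    stop_sapflux(paste0(path, ": need `ratio` or `t1_c`+`t2_c`"),
                 class = "sapflux_schema_error")
  d$timestamp <- parse_timestamp(d$timestamp, tz)
  d
}

#' Read a microclimate CSV
#'
#' Expected columns: `timestamp, af, rh_a_pct, t_a_c, par_umol_m2_s`
#' (optionally `vpd_kpa`; if absent it is derived per sample).
#'
#' @inheritParams read_heat_pulse_csv
#' @return Data frame with parsed timestamps and a `vpd_kpa` column.
#' @export
read_microclimate_csv <- function(path, tz = "Etc/GMT+5") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(d, c("timestamp", "af", "rh_a_pct", "t_a_c",
                     "par_umol_m2_s"), path)
  d$timestamp <- parse_timestamp(d$timestamp, tz)
  if (!"vpd_kpa" %in% names(d))
    d$vpd_kpa <- vpd(d$t_a_c, d$rh_a_pct)
  d
}

#' Write a processed sap-flow CSV
#'
#' Columns: `timestamp, plant_id, af, vh_cm_h, vs_l_h`.
#'
#' @param x processed data frame (from [process_heat_pulse()]).
#' @param path output path.
#' @export
write_sap_flow_csv <- function(x, path) {
  check_columns(x, c("timestamp", "plant_id", "af", "vh_cm_h", "vs_l_h"),
                "sap flow table")
  x$timestamp <- format_timestamp(x$timestamp)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
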