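# Microclimate derivations: saturation vapor pressure and vapor pressure
# deficit (FAO-56 formulation), day/night classification, hourly slot
# summaries and between-system comparisons (Fisher's LSD letters).

#' Saturation vapor pressure
#'
#' Tetens-type FAO-56 formula
#' \deqn{e_s(T) = 0.6108\,\exp(17.27\,T / (T + 237.3))}
#' strictly increasing in temperature.
#'
#' @param t_a air temperature, degC (> -237.3).
#' @return Saturation vapor pressure, kPa.
#' @export
saturation_vapor_pressure <- function(t_a) {
  if (any(t_a <= -237.3))
    stop_sapflux("temperature outside the physical range of the formula")
  0.6108 * exp(17.27 * t_a / (t_a + 237.3))
}

#' Vapor pressure deficit from instantaneous temperature and humidity
#'
#' \deqn{VPD = e_s(T_a)\,(1 - RH_a/100)}
#'
#' Computed per sample, before any averaging: because the formula is
#' nonlinear, the mean of minute-level VPD over an hour is generally not the
#' VPD of the hour's mean temperature and humidity.
#'
#' @param t_a air temperature, degC.
#' @param rh_a air relative humidity, % (0-100).
#' @param lenient if `TRUE`, humidity slightly outside \[0, 100\] is clipped
#'   (with a warning) instead of raising an error.
#' @return VPD, kPa (>= 0; exactly 0 at saturation).
#' @export
vpd <- function(t_a, rh_a, lenient = FALSE) {
  bad <- !is.finite(rh_a) | rh_a < 0 | rh_a > 100
  if (any(bad)) {
    if (!lenient)
      stop_sapflux(paste0("relative humidity outside [0, 100] at position(s) ",
                          paste(head(which(bad), 5), collapse = ", ")),
                   class = "sapflux_domain_error")
    warning(sprintf("clipped %d humidity value(s) into [0, 100]", sum(bad)))
    rh_a <- pmin(100, pmax(0, rh_a))
  }
  saturation_vapor_pressure(t_a) * (1 - rh_a / 100)
}

#' Slot-level VPD from period extremes
#'
#' Secondary FAO-56 estimator based on the maximum and minimum temperature
#' and humidity of a period: mean saturation pressure at the temperature
#' extremes minus the actual vapor pressure estimated from the paired
#' extremes.  Provided for comparison with the instantaneous estimator,
#' which is the one used throughout the package.
#'
#' @param t_max,t_min period temperature extremes, degC.
#' @param rh_max,rh_min period humidity extremes, %.
#' @return VPD, kPa.
#' @export
vpd_from_extremes <- function(t_max, t_min, rh_max, rh_min) {
  es <- (saturation_vapor_pressure(t_max) +
           saturation_vapor_pressure(t_min)) / 2
  ea <- (saturation_vapor_pressure(t_min) * rh_max / 100 +
           saturation_vapor_pressure(t_max) * rh_min / 100) / 2
  es - ea
}

local_hour <- function(timestamps) {
  as.POSIXlt(timestamps)$hour + as.POSIXlt(timestamps)$min / 60
}

#' Classify samples as day or night
#'
#' Either by local hour (day iff `day_start <= hour < day_end`) or by a PAR
#' threshold (day iff `par > par_threshold`).
#'
#' @param x data frame with a `timestamp` column (and `par_umol_m2_s` for
#'   the PAR mode), or a POSIXct vector.
#' @param method `"hour"` (default) or `"par"`.
#' @param day_start,day_end local-hour day boundaries.
#' @param par_threshold PAR threshold, umol m-2 s-1.
#' @return Character vector `"day"`/`"night"`.
#' @export
classify_day_night <- function(x, method = c("hour", "par"),
                               day_start = 6, day_end = 18,
                               par_threshold = 5) {
  method <- match.arg(method)
  if (method == "par") {
    par <- if (is.data.frame(x)) x$par_umol_m2_s else x
    return(ifelse(par > par_threshold, "day", "night"))
  }
  ts <- if (is.data.frame(x)) x$timestamp else x
  h <- local_hour(ts)
  ifelse(h >= day_start & h < day_end, "day", "night")
}

#' Hourly slot summaries per system
#'
#' Mean and standard error (SD/sqrt(n)) of each variable over the samples
#' whose local hour equals the slot hour, per agroforestry system.  PAR is
#' omitted for night slots.  Slots with a single sample get SE 0 and a
#' degenerate flag; empty slots are absent.
#'
#' @param data microclimate data frame (`timestamp, af, rh_a_pct, t_a_c,
#'   par_umol_m2_s, vpd_kpa`).
#' @param slot_hours integer hours of day to summarise.
#' @param day_start,day_end hours defining day (for the PAR omission).
#' @return Data frame `af, hour, variable, mean, se, n, degenerate`.
#' @export
slot_summary <- function(data, slot_hours = c(10, 13, 16, 20, 0, 4),
                         day_start = 6, day_end = 18) {
  if (!nrow(data)) stop_sapflux("empty microclimate series")
  check_columns(data, c("timestamp", "af", "rh_a_pct", "t_a_c",
                        "par_umol_m2_s", "vpd_kpa"), "slot_summary")
  hour <- floor(local_hour(data$timestamp))
  vars <- c("rh_a_pct", "t_a_c", "par_umol_m2_s", "vpd_kpa")
  rows <- list()
  for (af in unique(data$af)) for (h in slot_hours) {
    sl <- data[data$af == af & hour == h, ]
    if (!nrow(sl)) next
    use <- if (h >= day_start && h < day_end) vars
           else setdiff(vars, "par_umol_m2_s")
    for (v in use) {
      x <- sl[[v]]
      rows[[length(rows) + 1]] <- data.frame(
        af = af, hour = h, variable = v, mean = mean(x),
        se = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
        n = length(x), degenerate = length(x) < 2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# compact letter display from a logical "significantly different" matrix;
# groups must be ordered by descending mean.  Enumerate subsets (k is tiny),
# keep maximal cliques of the not-different graph, letter them in order.
cld_letters <- function(sig) {
  k <- nrow(sig)
  if (k == 1) return("a")
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  ok <- vapply(subsets, function(s) {
    all(!sig[s, s, drop = FALSE][upper.tri(matrix(0, length(s), length(s)))])
  }, logical(1))
  cliques <- subsets[ok]
  maximal <- cliques[vapply(cliques, function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))]
  maximal <- maximal[order(vapply(maximal, min, integer(1)))]
  out <- character(k)
  for (i in seq_along(maximal))
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  out
}

#' Compare systems within each hourly slot (Fisher's LSD)
#'
#' One-way comparison of the system means of a variable within each slot:
#' omnibus F test, then all unadjusted pairwise t tests using the pooled
#' residual variance (Fisher's least significant difference), with compact
#' letters assigned in order of descending mean - groups sharing a letter do
#' not differ at `alpha`.
#'
#' @param data microclimate data frame (see [slot_summary()]).
#' @param variable one of `rh_a_pct, t_a_c, par_umol_m2_s, vpd_kpa`.
#' @param slot_hours slots to test.
#' @param alpha significance level for the pairwise tests.
#' @return Data frame `hour, af, mean, letter, omnibus_p, degenerate`; the
#'   pairwise p-values are attached as attribute `"pairwise"`.
#' @export
compare_afs <- function(data, variable, slot_hours = c(10, 13, 16, 20, 0, 4),
                        alpha = 0.05) {
  check_columns(data, c("timestamp", "af", variable), "compare_afs")
  hour <- floor(local_hour(data$timestamp))
  res <- list(); pw <- list()
  for (h in slot_hours) {
    sl <- data[hour == h & is.finite(data[[variable]]), ]
    cnt <- table(sl$af)
    if (length(cnt) < 2 || any(cnt < 2) || var(sl[[variable]]) == 0) {
      res[[length(res) + 1]] <- data.frame(
        hour = h, af = names(cnt) %||% NA_character_,
        mean = if (length(cnt)) tapply(sl[[variable]], sl$af, mean) else NA,
        letter = NA_character_, omnibus_p = NA_real_, degenerate = TRUE)
      next
    }
    g <- factor(sl$af)
    fit <- aov(sl[[variable]] ~ g)
    an <- anova(fit)
    mse <- an[["Mean Sq"]][2]; dfres <- an[["Df"]][2]
    omni <- an[["Pr(>F)"]][1]
    means <- tapply(sl[[variable]], g, mean)
    ns <- tapply(sl[[variable]], g, length)
    ord <- order(means, decreasing = TRUE)
    means <- means[ord]; ns <- ns[ord]
    k <- length(means)
    sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tval <- (means[i] - means[j]) /
        sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      p <- 2 * pt(-abs(tval), dfres)
      sig[i, j] <- sig[j, i] <- p < alpha
      pw[[length(pw) + 1]] <- data.frame(
        hour = h, af_a = names(means)[i], af_b = names(means)[j],
        estimate = unname(means[i] - means[j]), p = p)
    }
    res[[length(res) + 1]] <- data.frame(
      hour = h, af = names(means), mean = as.numeric(means),
      letter = cld_letters(sig), omnibus_p = omni, degenerate = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "pairwise") <- do.call(rbind, pw)
  out
}
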