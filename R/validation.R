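# Goodness-of-fit and diagnostic statistics: RMSE, percent bias,
# Nash-Sutcliffe efficiency, observed-versus-predicted regression with a
# slope-vs-identity test, correlation tables, holdout splitting and
# nocturnal (reverse-flow) summaries.

check_pair <- function(obs, pred, min_n = 2) {
  if (length(obs) != length(pred))
    stop_sapflux("obs and pred must have the same length",
                 class = "sapflux_domain_error")
  if (length(obs) < min_n)
    stop_sapflux(sprintf("need at least %d paired values", min_n),
                 class = "sapflux_domain_error")
  invisible(NULL)
}

#' Root mean square error
#'
#' `sqrt(mean((pred - obs)^2))`, in the units of the inputs (L/h for sap
#' flow).
#'
#' @param obs,pred observed and predicted series.
#' @return RMSE (>= 0).
#' @export
rmse <- function(obs, pred) {
  check_pair(obs, pred)
  sqrt(mean((pred - obs)^2))
}

#' Percent bias
#'
#' `100 * sum(pred - obs) / sum(obs)`.  Positive values mean the model
#' overpredicts (this sign convention is used in all output headers).
#'
#' @inheritParams rmse
#' @return Percent bias, %.
#' @export
pbias <- function(obs, pred) {
  check_pair(obs, pred)
  100 * sum(pred - obs) / sum(obs)
}

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`.  1 is a perfect
#' model; 0 is no better than predicting the observed mean; negative values
#' are worse than the mean.
#'
#' @inheritParams rmse
#' @return NSE (<= 1).
#' @export
nse <- function(obs, pred) {
  check_pair(obs, pred)
  ss_obs <- sum((obs - mean(obs))^2)
  if (ss_obs == 0)
    stop_sapflux("observations have zero variance; NSE undefined",
                 class = "sapflux_domain_error")
  1 - sum((pred - obs)^2) / ss_obs
}

#' Observed-versus-predicted regression
#'
#' Least-squares regression of the observations on the predictions
#' (observed on the y axis), its R-squared, and a t test of the regression
#' slope against the identity line (slope 1).  With a perfect fit the slope
#' SE is 0 and the test is undefined; `slope_vs_1_p` is then `NA` with
#' `perfect = TRUE`.
#'
#' @inheritParams rmse
#' @return One-row data frame `slope, intercept, r2, slope_se,
#'   slope_vs_1_p, perfect, n`.
#' @export
obs_pred_regression <- function(obs, pred) {
  check_pair(obs, pred, min_n = 3)
  if (var(pred) == 0)
    stop_sapflux("predictions have zero variance",
                 class = "sapflux_domain_error")
  fit <- lm(obs ~ pred)
  # exact fits are legitimate here (handled via `perfect` below); silence
  # summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  slope <- coef(fit)[["pred"]]
  slope_se <- sm$coefficients["pred", "Std. Error"]
  perfect <- isTRUE(all.equal(obs, pred)) || slope_se == 0
  p <- if (perfect) NA_real_ else
    2 * pt(-abs((slope - 1) / slope_se), df = fit$df.residual)
  data.frame(slope = slope, intercept = coef(fit)[["(Intercept)"]],
             r2 = sm$r.squared, slope_se = slope_se, slope_vs_1_p = p,
             perfect = perfect, n = length(obs))
}

#' Validation metric bundle
#'
#' RMSE, percent bias, NSE and the observed-versus-predicted regression in
#' one row, the shape written by the pipeline's metrics CSV.
#'
#' @inheritParams rmse
#' @param label optional label column (e.g. the system).
#' @return One-row data frame `af, n, rmse, pbias_pct, nse, r2, slope,
#'   intercept, slope_vs_1_p`.
#' @export
validation_metrics <- function(obs, pred, label = NA_character_) {
  reg <- obs_pred_regression(obs, pred)
  data.frame(af = label, n = length(obs), rmse = rmse(obs, pred),
             pbias_pct = pbias(obs, pred), nse = nse(obs, pred),
             r2 = reg$r2, slope = reg$slope, intercept = reg$intercept,
             slope_vs_1_p = reg$slope_vs_1_p)
}

#' Pearson correlations between sap flow and the microclimate covariates
#'
#' Correlation (and p-value) of the response with each covariate, per
#' system and pooled (`"General"`).  Cells with a constant column are
#' flagged `NA`.
#'
#' @param data data frame with `af`, the response and covariate columns.
#' @param response response column.
#' @param covariates covariate columns.
#' @return Data frame `group, variable, r, p, n`.
#' @export
correlation_table <- function(data, response = "vs_l_h",
                              covariates = .default_covariates) {
  check_columns(data, c("af", response, covariates), "correlation_table")
  groups <- c(list(General = data), split(data, data$af))
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (v in covariates) {
      ok <- nrow(d) >= 3 && var(d[[v]]) > 0 && var(d[[response]]) > 0
      if (ok) {
        ct <- cor.test(d[[response]], d[[v]])
        out[[length(out) + 1]] <- data.frame(
          group = g, variable = term_label(v),
          r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
      } else {
        out[[length(out) + 1]] <- data.frame(
          group = g, variable = term_label(v),
          r = NA_real_, p = NA_real_, n = nrow(d))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a dataset into fitting and validation parts
#'
#' Chronological-tail split by default: the last `fraction` of rows in
#' timestamp order become the validation set.  `mode = "random"` samples
#' the validation rows instead (seedable).
#'
#' @param data data frame (needs a `timestamp` column for the
#'   chronological mode).
#' @param fraction validation fraction, strictly between 0 and 1.
#' @param mode `"chronological"` or `"random"`.
#' @param seed optional seed for the random mode.
#' @return List `fit`, `validation`; sizes in attribute `"sizes"`.
#' @export
holdout_split <- function(data, fraction,
                          mode = c("chronological", "random"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!(fraction > 0 && fraction < 1))
    stop_sapflux("fraction must be in (0, 1)")
  n <- nrow(data)
  n_val <- round(n * fraction)
  if (n_val < 1 || n - n_val < 1)
    stop_sapflux("split would produce an empty part",
                 class = "sapflux_domain_error")
  if (mode == "chronological") {
    check_columns(data, "timestamp", "holdout_split")
    ord <- order(data$timestamp)
    val_ix <- ord[(n - n_val + 1):n]
  } else {
    if (!is.null(seed)) set.seed(seed)
    val_ix <- sample.int(n, n_val)
  }
  out <- list(fit = data[-val_ix, , drop = FALSE],
              validation = data[val_ix, , drop = FALSE])
  attr(out, "sizes") <- c(fit = n - n_val, validation = n_val)
  out
}

#' Nocturnal flow summary and reversed-flow proportion
#'
#' Per system: mean and standard error of the nocturnal sap flow, a
#' two-sided one-sample t test of the nocturnal mean against zero, and the
#' volume-weighted proportion of the full day's flow that is reversed
#' (basipetal): 100 * |integrated negative flow| / integrated |flow|, with
#' per-sample time weights from the timestamp spacing.
#'
#' @param data data frame `timestamp, af, vs_l_h`.
#' @param labels `"day"`/`"night"` labels parallel to `data` (defaults to
#'   [classify_day_night()] on the timestamps).
#' @return Data frame `af, n_night, nocturnal_mean, nocturnal_se, t, p,
#'   reversed_pct`.
#' @export
nocturnal_summary <- function(data, labels = NULL) {
  check_columns(data, c("timestamp", "af", "vs_l_h"), "nocturnal_summary")
  if (is.null(labels)) labels <- classify_day_night(data)
  if (!any(labels == "night"))
    stop_sapflux("no night samples", class = "sapflux_domain_error")
  out <- lapply(split(seq_len(nrow(data)), data$af), function(ix) {
    d <- data[ix, ]; lab <- labels[ix]
    d <- d[order(d$timestamp), ]; lab <- lab[order(d$timestamp)]
    night <- d$vs_l_h[lab == "night"]
    if (!length(night))
      stop_sapflux(paste("no night samples for", d$af[1]),
                   class = "sapflux_domain_error")
    tt <- tryCatch(t.test(night, mu = 0),
                   error = function(e)
                     list(statistic = c(t = NA_real_), p.value = NA_real_))
    # time weights: midpoint spacing, L/h * h -> litres
    ts_h <- as.numeric(d$timestamp) / 3600
    w <- diff(ts_h)
    w <- c(w[1] / 2, (head(w, -1) + tail(w, -1)) / 2, w[length(w)] / 2)
    vol <- d$vs_l_h * w
    data.frame(af = d$af[1], n_night = length(night),
               nocturnal_mean = mean(night),
               nocturnal_se = sd(night) / sqrt(length(night)),
               t = unname(tt$statistic), p = tt$p.value,
               reversed_pct = 100 * sum(abs(vol[vol < 0])) / sum(abs(vol)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
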