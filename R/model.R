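# The core estimator: a linear (mixed) model predicting sap flow from the
# four microclimate covariates with a separate intercept and separate
# slopes for every agroforestry system (full dummy interaction), and
# crossed random intercepts for plant and day.

.default_covariates <- c("rh_a_pct", "t_a_c", "par_umol_m2_s", "vpd_kpa")
# pretty term names aligned with sapflow_coefficients()
.term_names <- c(rh_a_pct = "rh_a", t_a_c = "t_a",
                 par_umol_m2_s = "par", vpd_kpa = "vpd")

term_label <- function(col) {
  unname(ifelse(is.na(.term_names[col]), col, .term_names[col]))
}

#' Build the fixed-effect design matrix
#'
#' Full-interaction dummy coding: one intercept and one slope per covariate
#' for every system present, i.e. `n_af * (1 + n_covariates)` columns, in
#' block order (all terms of the first system, then the next).  Rows with an
#' unknown system label or a missing covariate raise an error naming their
#' indices.
#'
#' @param data data frame with an `af` column and the covariate columns.
#' @param covariates covariate column names.
#' @return The design matrix; column metadata in attributes `af` and `term`.
#' @export
build_design <- function(data, covariates = .default_covariates) {
  check_columns(data, c("af", covariates), "build_design")
  bad_af <- which(!data$af %in% af_levels())
  if (length(bad_af))
    stop_sapflux(paste0("unknown AF label at row(s) ",
                        paste(head(bad_af, 10), collapse = ", ")),
                 class = "sapflux_design_error")
  for (v in covariates) {
    bad <- which(!is.finite(data[[v]]))
    if (length(bad))
      stop_sapflux(paste0("missing/non-finite `", v, "` at row(s) ",
                          paste(head(bad, 10), collapse = ", ")),
                   class = "sapflux_design_error")
  }
  afs <- intersect(af_levels(), unique(data$af))
  cols <- list(); af_of <- character(); term_of <- character()
  for (af in afs) {
    ind <- as.numeric(data$af == af)
    cols[[paste0(af, ":beta0")]] <- ind
    af_of <- c(af_of, af); term_of <- c(term_of, "beta0")
    for (v in covariates) {
      cols[[paste0(af, ":", term_label(v))]] <- ind * data[[v]]
      af_of <- c(af_of, af); term_of <- c(term_of, term_label(v))
    }
  }
  X <- do.call(cbind, cols)
  structure(X, af = af_of, term = term_of)
}

#' Fit the system-stratified sap-flow model
#'
#' Fits \eqn{V_s = \beta_{0,g} + \beta_{1,g} RH_a + \beta_{2,g} T_a +
#' \beta_{3,g} PAR + \beta_{4,g} VPD} with a full set of coefficients per
#' system `g`, by REML with crossed random intercepts for plant and day
#' (`lme4::lmer`), or by ordinary least squares.  Random factors with fewer
#' than two levels are dropped with a warning; with none left the fit falls
#' back to OLS, to which the mixed fit reduces when the random-effect
#' variances are zero.
#'
#' @param data data frame with the response, `af`, the covariates, and the
#'   random-factor columns (a `day` column is derived from `timestamp` if
#'   absent).
#' @param covariates covariate column names.
#' @param response response column (L/h).
#' @param method `"reml"` (default) or `"ols"`.
#' @param random random-intercept factors; `nested = TRUE` uses day nested
#'   in plant instead of crossed factors.
#' @param nested see `random`.
#' @param quadratic covariate columns for which a centred squared term is
#'   added (per system); used by [select_model()].
#' @return An object of class `sapflow_model` with `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `simulate` and `plot`
#'   methods.
#' @export
sapflow_model <- function(data, covariates = .default_covariates,
                          response = "vs_l_h",
                          method = c("reml", "ols"),
                          random = c("plant_id", "day"), nested = FALSE,
                          quadratic = character()) {
  method <- match.arg(method)
  check_columns(data, c(response, "af"), "sapflow_model")
  if (!"day" %in% names(data) && "timestamp" %in% names(data))
    data$day <- as.Date(data$timestamp,
                        tz = attr(data$timestamp, "tzone") %||% "UTC")
  sq_cols <- character()
  centers <- numeric()
  for (v in quadratic) {
    cn <- paste0(term_label(v), "_sq")
    centers[cn] <- mean(data[[v]])
    data[[cn]] <- (data[[v]] - centers[cn])^2
    sq_cols <- c(sq_cols, cn)
  }
  all_cov <- c(covariates, sq_cols)
  X <- build_design(data, all_cov)
  if (nrow(X) <= ncol(X))
    stop_sapflux("more fixed-effect columns than rows",
                 class = "sapflux_design_error")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_sapflux(paste0("singular design; collinear column(s): ",
                        paste(drop, collapse = ", ")),
                 class = "sapflux_design_error")
  }

  afs <- intersect(af_levels(), unique(data$af))
  # with a single system the dummy coding collapses to a plain intercept
  rhs <- if (length(afs) > 1)
    paste0("0 + af + af:(", paste(all_cov, collapse = " + "), ")")
  else paste(all_cov, collapse = " + ")
  use_random <- character()
  if (method == "reml") {
    for (r in random) {
      if (!r %in% names(data)) {
        warning(sprintf("random factor `%s` not in data; dropped", r))
      } else if (length(unique(data[[r]])) < 2) {
        warning(sprintf("random factor `%s` has < 2 levels; dropped", r))
      } else use_random <- c(use_random, r)
    }
    if (!length(use_random)) {
      warning("no usable random factors; falling back to OLS")
      method <- "ols"
    }
  }

  if (method == "reml") {
    re <- if (nested && length(use_random) == 2)
      sprintf("(1 | %s/%s)", use_random[1], use_random[2])
    else paste(sprintf("(1 | %s)", use_random), collapse = " + ")
    form <- stats::as.formula(paste(response, "~", rhs, "+", re))
    fit <- lme4::lmer(form, data = data, REML = TRUE,
                      control = lme4::lmerControl(check.scaleX = "ignore"))
    fe <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    vcl <- lme4::VarCorr(fit)
    ranef_sd <- c(vapply(vcl, function(m) sqrt(m[1, 1]), numeric(1)),
                  residual = attr(vcl, "sc"))
  } else {
    form <- stats::as.formula(paste(response, "~", rhs))
    fit <- lm(form, data = data)
    fe <- coef(fit)
    vc <- vcov(fit)
    ranef_sd <- c(residual = summary(fit)$sigma)
  }

  # map lmer/lm coefficient names (afH_PAR, afH_PAR:rh_a_pct, ...) to
  # (af, term)
  nms <- names(fe)
  terms <- c("beta0", term_label(all_cov))
  cmat <- semat <- matrix(NA_real_, length(afs), length(terms),
                          dimnames = list(afs, terms))
  key <- matrix(NA_character_, length(afs), length(terms),
                dimnames = list(afs, terms))
  ses <- sqrt(diag(vc))
  for (af in afs) {
    if (length(afs) > 1) {
      key[af, "beta0"] <- paste0("af", af)
      for (v in all_cov)
        key[af, term_label(v)] <- paste0("af", af, ":", v)
    } else {
      key[af, "beta0"] <- "(Intercept)"
      for (v in all_cov) key[af, term_label(v)] <- v
    }
  }
  if (!all(key %in% nms))
    stop_sapflux("internal: coefficient names did not match the design")
  cmat[] <- fe[key]; semat[] <- ses[key]

  ll <- logLik(fit)
  structure(list(
    fit = fit, method = method, response = response,
    covariates = covariates, quadratic = quadratic, centers = centers,
    random = use_random, nested = nested,
    coefficients = cmat, se = semat, vcov = vc, coef_key = key,
    ranef_sd = ranef_sd,
    logLik = as.numeric(ll), df = attr(ll, "df"), n = nrow(data),
    aic = AIC(fit), bic = BIC(fit),
    data = data, call = match.call()),
    class = "sapflow_model")
}

#' Predict sap flow from an explicit coefficient set
#'
#' Linear evaluation of the system-stratified model.  This is the single
#' code path shared by [true_sap_flow()] and by `predict` on fitted models
#' (without quadratic terms).
#'
#' @param coeffs data frame `af, beta0, rh_a, t_a, par, vpd` (see
#'   [sapflow_coefficients()]).
#' @param newdata data frame with `af` and the covariate columns
#'   `rh_a_pct, t_a_c, par_umol_m2_s, vpd_kpa`.
#' @return Predicted sap flow, L/h.
#' @export
predict_sapflow <- function(coeffs, newdata) {
  check_columns(newdata, c("af", .default_covariates), "predict_sapflow")
  miss <- setdiff(unique(newdata$af), coeffs$af)
  if (length(miss))
    stop_sapflux(paste("no coefficients for AF:",
                       paste(miss, collapse = ", ")))
  i <- match(newdata$af, coeffs$af)
  coeffs$beta0[i] +
    coeffs$rh_a[i] * newdata$rh_a_pct +
    coeffs$t_a[i] * newdata$t_a_c +
    coeffs$par[i] * newdata$par_umol_m2_s +
    coeffs$vpd[i] * newdata$vpd_kpa
}

as_coef_frame <- function(object) {
  cm <- object$coefficients
  data.frame(af = rownames(cm), beta0 = cm[, "beta0"],
             rh_a = cm[, "rh_a"], t_a = cm[, "t_a"],
             par = cm[, "par"], vpd = cm[, "vpd"], row.names = NULL)
}

#' @export
coef.sapflow_model <- function(object, ...) object$coefficients

#' Coefficient table of a fitted model
#'
#' @param object a fitted [sapflow_model()].
#' @param form `"absolute"` for per-system coefficients or `"difference"`
#'   for the reference-coded form (first system as reference, plus the
#'   contrast between the remaining two).
#' @return Data frame `af` (or `group`), `term, estimate, se, z, p`
#'   (two-sided Wald).
#' @export
coef_table <- function(object, form = c("absolute", "difference")) {
  form <- match.arg(form)
  stopifnot(inherits(object, "sapflow_model"))
  if (form == "absolute") {
    est <- as.vector(object$coefficients)
    se <- as.vector(object$se)
    out <- data.frame(
      af = rep(rownames(object$coefficients),
               ncol(object$coefficients)),
      term = rep(colnames(object$coefficients),
                 each = nrow(object$coefficients)),
      estimate = est, se = se)
  } else {
    afs <- rownames(object$coefficients)
    if (length(afs) < 2)
      stop_sapflux("difference form needs >= 2 systems")
    ref <- afs[1]
    rows <- list()
    for (tm in colnames(object$coefficients)) {
      rows[[length(rows) + 1]] <- data.frame(
        group = ref, term = tm,
        estimate = object$coefficients[ref, tm],
        se = object$se[ref, tm])
      for (af in afs[-1]) {
        ct <- coef_contrast(object, tm, af, ref)
        rows[[length(rows) + 1]] <- data.frame(
          group = paste0(af, "_minus_", ref), term = tm,
          estimate = ct[["estimate"]], se = ct[["se"]])
      }
      if (length(afs) >= 3) {
        ct <- coef_contrast(object, tm, afs[2], afs[3])
        rows[[length(rows) + 1]] <- data.frame(
          group = paste0(afs[2], "_vs_", afs[3]), term = tm,
          estimate = ct[["estimate"]], se = ct[["se"]])
      }
    }
    out <- do.call(rbind, rows)
  }
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  rownames(out) <- NULL
  out
}

coef_contrast <- function(object, term, af_a, af_b) {
  ka <- object$coef_key[af_a, term]; kb <- object$coef_key[af_b, term]
  est <- object$coefficients[af_a, term] - object$coefficients[af_b, term]
  v <- object$vcov[ka, ka] + object$vcov[kb, kb] - 2 * object$vcov[ka, kb]
  c(estimate = est, se = sqrt(max(v, 0)))
}

#' Wald contrast between two systems' slopes
#'
#' Difference of the two estimated coefficients for `variable`, with its
#' standard error from the fitted covariance and a two-sided Wald p-value.
#' Contrasting a system with itself returns estimate 0 and p = 1.
#'
#' @param object fitted [sapflow_model()].
#' @param variable covariate column name (or term name), or `"beta0"`.
#' @param af_a,af_b system labels.
#' @return One-row data frame `variable, af_a, af_b, estimate, se, z, p`.
#' @export
contrast_slopes <- function(object, variable, af_a, af_b) {
  stopifnot(inherits(object, "sapflow_model"))
  tm <- if (variable %in% colnames(object$coefficients)) variable
        else term_label(variable)
  if (!tm %in% colnames(object$coefficients))
    stop_sapflux(paste("unknown variable:", variable))
  afs <- rownames(object$coefficients)
  if (!all(c(af_a, af_b) %in% afs))
    stop_sapflux(paste("unknown AF label(s):",
                       paste(setdiff(c(af_a, af_b), afs), collapse = ", ")))
  if (af_a == af_b)
    return(data.frame(variable = tm, af_a = af_a, af_b = af_b,
                      estimate = 0, se = 0, z = 0, p = 1))
  ct <- coef_contrast(object, tm, af_a, af_b)
  z <- ct[["estimate"]] / ct[["se"]]
  data.frame(variable = tm, af_a = af_a, af_b = af_b,
             estimate = ct[["estimate"]], se = ct[["se"]], z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' @export
predict.sapflow_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (!length(object$quadratic))
    return(predict_sapflow(as_coef_frame(object), newdata))
  for (v in object$quadratic) {
    cn <- paste0(term_label(v), "_sq")
    newdata[[cn]] <- (newdata[[v]] - object$centers[cn])^2
  }
  X <- build_design(newdata, c(object$covariates,
                               paste0(term_label(object$quadratic), "_sq")))
  beta <- setNames(as.vector(object$coefficients),
                   as.vector(object$coef_key))
  xcols <- sub("^af([^:]+)$", "\\1:beta0", colnames(X))
  drop(X %*% beta[paste0("af", sub(":beta0$", "", xcols), ":",
                         sub("^[^:]+:", "", colnames(X)))])
}

#' @export
fitted.sapflow_model <- function(object, ...) fitted(object$fit)

#' @export
residuals.sapflow_model <- function(object, ...) residuals(object$fit)

#' @export
simulate.sapflow_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, object$data)
  n <- length(mu)
  sig <- object$ranef_sd[["residual"]]
  out <- replicate(nsim, {
    y <- mu + rnorm(n, 0, sig)
    for (r in object$random) {
      sd_r <- object$ranef_sd[[r]]
      if (!is.null(sd_r) && !is.na(sd_r)) {
        lev <- unique(object$data[[r]])
        y <- y + setNames(rnorm(length(lev), 0, sd_r),
                          lev)[as.character(object$data[[r]])]
      }
    }
    y
  })
  as.data.frame(out)
}

#' @export
print.sapflow_model <- function(x, digits = 5, ...) {
  cat("System-stratified sap-flow model (", toupper(x$method), ")\n",
      sep = "")
  cat(sprintf("n = %d; logLik = %.2f; AIC = %.1f; BIC = %.1f\n",
              x$n, x$logLik, x$aic, x$bic))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.sapflow_model <- function(object, ...) {
  out <- list(coefficients = coef_table(object, "absolute"),
              ranef_sd = object$ranef_sd, method = object$method,
              n = object$n, logLik = object$logLik,
              aic = object$aic, bic = object$bic)
  class(out) <- "summary.sapflow_model"
  out
}

#' @export
print.summary.sapflow_model <- function(x, ...) {
  cat("System-stratified sap-flow model (", toupper(x$method), ")\n",
      sep = "")
  cat(sprintf("n = %d; logLik = %.2f; AIC = %.1f; BIC = %.1f\n",
              x$n, x$logLik, x$aic, x$bic))
  cat("\nFixed effects (Wald):\n")
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, 5); cf$se <- signif(cf$se, 3)
  cf$z <- round(cf$z, 2); cf$p <- signif(cf$p, 3)
  print(cf, row.names = FALSE)
  cat("\nRandom-effect / residual SDs (L/h):\n")
  print(round(x$ranef_sd, 5))
  invisible(x)
}

#' Observed-versus-fitted diagnostic plot
#'
#' @param x fitted model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sapflow_model <- function(x, ...) {
  obs <- x$data[[x$response]]
  prd <- predict(x, x$data)
  graphics::plot(prd, obs, xlab = "predicted sap flow (L/h)",
                 ylab = "observed sap flow (L/h)",
                 pch = 16, cex = 0.4, col = "#00000044", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Rank candidate model specifications by AIC and BIC
#'
#' Fits each candidate (given as the set of covariates receiving an added
#' centred quadratic term; `character(0)` is the plain linear model) and
#' ranks by both criteria.  Ties are broken toward fewer parameters, then
#' earlier position in `candidates`.  Candidates that fail to fit are
#' excluded and recorded in the `"failed"` attribute.
#'
#' @param data model data frame.
#' @param candidates named list of character vectors.
#' @param ... passed to [sapflow_model()].
#' @return Data frame `candidate, n_par, aic, bic, aic_rank, bic_rank`.
#' @export
select_model <- function(data, candidates = list(linear = character()),
                         ...) {
  if (!length(candidates)) stop_sapflux("no candidates")
  fits <- list(); failed <- character()
  for (nm in names(candidates)) {
    f <- tryCatch(sapflow_model(data, quadratic = candidates[[nm]], ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, nm)
      message(sprintf("candidate `%s` failed: %s", nm,
                      conditionMessage(f)))
    } else fits[[nm]] <- f
  }
  if (!length(fits)) stop_sapflux("all candidates failed to fit")
  out <- data.frame(candidate = names(fits),
                    n_par = vapply(fits, function(f) f$df, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)),
                    bic = vapply(fits, function(f) f$bic, numeric(1)))
  idx <- seq_len(nrow(out))
  out$aic_rank <- rank_with_ties(out$aic, out$n_par, idx)
  out$bic_rank <- rank_with_ties(out$bic, out$n_par, idx)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  attr(out, "fits") <- fits
  out
}

rank_with_ties <- function(score, n_par, idx) {
  ord <- order(score, n_par, idx)
  rk <- integer(length(score)); rk[ord] <- seq_along(score)
  rk
}

#' Partial residuals and curvature diagnostic
#'
#' Partial residual = model residual + the fitted component of `variable`
#' (its per-system slope times the covariate).  The curvature flag is the
#' significance, at `alpha`, of the quadratic coefficient in a follow-up
#' regression of the partial residuals on the centred covariate and its
#' square - the standard check of whether a linear term suffices.
#'
#' @param object fitted [sapflow_model()].
#' @param variable covariate column name.
#' @param alpha significance level of the curvature test.
#' @return List with `partial_residuals`, `variable`, `quad_p`, `curved`.
#' @export
partial_residuals <- function(object, variable, alpha = 0.01) {
  stopifnot(inherits(object, "sapflow_model"))
  tm <- term_label(variable)
  if (!tm %in% colnames(object$coefficients))
    stop_sapflux(paste("variable not in model:", variable))
  x <- object$data[[variable]]
  if (var(x) == 0)
    stop_sapflux("constant covariate: no variance to diagnose",
                 class = "sapflux_domain_error")
  slope <- object$coefficients[object$data$af, tm]
  pr <- residuals(object) + slope * x
  xc <- x - mean(x)
  # the follow-up regression keeps per-system linear terms (the slopes
  # differ by system) and tests one shared quadratic coefficient
  af <- factor(object$data$af)
  qfit <- if (nlevels(af) > 1) lm(pr ~ af + af:xc + I(xc^2))
          else lm(pr ~ xc + I(xc^2))
  quad_p <- summary(qfit)$coefficients["I(xc^2)", "Pr(>|t|)"]
  list(partial_residuals = pr, variable = variable,
       quad_p = unname(quad_p), curved = quad_p < alpha)
}
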