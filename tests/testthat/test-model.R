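# The system-stratified mixed model: design construction, recovery,
# selection, diagnostics, contrasts

test_that("design matrix has one intercept and four slopes per system", {
  md <- small_campaign()$model_data
  X <- build_design(md)
  expect_equal(ncol(X), 15)
  expect_equal(attr(X, "term")[1:5],
               c("beta0", "rh_a", "t_a", "par", "vpd"))
  one <- build_design(md[md$af == "H_PAR", ])
  expect_equal(ncol(one), 5)
  bad <- md[1:10, ]; bad$vpd_kpa[c(3, 7)] <- NA
  expect_error(build_design(bad), "3, 7", class = "sapflux_design_error")
  bad2 <- md[1:5, ]; bad2$af[2] <- "nope"
  expect_error(build_design(bad2), "unknown AF label at row",
               class = "sapflux_design_error")
})

test_that("noiseless data is interpolated exactly; OLS equals REML", {
  md <- clean_campaign()$model_data
  gen <- sapflow_coefficients("reconciled")
  ols <- sapflow_model(md, method = "ols")
  for (af in af_levels())
    expect_equal(unname(coef(ols)[af, ]),
                 unname(unlist(gen[gen$af == af, -1])), tolerance = 1e-8)
  reml <- suppressWarnings(suppressMessages(sapflow_model(md)))
  expect_equal(coef(reml), coef(ols), tolerance = 1e-6)
})

test_that("fitted-model prediction and the explicit evaluator share a path", {
  md <- small_campaign()$model_data
  fit <- sapflow_model(md)
  co <- data.frame(af = rownames(coef(fit)), beta0 = coef(fit)[, "beta0"],
                   rh_a = coef(fit)[, "rh_a"], t_a = coef(fit)[, "t_a"],
                   par = coef(fit)[, "par"], vpd = coef(fit)[, "vpd"])
  expect_identical(predict(fit, md), predict_sapflow(co, md))
  # linearity: doubling PAR moves the prediction by beta_par * dPAR
  d1 <- md[1:20, ]; d2 <- d1; d2$par_umol_m2_s <- 2 * d1$par_umol_m2_s
  slope <- unname(coef(fit)[d1$af, "par"])
  expect_equal(predict(fit, d2) - predict(fit, d1),
               slope * d1$par_umol_m2_s, tolerance = 1e-10)
  # true_sap_flow is the same evaluator applied to a coefficient set
  ref <- sapflow_coefficients()
  sub <- md[md$af == "M_PAR", ]
  expect_identical(true_sap_flow(sub, ref, "M_PAR"),
                   predict_sapflow(ref, transform(sub, af = "M_PAR")))
})

test_that("information criteria are consistent with the log-likelihood", {
  md <- small_campaign()$model_data
  for (fit in list(sapflow_model(md), sapflow_model(md, method = "ols"))) {
    expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$df, tolerance = 1e-6)
    expect_equal(fit$bic, -2 * fit$logLik + fit$df * log(fit$n),
                 tolerance = 1e-6)
    expect_true(all(fit$se > 0))
  }
})

test_that("random factors degrade gracefully", {
  md <- small_campaign()$model_data
  one_plant <- md[md$plant_id == "H_PAR_p1", ]
  expect_warning(fit <- sapflow_model(one_plant), "plant_id.*dropped")
  expect_identical(fit$random, "day")
  w <- capture_warnings(
    fit2 <- sapflow_model(one_plant[one_plant$day == 1, ]))
  expect_true(any(grepl("OLS", w)))
  expect_identical(fit2$method, "ols")
})

test_that("singular designs are refused with the collinear column named", {
  md <- small_campaign()$model_data
  md$dup <- md$t_a_c
  expect_error(sapflow_model(md, covariates = c("t_a_c", "dup")),
               "collinear", class = "sapflux_design_error")
})

test_that("recovered coefficients are unbiased over repeated campaigns", {
  # Monte-Carlo mean of each of the 15 fixed effects over 10 seeds vs the
  # generating value, allowing 3 MC SEs for the 15 simultaneous checks
  gen <- sapflow_coefficients("reconciled")
  ests <- array(NA_real_, c(10, 3, 5),
                dimnames = list(NULL, af_levels(),
                                c("beta0", "rh_a", "t_a", "par", "vpd")))
  for (s in 1:10) {
    md <- simulate_campaign(small_config(seed = 100 + s, n_days = 5,
                                         rows_per_plant = 300))$model_data
    ests[s, , ] <- coef(sapflow_model(md))[af_levels(), ]
  }
  for (af in af_levels()) for (tm in dimnames(ests)[[3]]) {
    dev <- mean(ests[, af, tm]) - gen[gen$af == af, tm]
    mcse <- sd(ests[, af, tm]) / sqrt(10)
    expect_lt(abs(dev), 3 * mcse,
              label = sprintf("|MC bias of %s %s| = %.2g, 3 MC SE", af, tm,
                              abs(dev)))
  }
})

test_that("model selection ranks by AIC and BIC with stable tie-breaks", {
  md <- simulate_campaign(small_config(seed = 11, n_days = 4,
                                       rows_per_plant = 400,
                                       plant_effect_sd = 0,
                                       day_effect_sd = 0))$model_data
  out <- select_model(md, list(linear = character(),
                               quad_par = "par_umol_m2_s"),
                      method = "ols")
  expect_equal(out$candidate[out$bic_rank == 1], "linear")
  # duplicate candidates tie; the earlier one ranks first
  dup <- select_model(md, list(a = character(), b = character()),
                      method = "ols")
  expect_equal(dup$aic[1], dup$aic[2])
  expect_equal(dup$candidate[dup$aic_rank == 1], "a")
  single <- select_model(md, list(only = character()), method = "ols")
  expect_equal(single$aic_rank, 1)
})

test_that("the linear truth wins BIC across seeds", {
  wins <- 0
  for (s in 1:8) {
    md <- simulate_campaign(small_config(seed = 200 + s, n_days = 3,
                                         rows_per_plant = 250,
                                         plant_effect_sd = 0,
                                         day_effect_sd = 0))$model_data
    out <- select_model(md, list(linear = character(),
                                 quad = c("par_umol_m2_s", "t_a_c")),
                        method = "ols")
    wins <- wins + (out$candidate[out$bic_rank == 1] == "linear")
  }
  expect_gte(wins, 7)
})

test_that("partial residuals flag curvature only when it is generated", {
  flags <- logical(8)
  for (s in 1:8) {
    md <- simulate_campaign(small_config(seed = 300 + s, n_days = 3,
                                         rows_per_plant = 250))$model_data
    fit <- sapflow_model(md, method = "ols")
    flags[s] <- partial_residuals(fit, "par_umol_m2_s",
                                  alpha = 0.01)$curved
  }
  expect_gte(sum(!flags), 7)
  # inject a quadratic PAR component and expect detection
  md <- simulate_campaign(small_config(seed = 12, n_days = 4,
                                       rows_per_plant = 400))$model_data
  md$vs_l_h <- md$vs_l_h + 2e-8 * (md$par_umol_m2_s - 800)^2
  fitq <- sapflow_model(md, method = "ols")
  prq <- partial_residuals(fitq, "par_umol_m2_s", alpha = 0.01)
  expect_true(prq$curved)
  expect_length(prq$partial_residuals, nrow(md))
  # a constant covariate never reaches the diagnostic: the fit itself
  # refuses the singular design
  md$const <- 1
  expect_error(sapflow_model(md, covariates = c("rh_a_pct", "const"),
                             method = "ols"),
               class = "sapflux_design_error")
  expect_error(partial_residuals(fitq, "nope"), "not in model")
})

test_that("slope contrasts behave as Wald tests", {
  md <- small_campaign()$model_data
  fit <- sapflow_model(md)
  self <- contrast_slopes(fit, "vpd_kpa", "H_PAR", "H_PAR")
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
  hm <- contrast_slopes(fit, "vpd_kpa", "H_PAR", "M_PAR")
  expect_equal(hm$estimate,
               coef(fit)["H_PAR", "vpd"] - coef(fit)["M_PAR", "vpd"])
  expect_true(hm$p >= 0 && hm$p <= 1)
  expect_error(contrast_slopes(fit, "vpd_kpa", "H_PAR", "X"), "unknown AF")
  expect_error(contrast_slopes(fit, "nope", "H_PAR", "M_PAR"),
               "unknown variable")
  # the difference-form table reproduces the contrasts
  ctab <- coef_table(fit, "difference")
  mh <- ctab[ctab$group == "M_PAR_minus_H_PAR" & ctab$term == "vpd", ]
  expect_equal(mh$estimate,
               coef(fit)["M_PAR", "vpd"] - coef(fit)["H_PAR", "vpd"])
})

test_that("the reference VPD slope gap is detected at campaign scale", {
  # power check: H vs M VPD contrast at full n, a 0.078 L/h/kPa gap
  md <- reference_campaign()$model_data
  fit <- sapflow_model(md)
  expect_lt(contrast_slopes(fit, "vpd_kpa", "H_PAR", "M_PAR")$p, 0.01)
})

test_that("type-I error of slope contrasts is controlled", {
  # generate with identical t_a slopes for H and L; count false rejections
  co <- sapflow_coefficients("reconciled")
  co$t_a[co$af == "L_PAR"] <- co$t_a[co$af == "H_PAR"]
  rej <- 0; n_sim <- 12
  for (s in 1:n_sim) {
    md <- simulate_campaign(small_config(seed = 400 + s, n_days = 3,
                                         rows_per_plant = 250,
                                         coefficients = co))$model_data
    fit <- sapflow_model(md, method = "ols")
    rej <- rej + (contrast_slopes(fit, "t_a_c", "H_PAR", "L_PAR")$p < 0.05)
  }
  expect_lte(rej, 3)  # ~0.05 nominal; allow wide slack at 12 replicates
})

test_that("simulate() draws new responses around the fitted mean", {
  md <- small_campaign()$model_data
  fit <- sapflow_model(md, method = "ols")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(md), 2))
  expect_false(identical(sims[[1]], sims[[2]]))
  expect_lt(abs(mean(sims[[1]] - predict(fit, md))), 0.002)
})
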