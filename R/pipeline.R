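# End-to-end pipeline: a YAML-configurable chain of
# simulate -> process -> fit -> validate -> report steps, each writing CSVs
# into an output directory, plus a manifest with checksums.  A thin Rscript
# front end lives in inst/cli/sapflux.R (exit codes: 0 ok, 2 config/input
# error, 3 pipeline-order/schema error).

#' Pipeline configuration
#'
#' Builds the run configuration from defaults, an optional YAML file and
#' explicit overrides (in increasing precedence).  Keys: `seed`, `outdir`,
#' `probe` (`k_cm2_s, x_cm`), `wound` (`coeffs`), `wood` (`rho_b, rho_s,
#' m_c, C_w, C_s, S_cm2`), `generator` (fields of [generator_config()]),
#' `model` (`method, nested`), `split` (`fraction, mode`), `alpha`.
#'
#' @param path optional YAML file.
#' @param ... named overrides.
#' @return Nested list of class `sapflux_config`.
#' @export
sapflux_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 42,
    outdir = "sapflux_run",
    probe = list(k_cm2_s = 0.0025, x_cm = 0.6, depths_mm = c(5, 20)),
    wound = list(coeffs = c(1, 0, 0)),
    wood = list(rho_b = 500, rho_s = 1000, m_c = 1,
                C_w = 1200, C_s = 4186, S_cm2 = 40),
    generator = list(n_days = 14, interval_min = 1, n_plants = 4,
                     rows_per_plant = 1389, noise_sd = 0.015,
                     plant_effect_sd = 0.005, day_effect_sd = 0.005,
                     coefficient_set = "reconciled"),
    model = list(method = "reml", nested = FALSE),
    split = list(fraction = 1740 / 5556, mode = "chronological"),
    alpha = 0.05)
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_sapflux(paste("config file not found:", path),
                   class = "sapflux_config_error")
    cfg <- modify_list(cfg, yaml::read_yaml(path))
  }
  cfg <- modify_list(cfg, list(...))
  structure(cfg, class = "sapflux_config")
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
      modify_list(base[[nm]], new[[nm]]) else new[[nm]]
  }
  base
}

cfg_generator <- function(cfg) {
  g <- cfg$generator
  generator_config(seed = cfg$seed, n_days = g$n_days,
                   interval_min = g$interval_min, n_plants = g$n_plants,
                   rows_per_plant = g$rows_per_plant,
                   noise_sd = g$noise_sd,
                   plant_effect_sd = g$plant_effect_sd,
                   day_effect_sd = g$day_effect_sd,
                   coefficients = sapflow_coefficients(g$coefficient_set))
}

cfg_wood <- function(cfg) {
  w <- cfg$wood
  sapwood_properties(rho_b = w$rho_b, rho_s = w$rho_s, m_c = w$m_c,
                     C_w = w$C_w, C_s = w$C_s, S = w$S_cm2)
}

cfg_geom <- function(cfg) {
  probe_geometry(k = cfg$probe$k_cm2_s, x = cfg$probe$x_cm,
                 depths = cfg$probe$depths_mm)
}

write_with_manifest <- function(files, outdir, cfg) {
  manifest <- list(seed = cfg$seed,
                   created = format_timestamp(Sys.time()),
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

out_path <- function(cfg, name) file.path(cfg$outdir, name)

require_upstream <- function(cfg, files, stage) {
  missing <- files[!file.exists(out_path(cfg, files))]
  if (length(missing))
    stop_sapflux(paste0(stage, ": missing upstream output(s): ",
                        paste(missing, collapse = ", "),
                        " (run the earlier stages first)"),
                 class = "sapflux_order_error")
}

#' Pipeline stage: simulate
#'
#' Writes the synthetic CSV bundle: minute microclimate, raw heat-pulse
#' ratios, noiseless truth (with the generating coefficients) and a
#' manifest with md5 checksums.
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the written file paths.
#' @export
pipeline_simulate <- function(cfg = sapflux_config()) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  camp <- simulate_campaign(cfg_generator(cfg), raw_sensor = TRUE)
  mc <- camp$microclimate
  mc$timestamp <- format_timestamp(mc$timestamp)
  f1 <- out_path(cfg, "microclimate.csv")
  write.csv(mc[, c("timestamp", "af", "rh_a_pct", "t_a_c",
                   "par_umol_m2_s", "vpd_kpa")], f1,
            row.names = FALSE, quote = FALSE)
  raw <- camp$raw
  raw$timestamp <- format_timestamp(raw$timestamp)
  f2 <- out_path(cfg, "heat_pulse_raw.csv")
  write.csv(raw, f2, row.names = FALSE, quote = FALSE)
  tr <- camp$truth
  tr$timestamp <- format_timestamp(tr$timestamp)
  f3 <- out_path(cfg, "truth.csv")
  write.csv(tr, f3, row.names = FALSE, quote = FALSE)
  f4 <- out_path(cfg, "generating_coefficients.csv")
  write.csv(camp$config$coefficients, f4, row.names = FALSE, quote = FALSE)
  write_with_manifest(c(f1, f2, f3, f4), cfg$outdir, cfg)
}

#' Pipeline stage: process raw heat-pulse data into sap flow
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the processed CSV path.
#' @export
pipeline_process <- function(cfg = sapflux_config()) {
  require_upstream(cfg, "heat_pulse_raw.csv", "process")
  raw <- read_heat_pulse_csv(out_path(cfg, "heat_pulse_raw.csv"))
  af_of_plant <- NULL
  if (!is.null(raw$plant_id)) {
    ids <- unique(as.character(raw$plant_id))
    guess <- sub("_p[0-9]+$", "", ids)
    if (all(guess %in% af_levels()))
      af_of_plant <- setNames(guess, ids)
  }
  proc <- process_heat_pulse(raw, geom = cfg_geom(cfg),
                             wood = cfg_wood(cfg),
                             wound = cfg$wound$coeffs,
                             af = af_of_plant %||% NA_character_)
  f <- out_path(cfg, "sap_flow.csv")
  write_sap_flow_csv(proc, f)
  invisible(f)
}

merged_model_data <- function(cfg) {
  sf <- read.csv(out_path(cfg, "sap_flow.csv"), stringsAsFactors = FALSE)
  sf$timestamp <- parse_timestamp(sf$timestamp)
  mc <- read_microclimate_csv(out_path(cfg, "microclimate.csv"))
  m <- merge(sf, mc[, c("timestamp", "af", "rh_a_pct", "t_a_c",
                        "par_umol_m2_s", "vpd_kpa")],
             by = c("timestamp", "af"))
  if (!nrow(m))
    stop_sapflux("no overlap between sap flow and microclimate tables",
                 class = "sapflux_schema_error")
  m$day <- as.Date(m$timestamp, tz = attr(m$timestamp, "tzone") %||% "UTC")
  m[order(m$timestamp, m$plant_id), ]
}

#' Pipeline stage: fit the sap-flow model
#'
#' Merges the processed flow with the microclimate, holds out the
#' validation fraction, fits the model on the remainder and writes the
#' absolute and difference coefficient tables.
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the fitted model.
#' @export
pipeline_fit <- function(cfg = sapflux_config()) {
  require_upstream(cfg, c("sap_flow.csv", "microclimate.csv"), "fit")
  m <- merged_model_data(cfg)
  sp <- holdout_split(m, cfg$split$fraction, cfg$split$mode,
                      seed = cfg$seed)
  fit <- sapflow_model(sp$fit, method = cfg$model$method,
                       nested = isTRUE(cfg$model$nested))
  write.csv(coef_table(fit, "absolute"),
            out_path(cfg, "coefficients.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(coef_table(fit, "difference"),
            out_path(cfg, "contrasts.csv"),
            row.names = FALSE, quote = FALSE)
  saveRDS_path <- NULL # fitted model is recomputed by later stages
  invisible(fit)
}

#' Pipeline stage: validate the fitted model
#'
#' Refits on the fitting part of the split, predicts the held-out part and
#' writes per-system and pooled metrics, the correlation table and the
#' nocturnal summaries.
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the metrics data frame.
#' @export
pipeline_validate <- function(cfg = sapflux_config()) {
  require_upstream(cfg, c("sap_flow.csv", "microclimate.csv",
                          "coefficients.csv"), "validate")
  m <- merged_model_data(cfg)
  sp <- holdout_split(m, cfg$split$fraction, cfg$split$mode,
                      seed = cfg$seed)
  fit <- sapflow_model(sp$fit, method = cfg$model$method,
                       nested = isTRUE(cfg$model$nested))
  val <- sp$validation
  pred <- predict(fit, val)
  met <- do.call(rbind, c(
    lapply(split(seq_len(nrow(val)), val$af), function(ix)
      validation_metrics(val$vs_l_h[ix], pred[ix], val$af[ix][1])),
    list(validation_metrics(val$vs_l_h, pred, "pooled"))))
  write.csv(met, out_path(cfg, "metrics.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(correlation_table(m), out_path(cfg, "correlations.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(nocturnal_summary(m), out_path(cfg, "nocturnal.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(met)
}

#' Pipeline stage: report
#'
#' Writes a markdown summary juxtaposing the run's outputs with the bundled
#' reference tables (microclimate slot means, coefficient sets, correlation
#' signs, nocturnal anchors).
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the report path.
#' @export
pipeline_report <- function(cfg = sapflux_config()) {
  require_upstream(cfg, c("coefficients.csv", "metrics.csv",
                          "correlations.csv", "nocturnal.csv"), "report")
  co <- read.csv(out_path(cfg, "coefficients.csv"))
  met <- read.csv(out_path(cfg, "metrics.csv"))
  cor_t <- read.csv(out_path(cfg, "correlations.csv"))
  noct <- read.csv(out_path(cfg, "nocturnal.csv"))
  ref_c <- sapflow_coefficients("reconciled")
  lines <- c(
    "# sapflux run report", "",
    sprintf("seed: %d", cfg$seed), "",
    "## Fitted coefficients vs bundled reference set", "")
  for (af in af_levels()) {
    lines <- c(lines, sprintf("### %s", af), "",
               "| term | fitted | se | reference |",
               "|---|---|---|---|")
    for (tm in c("beta0", "rh_a", "t_a", "par", "vpd")) {
      row <- co[co$af == af & co$term == tm, ]
      if (!nrow(row)) next
      lines <- c(lines, sprintf("| %s | %.5f | %.5f | %.5f |", tm,
                                row$estimate, row$se,
                                ref_c[ref_c$af == af, tm]))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Holdout metrics", "",
             paste0("| ", paste(names(met), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(met)), collapse = "|"), "|"),
             apply(met, 1, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")), "",
             "## Correlation signs (reference: rh_a negative, others positive)",
             "")
  sign_ok <- with(cor_t[cor_t$group != "pooled", ],
                  ifelse(variable == "rh_a", r < 0, r > 0))
  lines <- c(lines,
             sprintf("sign pattern matches reference in %d/%d cells",
                     sum(sign_ok, na.rm = TRUE), sum(!is.na(sign_ok))), "",
             "## Nocturnal summaries vs reference", "",
             "| af | nocturnal mean | reference | reversed %% |",
             "|---|---|---|---|")
  ref_n <- nocturnal_reference()
  for (af in af_levels()) {
    r <- noct[noct$af == af, ]; rr <- ref_n[ref_n$af == af, ]
    if (!nrow(r)) next
    lines <- c(lines, sprintf("| %s | %+.4f | %+.4f | %.1f |", af,
                              r$nocturnal_mean, rr$nocturnal_mean,
                              r$reversed_pct))
  }
  f <- out_path(cfg, "report.md")
  writeLines(lines, f)
  invisible(f)
}

#' Run the whole pipeline
#'
#' `simulate`, `process`, `fit`, `validate`, `report`, in order.
#'
#' @param cfg a [sapflux_config()].
#' @return Invisibly, the output directory.
#' @export
pipeline_all <- function(cfg = sapflux_config()) {
  pipeline_simulate(cfg)
  pipeline_process(cfg)
  pipeline_fit(cfg)
  pipeline_validate(cfg)
  pipeline_report(cfg)
  invisible(cfg$outdir)
}
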