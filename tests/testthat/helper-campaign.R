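# shared fixtures: small synthetic campaigns, built once per run

.camp_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 42, n_days = 4, rows_per_plant = 240,
                         noise_sd = 0.015, plant_effect_sd = 0.005,
                         day_effect_sd = 0.005, ...) {
  generator_config(seed = seed, n_days = n_days,
                   rows_per_plant = rows_per_plant, noise_sd = noise_sd,
                   plant_effect_sd = plant_effect_sd,
                   day_effect_sd = day_effect_sd, ...)
}

cached_campaign <- function(key, config, ...) {
  if (is.null(.camp_cache[[key]]))
    .camp_cache[[key]] <- simulate_campaign(config, ...)
  .camp_cache[[key]]
}

# the default small campaign most tests share
small_campaign <- function() cached_campaign("small", small_config())

# noiseless campaign (no measurement noise, no random effects)
clean_campaign <- function() {
  cached_campaign("clean",
                  small_config(noise_sd = 0, plant_effect_sd = 0,
                               day_effect_sd = 0))
}

# full-size reference campaign at the default seed
reference_campaign <- function() {
  cached_campaign("reference", generator_config(seed = 42))
}

# chronological 3816/1740 split per system, mirroring the reference design
split_by_af <- function(model_data, fraction = 1740 / 5556) {
  parts <- lapply(split(model_data, model_data$af), holdout_split,
                  fraction = fraction)
  list(fit = do.call(rbind, lapply(parts, `[[`, "fit")),
       validation = do.call(rbind, lapply(parts, `[[`, "validation")))
}
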