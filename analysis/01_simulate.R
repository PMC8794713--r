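#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study at the default (study-emulating)
# conditions and write the raw data a field campaign would deliver:
# landscape mosaic, nests, observation sessions, landing points,
# arthropod samples and vegetation records, plus the generating truth.

suppressMessages(library(larkscape))

seed <- 42L
cfg <- study_config(rng_seed = seed)
truth <- sim_truth(rng_seed = seed)
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_dataset(truth, cfg)
write_tables(sim$data, out)
write_landscape(sim$landscape, file.path(out, "landscape.geojson"))
write_truth(truth, file.path(out, "truth.json"))

acc <- nest_accounting(sim$data$nests)
fs <- filter_safe_points(sim$data$landing_points)
cat(sprintf(
  "Simulated study written to %s\n  %d nests found: %d inactive, %d unobservable, %d too old -> %d observed\n  %d landing points (%.1f%% ambiguous, excluded from spatial analyses)\n  %d observation sessions, %d habitat patches\n",
  out, acc$n_found, acc$n_inactive, acc$n_unobservable,
  acc$n_chicks_too_old, acc$n_observed,
  fs$summary$n_total, fs$summary$excluded_pct,
  nrow(sim$data$sessions), length(sim$landscape$patches)))
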