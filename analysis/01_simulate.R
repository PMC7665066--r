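#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Six Tanzanian-like regions (alternating unimodal/bimodal rainfall
# regimes), harvest years 2009-2019 (2019 reserved for the independent
# holdout forecast), daily weather from the Bernoulli-gamma/sinusoid
# generator, three AR(1) monthly SST anomaly indices, and yields from the
# known ground-truth model (cdd5_v and three SST medians; linear log
# trend from a 1.6 t/ha level; noise sd 0.02).

suppressPackageStartupMessages(library(maizecast))

seed <- 20L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(n_regions = 6, years = 2009:2019, seed = seed)
truth <- synthetic_truth(seed = seed)
ds <- gen_dataset(cfg, truth)

write_sst_csv(ds$sst, file.path(out, "sst.csv"))
write_truth_json(truth, file.path(out, "truth.json"))
all_yields <- do.call(rbind, lapply(ds$regions, `[[`, "yields"))
write_yields_csv(all_yields, file.path(out, "yields.csv"))
for (i in seq_along(ds$regions)) {
  write_weather_csv(ds$regions[[i]]$weather,
                    file.path(out, sprintf("weather_region%d.csv", i)))
}

cat("Generated", cfg$n_regions, "regions x", length(cfg$years), "years\n")
for (i in seq_along(ds$regions)) {
  w <- ds$regions[[i]]$weather
  cat(sprintf("  region %d (%s): mean annual rain %.0f mm, mean tas %.1f C, yields %.2f-%.2f t/ha\n",
              i, attr(w, "regime"), sum(w$precip) / length(unique(w$year)),
              mean(w$tas), min(ds$regions[[i]]$yields$yield),
              max(ds$regions[[i]]$yields$yield)))
}
cat("True model:", paste(sprintf("%+.2f x %s", truth$true_betas,
                                 truth$true_feature_names), collapse = ", "),
    "\nInputs written to", out, "\n")
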