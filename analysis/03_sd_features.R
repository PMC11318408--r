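#!/usr/bin/env Rscript
# Stage 3 -- extract per-event SD features from the simulated episodes and
# score them against the generator's ground truth.
#
# Reads results/simulated/, writes results/features/.

library(oxyslice)

src <- "results/simulated"
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- read_study_config(system.file("extdata", "example_study.yaml",
                                     package = "oxyslice"))

rows <- list()
for (nm in names(cfg$scenarios)) {
  ep <- read_trace_set(file.path(src, paste0("episode_", nm, ".csv")))
  ft <- extract_sd_features(ep)
  truth <- jsonlite::read_json(
    file.path(src, paste0("episode_", nm, "_truth.json")),
    simplifyVector = TRUE)
  row <- as.data.frame(ft)
  row <- cbind(data.frame(condition = nm), row,
               data.frame(true_delta_k_mM = truth$delta_k,
                          true_dc_duration_s = truth$dc_duration,
                          true_t1_50_s = truth$t1_50,
                          true_t2_50_s = truth$t2_50))
  rows[[nm]] <- row
  message(sprintf(
    "  [%s] dK %.1f mM (truth %.1f), DC duration %.1f s (truth %.0f), T1_50 %.1f s, T2_50 %s s, core %s",
    nm, ft$delta_k, truth$delta_k, ft$dc_duration, truth$dc_duration,
    ft$t1_50, if (ft$t2_50_censored) "censored" else sprintf("%.1f", ft$t2_50),
    if (ft$hypoxia) "hypoxic" else "oxygenated"))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "episode_features.csv"), row.names = FALSE)
message("Wrote SD features to ", out)
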