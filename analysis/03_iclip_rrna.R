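#!/usr/bin/env Rscript
# iCLIP 18S crosslink-profile analysis on synthetic data: 3 asynchronous +
# 3 mitotic samples with the default injected 3.5-fold mitotic ES3SB
# effect. Normalizes, smooths (width-9 Gaussian, sd 2), summarises
# condition metaprofiles and quantifies the three analysis windows.
# Writes tables under results/iclip/.

suppressPackageStartupMessages(library(xlinktools))

out_dir <- "results/iclip"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

params <- clip_sim_params(seed = 20260927L)
sim <- simulate_crosslinks(params)
write_tsv_file(sim$crosslinks, file.path(out_dir, "crosslinks.tsv"))
write_crosslink_bed(sim$crosslinks, file.path(out_dir, "crosslinks.bed"))
write_tsv_file(sim$design, file.path(out_dir, "design.tsv"))
write_tsv_file(sim$truth, file.path(out_dir, "truth.tsv"))

res <- run_clip(sim$crosslinks, sim$design, params$reference,
                params$ref_length,
                conditions = c("asynchronous", "mitotic"))
write_tsv_file(res$condition_profiles,
               file.path(out_dir, "metaprofile_condition.tsv"))
write_tsv_file(res$windows, file.path(out_dir, "window_comparison.tsv"))
write_tsv_file(attr(res$windows, "window_sums"),
               file.path(out_dir, "window_sums.tsv"))

cat("Strongest asynchronous crosslink position (smoothed mean profile):\n")
asyn <- res$condition_profiles[
  res$condition_profiles$condition == "asynchronous", ]
cat("  position", asyn$position[which.max(asyn$mean)], "\n\n")
cat("Window quantification (fold change = mitotic / asynchronous):\n")
print(as.data.frame(res$windows[, c("window", "start", "end", "fold_change",
                                    "t", "df", "p", "low_n")]))
cat("\nInjected truth:\n")
print(as.data.frame(sim$truth))
cat("\nTables written to", out_dir, "\n")
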