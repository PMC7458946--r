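#!/usr/bin/env Rscript
# Stage 1: simulate the audit/study/site tables.
#
# The generator emulates the descriptive statistics of the quality-assurance
# dataset under study: ~86.7 audit/inspection activities per year over
# 2011-2018 (~13% inspections), 5.9 findings per activity, and per-CIF
# presence rates of 55/84/86/59/76%. Ground-truth log-odds effects mirror
# the reported risk-factor directions, so downstream stages can be checked
# against a known truth (results/data/truth.json).

suppressPackageStartupMessages(library(cifrisk))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- generator_config(seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, "results/data")

acts <- ds$activities
fc <- as.matrix(acts[paste0("findings_", cif_names())])
cat("simulated", nrow(acts), "activities over", cfg$n_years, "years;",
    sum(fc), "findings total\n")
cat(sprintf("  findings per activity: %.2f (target %.1f)\n",
            sum(fc) / nrow(acts), cfg$mean_findings_per_audit))
cat(sprintf("  inspections: %.1f%% (target %.0f%%)\n",
            100 * mean(acts$activity_type == "inspection"),
            100 * cfg$inspection_fraction))
for (cf in cif_names()) {
  cat(sprintf("  %-30s presence %.2f (target %.2f)\n", cf,
              mean(fc[, paste0("findings_", cf)] >= 1),
              cfg$cif_base_rates[[cf]]))
}
cat("tables written to results/data/\n")
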