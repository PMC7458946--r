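#!/usr/bin/env Rscript
# Stage 2: engineer the hand-crafted binary feature matrix.
#
# Every model input is a 0/1 indicator: categorical levels (rare levels
# pooled below 5%), fixed operational thresholds, the within-study site
# burden score band, and the randomization-by-design interaction flags.
# Features below 5% prevalence are dropped; the strongest pairwise
# correlation is reported because correlated pairs are barred from being
# co-selected later.

suppressPackageStartupMessages(library(cifrisk))

tabs <- read_tables("results/data")
fm <- build_feature_matrix(tabs$activities, tabs$studies, tabs$sites)

utils::write.csv(cbind(activity_id = fm$activity_ids,
                       as.data.frame(fm$values)),
                 "results/feature_matrix.csv", row.names = FALSE)
utils::write.csv(data.frame(feature = fm$feature_names,
                            prevalence = unname(fm$prevalence)),
                 "results/feature_prevalence.csv", row.names = FALSE)

cat("feature matrix:", nrow(fm$values), "activities x", ncol(fm$values),
    "binary features\n")
print(data.frame(feature = fm$feature_names,
                 prevalence = round(unname(fm$prevalence), 3)))
mc <- max_abs_pairwise_correlation(fm)
cat(sprintf("strongest pairwise correlation: %.3f (%s ~ %s)\n",
            mc$value, mc$pair[1], mc$pair[2]))
cat("written to results/feature_matrix.csv\n")
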