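#!/usr/bin/env Rscript
# Stage 5: step-function calibration of the cross-validated predictions.
#
# Each CIF's pooled test-set predictions are divided into 4 equal-width
# bins; a bin whose 75% Wilson interval excludes the base rate keeps its
# observed event rate, overlapping neighbors are merged, and anything still
# straddling the base rate defaults to it. The resulting step function gives
# the calibrated upper and lower bounds of each model's output (the delta
# column). A CIF whose selected model is null gets the constant base-rate
# curve outright.

suppressPackageStartupMessages(library(cifrisk))

preds <- utils::read.csv("results/cv_predictions.csv")
summaries <- utils::read.csv("results/backtest_summary.csv")
sel <- jsonlite::read_json("results/selected_features.json",
                           simplifyVector = TRUE)

curves <- list()
for (cf in cif_names()) {
  p <- preds[preds$cif == cf, ]
  base_rate <- summaries$base_rate[summaries$cif == cf]
  feats <- sel[[cf]]$features
  if (is.null(feats) || length(feats) == 0) {
    curves[[cf]] <- constant_curve(base_rate, range(p$predicted))
  } else {
    bins <- bin_predictions(p$predicted, p$observed, n_bins = 4)
    curves[[cf]] <- fit_step_calibration(bins, base_rate)
  }
  cat(sprintf("%-30s calibrated %2.0f-%2.0f%% (delta %2.0f%%), base rate %2.0f%%%s\n",
              cf, 100 * curves[[cf]]$prediction_range[1],
              100 * curves[[cf]]$prediction_range[2],
              100 * curves[[cf]]$delta, 100 * base_rate,
              if (curves[[cf]]$constant) "  [no deviation from base rate]"
              else ""))
}

jsonlite::write_json(
  lapply(curves, function(cv) list(steps = cv$steps, base_rate = cv$base_rate,
                                   delta = cv$delta, constant = cv$constant)),
  "results/calibration_curves.json", auto_unbox = TRUE, digits = NA)

# step-function figure (observed-vs-predicted analogue)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  dat <- do.call(rbind, lapply(cif_names(), function(cf) {
    cbind(cif = cf, curves[[cf]]$steps,
          base_rate = curves[[cf]]$base_rate)
  }))
  gp <- ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = lower, xend = upper, y = value,
                                       yend = value, color = cif),
                          linewidth = 1.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = base_rate),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~cif) +
    ggplot2::labs(x = "predicted probability", y = "calibrated probability") +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  ggplot2::ggsave("results/figures/calibration_steps.pdf", gp,
                  width = 8, height = 5)
  cat("figure written to results/figures/calibration_steps.pdf\n")
}
cat("curves written to results/calibration_curves.json\n")
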