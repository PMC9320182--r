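#!/usr/bin/env Rscript
# Stage 4 — Monte Carlo uncertainty and sensitivity.
#
# Propagates concentration uncertainty (lognormal, fitted to the campaign's
# positive values) through the cancer-risk equation for each carcinogen and
# cohort, 10,000 iterations, with contribution-to-variance sensitivity under
# the uncertain-exposure profile (normal body weight, uniform ingestion
# rate). Results are illustrative of uncertainty spread, not reproductions:
# the underlying distributional assumptions of the original spreadsheet
# analysis are unpublished.

library(aquarisk)

camp <- read_campaign("results/campaign.csv")
seed <- 20260925L

summary_rows <- list()
for (metal in carcinogens()) {
  for (co in c("adult", "child")) {
    specs <- fit_input_distributions(camp, metal, co, "uncertain-exposure")
    mc <- run_mc(specs, metal, co, n_iter = 10000L, seed = seed)
    tag <- sprintf("%s_%s", metal, co)
    write_mc_report(mc, sprintf("results/mc_%s.json", tag),
                    histogram_path = sprintf("results/mc_%s_hist.csv", tag))
    top <- sort(abs(mc$sensitivity), decreasing = TRUE)[1:2]
    cat(sprintf("%-3s %-5s mean %.3g  p5 %.3g  p95 %.3g  top drivers: %s\n",
                metal, co, mc$mean, mc$p5, mc$p95,
                paste(sprintf("%s %+0.1f%%", names(top),
                              mc$sensitivity[names(top)]), collapse = ", ")))
    summary_rows[[tag]] <- data.frame(
      metal = metal, cohort = co, mean = mc$mean, p5 = mc$p5, p50 = mc$p50,
      p95 = mc$p95)
  }
}
write.csv(do.call(rbind, summary_rows), "results/mc_summary.csv",
          row.names = FALSE)
cat("\nWrote per-target MC reports, histograms and results/mc_summary.csv\n")
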