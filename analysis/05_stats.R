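#!/usr/bin/env Rscript
# Stage 5 — descriptive statistics, correlations, clustering.
#
# Per-source descriptives with CV classes, Pearson correlation matrices with
# two-sided significance, and Ward clustering of the metal profiles.

library(aquarisk)

camp <- read_campaign("results/campaign.csv")

desc <- describe(camp, by = "source_type")
write.csv(desc, "results/descriptives.csv", row.names = FALSE)
cat("CV classes by source type:\n")
print(table(desc$group, desc$cv_label))

for (st in c("WRS", "GW", "TW")) {
  sub <- camp[camp$source_type == st, ]
  cm <- correlation_matrix(sub)
  lg <- correlation_long(cm)
  write.csv(lg, sprintf("results/correlations_%s.csv", st), row.names = FALSE)
  sig <- lg[lg$stars != "", ]
  cat(sprintf("\n%s: %d significant pairs (p < 0.05); strongest: %s-%s r=%.2f\n",
              st, nrow(sig),
              lg$var1[which.max(abs(lg$r))], lg$var2[which.max(abs(lg$r))],
              lg$r[which.max(abs(lg$r))]))
  cl <- cluster_metals(sub)
  write_linkage(cl, sprintf("results/linkage_%s.csv", st))
}
cat("\nWrote descriptives, per-source correlations and linkage trees\n")
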