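#!/usr/bin/env Rscript
# Stage 2 — pollution indices.
#
# Scores every sample with the weighted-mean heavy-metal pollution index
# (MPI), the per-metal single-factor index (SFPI), and the Nemerow index
# (NPI) against the PNSDW limits, then aggregates per source type both ways
# (index of mean concentrations, and mean of per-sample indices).

library(aquarisk)

camp <- read_campaign("results/campaign.csv")

idx <- index_table(camp, authority = "PNSDW")
write.csv(idx, "results/indices.csv", row.names = FALSE)

grp <- group_indices(camp, authority = "PNSDW")
write.csv(grp, "results/indices_by_group.csv", row.names = FALSE)

cat("Per-sample index classification:\n")
print(table(idx$mpi_label))
print(table(idx$npi_label))

cat("\nGroup-level indices (PNSDW):\n")
print(grp, digits = 4)

cat("\nReference point: the mean tap-water concentrations give MPI",
    sprintf("%.0f (%s)", mpi(study_mean_concentrations("TW")),
            classify("MPI", mpi(study_mean_concentrations("TW")))),
    "\n")
cat("Wrote results/indices.csv and results/indices_by_group.csv\n")
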