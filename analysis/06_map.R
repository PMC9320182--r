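#!/usr/bin/env Rscript
# Stage 6 — MLGI mapping of the pollution index surface.
#
# Interpolates the per-site MPI of the spatially structured campaign with
# the neural-network trend (hidden-layer size chosen by AIC) plus residual
# ordinary kriging, and writes the gridded surface, the training report
# (hidden neurons / particles / iterations / elapsed / MSE / R), and the
# AIC-vs-neurons curve.

library(aquarisk)

camp <- read_campaign("results/campaign_spatial.csv")
seed <- 20260925L

idx <- index_table(camp)
sites <- data.frame(x = camp$x, y = camp$y, value = idx$mpi)

surf <- build_surface(sites, n_hidden = c(1:6, 8L, 12L),
                      n_particles = 30L, n_iterations = 200L, seed = seed)

write_surface_csv(surf, "results/surface_mpi.csv")
write_surface_geojson(surf, "results/surface_mpi.geojson")
write.csv(surf$model$report, "results/train_report_mpi.csv", row.names = FALSE)
write.csv(surf$aic_curve, "results/aic_curve_mpi.csv", row.names = FALSE)

cat("Selected architecture:\n")
print(surf$model$report, digits = 4)
cat("\nAIC curve:\n")
print(surf$aic_curve, digits = 5)
g <- surf$grid
cat(sprintf("\nSurface: %d cells (%d interpolated, %d extrapolated), MPI range %.0f-%.0f\n",
            nrow(g), sum(!g$extrapolated), sum(g$extrapolated),
            min(g$value), max(g$value)))
cat("Wrote surface CSV/GeoJSON, training report and AIC curve\n")
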