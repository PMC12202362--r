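#!/usr/bin/env Rscript
# Computes the full zone-wise metric table for the phantom cohort written
# by 02_phantom_cohort.R: vessel density (VD), vessel diameter index
# (VDI, px and um), vessel length fraction (VLF), box-counting fractal
# dimension (FD), and per-track tortuosity aggregates (MDAC, LC, TSC,
# TSC/LX, TSC/LC) for every eye x zone x vessel class.
#
# One row per eye x (fovea, 4 parafoveal quadrants, whole image) x
# (artery, vein, all); zones without vessels carry NA, not zero.

library(vesselmetrics)

manifest <- load_cohort_manifest("results/cohort/manifest.csv")
metrics <- run_metrics(manifest)
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
cat(sprintf("wrote results/metrics.csv (%d rows, %d eyes)\n",
            nrow(metrics), length(unique(metrics$eye_id))))

all_rows <- subset(metrics, vessel_class == "all" & zone != "image")
cat("\nmean VD by zone (all vessels):\n")
print(round(tapply(all_rows$vd, all_rows$zone, mean), 4))
cat("\nmean VDI (um) by zone:\n")
print(round(tapply(all_rows$vdi_um, all_rows$zone, mean, na.rm = TRUE), 1))
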