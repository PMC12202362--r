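#!/usr/bin/env Rscript
# Generates the synthetic study cohort: three groups (control, NDR,
# NPDR) of 10 eyes each, 304 x 304 artery/vein label maps over a
# 3 x 3 mm macular field. The NPDR group carries one injected effect --
# an arterial vessel-density deficit of 3 between-eye SDs in the
# inferior parafoveal quadrant -- emulating the kind of localized
# large-vessel change reported in early diabetic retinopathy; all other
# zone densities are drawn from the shared baseline.
#
# Output: results/cohort/ with one PNG label map per eye (red = artery,
# blue = vein, green = arteriovenous junction), manifest.csv,
# targets.csv (per-eye density targets actually used) and truth.csv.

library(vesselmetrics)

seed <- 1
cs <- cohort_spec(
  eyes_per_group = 10,
  effects = data.frame(group = "NPDR", zone = "para_I", class = "artery",
                       delta_vd = -3 * (0.12 / 2) * 0.10),
  seed = seed)
cohort <- generate_cohort(cs, out_dir = "results/cohort",
                          compute_truth = TRUE)
cat(sprintf("generated %d eyes in results/cohort (seed %d)\n",
            nrow(cohort$manifest), seed))
print(table(cohort$manifest$group, cohort$manifest$laterality))
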