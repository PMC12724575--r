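#!/usr/bin/env Rscript

# Step 2: derive movement-category velocity thresholds per cohort.
#
# Two-stage unsupervised procedure, run independently for each sex:
# stage 1 pools the traversal matrices of every retained match file and
# selects the category count k with the elbow method on the
# occupancy-weighted within-cluster sum of squares; stage 2 re-clusters
# each match file at that k and averages the per-match boundaries.
#
# Outputs: results/thresholds_{male,female}.json, results/elbow_curves.csv,
# results/cleaning_summary.csv.

library(velozone)

cfg <- default_config()
dir.create("results", showWarnings = FALSE)

elbow_rows <- list()
cleaning_rows <- list()
for (sex in c("male", "female")) {
  run <- suppressWarnings(run_derive(cfg, file.path("scratch", "traces", sex), sex))
  th <- run$thresholds
  cat(sprintf("\n== %s cohort (%d retained of %d files) ==\n",
              sex, run$n_retained, nrow(run$cleaning)))
  print(th)
  write_thresholds(th, file.path("results", sprintf("thresholds_%s.json", sex)),
                   config = cfg)
  elbow_rows[[sex]] <- data.frame(cohort = sex, k = th$elbow$k_values,
                                  wcss = th$elbow$wcss_values,
                                  selected = th$elbow$k_values == th$elbow$k_star)
  cleaning_rows[[sex]] <- run$cleaning
}

write.csv(do.call(rbind, elbow_rows), "results/elbow_curves.csv", row.names = FALSE)
write.csv(do.call(rbind, cleaning_rows), "results/cleaning_summary.csv", row.names = FALSE)
cat("\nwrote results/thresholds_{male,female}.json, results/elbow_curves.csv, results/cleaning_summary.csv\n")
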