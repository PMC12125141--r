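#!/usr/bin/env Rscript
# Fit the PSH-risk logistic models: stratified five-fold CV over the
# regularisation grid {2N, N, 1, 1/N, 1/(2N)} x {balanced, unbalanced}
# for each feature-set level, plus the 3-metric x 4-window enumeration
# for level III (best configuration per window).

library(pshrisk)

seed <- 1L
metadata <- read.csv("results/cohort/metadata.csv")
qc <- read.csv("results/qc_report.csv")
metadata <- metadata[metadata$patient_id %in% qc$patient_id[qc$passed], ]
records <- lapply(metadata$patient_id, function(id) {
  read_trend_csv(file.path("results/cohort/trends", paste0(id, ".csv")))
})
names(records) <- metadata$patient_id
tf <- read.csv("results/features_transient_w03.csv")

mc <- model_config(nrow(metadata), seed = seed)
summary_rows <- list()
for (lv in c("I", "II", "III")) {
  fm <- build_feature_set(lv, metadata, records, tf,
                          metric = if (lv == "III") "ZCR",
                          window_hours = if (lv == "III") 3)
  cv <- grid_search_cv(fm, mc)
  summary_rows[[lv]] <- cbind(level = lv, cv$best)
  cat(sprintf("level %-3s best C = %-8.4g (%s): AUC %.2f +/- %.2f, ACC %.2f +/- %.2f\n",
              lv, cv$best$strength, cv$best$weighting,
              cv$best$auc_mean, cv$best$auc_sd,
              cv$best$acc_mean, cv$best$acc_sd))
}
cv_summary <- do.call(rbind, summary_rows)
write.csv(cv_summary, "results/cv_summary.csv", row.names = FALSE)

cat("\nMetric x window grid (level III), best per configuration:\n")
mw <- metric_window_summary(metadata, records, config = mc)
write.csv(mw$grid, "results/metric_window_grid.csv", row.names = FALSE)
write.csv(mw$best_per_window, "results/metric_window_best.csv",
          row.names = FALSE)
print(mw$best_per_window, digits = 3, row.names = FALSE)
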