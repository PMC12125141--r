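#!/usr/bin/env Rscript
# Assemble the nested feature sets: level I (13 clinical covariates),
# level II (+ five 72-h neuromonitoring means), level III (+ one
# variability metric per pair and time bin; here ZCR on the 3-h window).

library(pshrisk)

metadata <- read.csv("results/cohort/metadata.csv")
qc <- read.csv("results/qc_report.csv")
metadata <- metadata[metadata$patient_id %in% qc$patient_id[qc$passed], ]
records <- lapply(metadata$patient_id, function(id) {
  read_trend_csv(file.path("results/cohort/trends", paste0(id, ".csv")))
})
names(records) <- metadata$patient_id
tf <- read.csv("results/features_transient_w03.csv")

for (lv in c("I", "II", "III")) {
  fm <- build_feature_set(lv, metadata, records, tf,
                          metric = if (lv == "III") "ZCR",
                          window_hours = if (lv == "III") 3)
  write.csv(data.frame(patient_id = fm$patient_id, psh_risk = fm$y,
                       fm$x, check.names = FALSE),
            sprintf("results/features_level_%s.csv", lv), row.names = FALSE)
  cat(sprintf("level %-3s %d patients x %3d features\n",
              lv, nrow(fm$x), ncol(fm$x)))
}
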