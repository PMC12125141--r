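#!/usr/bin/env Rscript
# Rolling-window correlation transients: for every QC-passed record and
# each window length (3, 6, 12, 24 h), compute the rolling Pearson
# correlation of the six ANS x hemodynamics pairs and extract MEAN, STD
# and ZCR per time bin.

library(pshrisk)

qc <- read.csv("results/qc_report.csv")
keep <- qc$patient_id[qc$passed]
records <- lapply(keep, function(id) {
  read_trend_csv(file.path("results/cohort/trends", paste0(id, ".csv")))
})
names(records) <- keep

for (w in c(3, 6, 12, 24)) {
  tf <- do.call(rbind, lapply(records, transient_features, window_hours = w))
  write.csv(tf, sprintf("results/features_transient_w%02d.csv", w),
            row.names = FALSE)
  z0 <- tf[tf$metric == "ZCR" & tf$bin_index == 0 &
             tf$pair %in% c("hr-icp", "hr-prx"), ]
  cat(sprintf("window %2d h: %5d feature rows; first-bin ZCR (HR pairs) mean %.4f\n",
              w, nrow(tf), mean(z0$value, na.rm = TRUE)))
}
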