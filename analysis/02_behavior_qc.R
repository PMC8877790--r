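#!/usr/bin/env Rscript
# Stage 2: photomotor-response trace QC. Groups wiped out by 100%
# mortality are not assayed; the remaining traces pass through the
# three exclusion rules (light serial exceedance, dark below light
# median, light:dark ratio).

source(file.path("analysis", "_common.R"))

traces <- read_traces(file.path(RESULTS_DIR, "traces.csv"))
screening <- read_screening(file.path(RESULTS_DIR, "screening.csv"))

gate <- mortality_gate(screening)
nonevaluable <- gate[!gate$evaluable, ]
if (nrow(nonevaluable) > 0) {
  cat("groups not evaluable for behavior (100% mortality):\n")
  print(as.data.frame(nonevaluable[, c("chemical", "concentration_nM", "duration")]))
  traces <- anti_join(traces, nonevaluable,
    by = c("chemical", "concentration_nM", "duration")
  )
}

qc <- apply_qc(traces, qc_thresholds())
print(qc)

readr::write_csv(qc$report, file.path(RESULTS_DIR, "qc_report.csv"))
readr::write_csv(qc$retention, file.path(RESULTS_DIR, "qc_retention.csv"))
write_traces(qc$retained, file.path(RESULTS_DIR, "traces_retained.csv"))
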