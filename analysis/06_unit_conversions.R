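#!/usr/bin/env Rscript
# Stage 6: molar-to-mass conversion of every designed exposure
# concentration, and a consistency check of observed condition labels
# against the nominal design.

source(file.path("analysis", "_common.R"))

design <- study_design(include_controls = FALSE)
design$ugL <- purrr::map2_dbl(design$chemical, design$concentration_nM, nM_to_ugL)
design$ugL_display <- round(design$ugL, 1)
readr::write_csv(design, file.path(RESULTS_DIR, "concentration_conversions.csv"))
print(as.data.frame(design))

# do the simulated DE tables cover the designed concentrations?
records <- read_deg_table(file.path(RESULTS_DIR, "deg_tables.tsv"))
for (chem in unique(design$chemical)) {
  chk <- validate_design(
    design$concentration_nM[design$chemical == chem],
    unique(records$concentration_nM[records$chemical == chem])
  )
  n_bad <- sum(chk$status != "ok")
  cat(sprintf(
    "%s: %d designed concentrations, %d discrepancies\n",
    chem, sum(design$chemical == chem), n_bad
  ))
  if (n_bad > 0) print(as.data.frame(chk[chk$status != "ok", ]))
}
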