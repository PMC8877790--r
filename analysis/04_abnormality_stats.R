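#!/usr/bin/env Rscript
# Stage 4: morphology and mortality endpoint statistics at the final
# (120 hpf, cumulative) screening view: per-endpoint global chi-square
# across concentrations and Bonferroni-corrected pairwise comparisons
# versus control, with the 100%-mortality evaluability gate applied to
# the non-mortality endpoints.

source(file.path("analysis", "_common.R"))

screening <- read_screening(file.path(RESULTS_DIR, "screening.csv"))

gate <- mortality_gate(screening)
readr::write_csv(gate, file.path(RESULTS_DIR, "mortality_gate.csv"))
cat(sprintf(
  "%d of %d groups evaluable for abnormality endpoints\n",
  sum(gate$evaluable), nrow(gate)
))

tests <- screening_tests(screening, control_concentration = 0, timepoint_hpf = 120)
readr::write_csv(tests, file.path(RESULTS_DIR, "screening_tests.csv"))

sig <- dplyr::filter(tests, significant)
cat(sprintf(
  "%d of %d pairwise endpoint comparisons significant after Bonferroni:\n",
  nrow(sig), nrow(tests)
))
print(as.data.frame(
  sig[, c("chemical", "duration", "endpoint", "concentration_nM", "adj_p")]
))

# diffuse signals: globally significant endpoints with no pairwise survivor
diffuse <- tests |>
  dplyr::group_by(chemical, duration, endpoint) |>
  dplyr::summarise(
    global_p = global_p[1], any_pairwise = any(significant), .groups = "drop"
  ) |>
  dplyr::filter(global_p < 0.05, !any_pairwise)
if (nrow(diffuse) > 0) {
  cat("globally significant endpoints with no single concentration driving them:\n")
  print(as.data.frame(diffuse))
}
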