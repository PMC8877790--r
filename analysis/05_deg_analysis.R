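#!/usr/bin/env Rscript
# Stage 5: differential-expression accounting. Applies the
# |log2FC| >= 0.75 & padj < 0.1 filter, tallies counts per
# concentration and per chemical x duration under both deduplication
# policies, and decomposes the cross-chemical overlap (each chemical's
# significant genes unioned over all concentrations and durations).

source(file.path("analysis", "_common.R"))

records <- read_deg_table(file.path(RESULTS_DIR, "deg_tables.tsv"))
truth <- jsonlite::read_json(file.path(RESULTS_DIR, "truth.json"),
  simplifyVector = TRUE
)$planted_degs

sig <- filter_degs(records, lfc_cut = 0.75, padj_cut = 0.1)
cat(sprintf(
  "%d of %d gene-condition records pass the significance filter (%d untested)\n",
  nrow(sig), nrow(records), attr(sig, "n_untested")
))

for (policy in c("sum", "unique")) {
  counts <- count_by_condition(sig, policy)
  readr::write_csv(
    counts$per_concentration,
    file.path(RESULTS_DIR, sprintf("deg_counts_per_concentration_%s.csv", policy))
  )
  readr::write_csv(
    counts$per_duration,
    file.path(RESULTS_DIR, sprintf("deg_counts_per_duration_%s.csv", policy))
  )
}
print(count_by_condition(sig, "sum"))

overlaps <- overlap_sets(combine_condition_sets(sig))
jsonlite::write_json(
  overlaps[, c("region", "degree", "n", "genes")],
  file.path(RESULTS_DIR, "deg_overlaps.json"),
  dataframe = "rows", auto_unbox = TRUE
)
cat("cross-chemical overlap regions:\n")
print(as.data.frame(overlaps[, c("region", "degree", "n")]))

# recovery of the planted truth
planted <- dplyr::semi_join(
  records, truth,
  by = c("gene_id", "chemical", "concentration_nM", "duration")
)
hit <- dplyr::semi_join(
  planted, sig,
  by = c("gene_id", "chemical", "concentration_nM", "duration")
)
cat(sprintf(
  "planted-DEG recovery: %d / %d (%.1f%%)\n",
  nrow(hit), nrow(planted), 100 * nrow(hit) / nrow(planted)
))
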