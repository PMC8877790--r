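#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth —
# locomotion traces (24 larvae per exposure group), screening count
# tables (150 embryos per condition) and genome-scale per-gene DE
# tables with planted DEGs and cross-chemical overlaps.

source(file.path("analysis", "_common.R"))

cfg <- study_sim_config()

traces <- simulate_traces(cfg)
screening <- simulate_screening(cfg, effect_or = screening_effects(cfg$groups))
deg <- simulate_deg_table(cfg)

write_traces(traces$traces, file.path(RESULTS_DIR, "traces.csv"))
write_screening(screening, file.path(RESULTS_DIR, "screening.csv"))
write_deg_table(deg$records, file.path(RESULTS_DIR, "deg_tables.tsv"))
jsonlite::write_json(
  list(nonresponders = traces$truth$larvae, planted_degs = deg$truth),
  file.path(RESULTS_DIR, "truth.json"),
  dataframe = "rows", auto_unbox = TRUE
)

cat(sprintf(
  "simulated %d traces across %d groups, %d screening rows, %d gene records\n",
  length(unique(traces$traces$larva_id)), nrow(cfg$groups),
  nrow(screening), nrow(deg$records)
))
cat(sprintf(
  "planted: %d nonresponder larvae, %d DEG plantings\n",
  sum(traces$truth$larvae$nonresponder), nrow(deg$truth)
))
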