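#!/usr/bin/env Rscript
# Stage 3: behavioral group statistics. Per chemical x duration, the
# per-larva light and dark phase means are compared across
# concentrations with one-way ANOVA and Tukey HSD versus the vehicle
# control; Shapiro-Wilk is reported as a diagnostic only.

source(file.path("analysis", "_common.R"))
library(purrr)

retained <- read_traces(file.path(RESULTS_DIR, "traces_retained.csv"))
summary_tbl <- summarize_movement(retained)
# carry the condition metadata for the per-family loop
meta <- distinct(retained, larva_id, chemical, concentration_nM, duration)
summary_tbl <- left_join(summary_tbl, meta, by = "larva_id")
readr::write_csv(summary_tbl, file.path(RESULTS_DIR, "behavior_summary.csv"))

families <- split(summary_tbl, list(summary_tbl$chemical, summary_tbl$duration),
  drop = TRUE
)
results <- map_dfr(families, function(fam) {
  control <- fam$group[fam$concentration_nM == 0][1]
  map_dfr(c("light", "dark"), function(ph) {
    res <- compare_groups(fam, control, phase_type = ph)
    mutate(res$pairwise,
      chemical = fam$chemical[1], duration = fam$duration[1],
      phase_type = ph, anova_F = res$anova_F, anova_p = res$anova_p,
      shapiro_p = res$normality$p, .before = 1
    )
  })
})
readr::write_csv(results, file.path(RESULTS_DIR, "behavior_tests.csv"))

sig <- filter(results, significant)
cat(sprintf(
  "%d of %d concentration-vs-control contrasts significant (Tukey p < 0.05):\n",
  nrow(sig), nrow(results)
))
print(as.data.frame(
  sig[, c("chemical", "duration", "phase_type", "group", "direction", "tukey_p")]
))
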