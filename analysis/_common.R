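# Shared configuration for the numbered analysis drivers.
#
# One master seed governs every stochastic stage. The planted effects
# echo the qualitative pattern of a three-chemical developmental
# screen: complete mortality at the two highest triclosan
# concentrations, dark-phase hypo-/hyperactivity at selected
# triclocarban concentrations, swim-bladder and skeletal abnormalities
# at high 4-nonylphenol, and cross-chemical DEG overlaps.

library(larvatox)
library(dplyr)
library(tibble)

MASTER_SEED <- 20220201L
RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

behavior_groups <- function() {
  g <- study_design() # 3 chemicals x (control + 5 concentrations) x 2 durations
  g$group <- paste(g$chemical, g$concentration_nM, g$duration, sep = "_")
  g$effect_multiplier_dark <- 1
  g$effect_multiplier_light <- 1
  set_mult <- function(g, chem, conc, dur, dark = NULL, light = NULL) {
    i <- g$chemical == chem & g$concentration_nM == conc & g$duration == dur
    if (!is.null(dark)) g$effect_multiplier_dark[i] <- dark
    if (!is.null(light)) g$effect_multiplier_light[i] <- light
    g
  }
  g |>
    set_mult("triclocarban", 0.1, "120h", dark = 0.65) |>
    set_mult("triclocarban", 100, "120h", dark = 1.4) |>
    set_mult("triclocarban", 0.01, "24h", dark = 0.6) |>
    set_mult("4-nonylphenol", 0.1, "120h", dark = 0.7, light = 0.7) |>
    set_mult("4-nonylphenol", 1000, "24h", dark = 0.55)
}

screening_effects <- function(groups) {
  bind_rows(
    tibble(
      group = groups$group[groups$chemical == "triclosan" &
        groups$concentration_nM %in% c(100, 1000) & groups$duration == "120h"],
      endpoint = "mortality", odds_ratio = Inf
    ),
    tibble(
      group = groups$group[groups$chemical == "triclosan" &
        groups$concentration_nM %in% c(100, 1000) & groups$duration == "24h"],
      endpoint = "mortality", odds_ratio = 40
    ),
    tibble(
      group = groups$group[groups$chemical == "triclocarban" &
        groups$concentration_nM == 100 & groups$duration == "120h"],
      endpoint = "uninflated_swim_bladder", odds_ratio = 3.5
    ),
    tibble(
      group = groups$group[groups$chemical == "4-nonylphenol" &
        groups$concentration_nM == 1000 & groups$duration == "24h"],
      endpoint = c("uninflated_swim_bladder", "skeletal", "yolk_sac_edema"),
      odds_ratio = c(4, 8, 2.5)
    )
  )
}

study_sim_config <- function() {
  simulation_config(
    seed = MASTER_SEED,
    groups = behavior_groups(),
    n_genes = 20000L,
    n_true_deg = 60L,
    shared_deg_counts = list(
      "triclosan&4-nonylphenol" = 8,
      "triclosan&triclocarban" = 14,
      "triclocarban&4-nonylphenol" = 27,
      "triclosan&triclocarban&4-nonylphenol" = 6
    )
  )
}
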