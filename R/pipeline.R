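#' Configuration of a full pipeline run
#'
#' One object carries every parameter of an end-to-end run so the
#' manifest written by [run_pipeline()] is sufficient to re-execute it.
#'
#' @param outdir Output directory (created if absent).
#' @param sim A [simulation_config()]; its seed governs all stochastic
#'   stages.
#' @param schedule A [photoperiod_schedule()].
#' @param thresholds A [qc_thresholds()].
#' @param control_label Group label of the behavioral control.
#' @param control_concentration Concentration (nM) of the screening
#'   control.
#' @param alpha Significance level for behavior and screening tests.
#' @param lfc_cut,padj_cut DEG filter thresholds.
#' @param dedup_policy `"sum"` or `"unique"` for the count tables.
#' @param screening_baseline_probs,screening_effect_or Optional overrides
#'   passed to [simulate_screening()] (baseline endpoint probabilities
#'   and per-group odds ratios).
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir,
                       sim = simulation_config(),
                       schedule = photoperiod_schedule(),
                       thresholds = qc_thresholds(),
                       control_label = "control",
                       control_concentration = 0,
                       alpha = 0.05,
                       lfc_cut = 0.75,
                       padj_cut = 0.1,
                       dedup_policy = "sum",
                       screening_baseline_probs = NULL,
                       screening_effect_or = NULL) {
  stopifnot(
    inherits(sim, "simulation_config"),
    inherits(schedule, "photoperiod_schedule"),
    inherits(thresholds, "qc_thresholds"),
    alpha > 0, alpha < 1, lfc_cut > 0, padj_cut > 0,
    dedup_policy %in% c("sum", "unique")
  )
  structure(
    list(
      outdir = outdir, sim = sim, schedule = schedule,
      thresholds = thresholds, control_label = control_label,
      control_concentration = control_concentration, alpha = alpha,
      lfc_cut = lfc_cut, padj_cut = padj_cut, dedup_policy = dedup_policy,
      screening_baseline_probs = screening_baseline_probs,
      screening_effect_or = screening_effect_or
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic pipeline end to end
#'
#' Executes simulate -> QC -> behavior statistics -> screening
#' statistics -> DEG accounting -> unit conversion with one master
#' seed, writing plain-text intermediates (CSV/TSV/JSON) plus a
#' manifest with all parameters and MD5 hashes of every output, so two
#' runs with the same configuration are hash-identical. Groups gated
#' out by 100% mortality are skipped in the behavior and abnormality
#' stages with an explicit manifest entry.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest (list), invisibly written to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  emit <- function(obj, file, writer = readr::write_csv) {
    path <- file.path(config$outdir, file)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  manifest <- list(
    parameters = list(
      seed = config$sim$seed,
      n_larvae_per_group = config$sim$n_larvae_per_group,
      n_embryos_per_condition = config$sim$n_embryos_per_condition,
      schedule = unclass(config$schedule),
      qc_thresholds = unclass(config$thresholds),
      alpha = config$alpha, lfc_cut = config$lfc_cut,
      padj_cut = config$padj_cut, dedup_policy = config$dedup_policy,
      control_label = config$control_label
    ),
    stages = list()
  )

  # --- simulate ------------------------------------------------------
  sim_out <- run_stage("simulate", {
    tr <- simulate_traces(config$sim, config$schedule)
    screening_args <- c(
      list(config$sim),
      if (!is.null(config$screening_baseline_probs)) {
        list(baseline_probs = config$screening_baseline_probs)
      },
      if (!is.null(config$screening_effect_or)) {
        list(effect_or = config$screening_effect_or)
      }
    )
    sc <- do.call(simulate_screening, screening_args)
    dg <- simulate_deg_table(config$sim)
    list(traces = tr, screening = sc, deg = dg)
  })
  emit(sim_out$traces$traces, "traces.csv")
  emit(sim_out$screening, "screening.csv")
  emit(sim_out$deg$records, "deg_tables.tsv", readr::write_tsv)
  emit(
    list(
      nonresponders = sim_out$traces$truth$larvae,
      planted_degs = sim_out$deg$truth
    ),
    "truth.json",
    function(x, p) jsonlite::write_json(x, p, dataframe = "rows", auto_unbox = TRUE)
  )
  say(
    "simulate: %d traces, %d screening rows, %d DEG records",
    length(unique(sim_out$traces$traces$larva_id)), nrow(sim_out$screening),
    nrow(sim_out$deg$records)
  )
  manifest$stages$simulate <- list(
    n_traces = length(unique(sim_out$traces$traces$larva_id)),
    n_screening_rows = nrow(sim_out$screening),
    n_deg_records = nrow(sim_out$deg$records)
  )

  # --- mortality gate ------------------------------------------------
  gate <- run_stage("mortality_gate", mortality_gate(sim_out$screening))
  nonevaluable <- gate[!gate$evaluable, ]
  if (nrow(nonevaluable) > 0L) {
    say(
      "mortality gate: %d group(s) non-evaluable (100%% mortality)",
      nrow(nonevaluable)
    )
  }
  manifest$stages$mortality_gate <- list(
    n_nonevaluable = nrow(nonevaluable),
    nonevaluable = nonevaluable[, c("chemical", "concentration_nM", "duration")]
  )

  # --- QC ------------------------------------------------------------
  qc <- run_stage("qc", {
    traces <- sim_out$traces$traces
    if (nrow(nonevaluable) > 0L) {
      traces <- dplyr::anti_join(traces, nonevaluable,
        by = c("chemical", "concentration_nM", "duration")
      )
    }
    apply_qc(traces, config$thresholds)
  })
  emit(qc$report, "qc_report.csv")
  emit(
    qc$report,
    "qc_report.json",
    function(x, p) jsonlite::write_json(x, p, dataframe = "rows", auto_unbox = TRUE)
  )
  say(
    "qc: %d in, %d retained, %d excluded",
    nrow(qc$report), sum(!qc$report$excluded), sum(qc$report$excluded)
  )
  manifest$stages$qc <- list(
    n_in = nrow(qc$report), n_retained = sum(!qc$report$excluded),
    n_excluded = sum(qc$report$excluded)
  )

  # --- behavior ------------------------------------------------------
  behavior <- run_stage("behavior", {
    summ <- summarize_movement(qc$retained)
    res <- purrr::map(c("light", "dark"), function(ph) {
      compare_groups(summ, config$control_label,
        phase_type = ph, alpha = config$alpha
      )
    })
    names(res) <- c("light", "dark")
    list(summary = summ, tests = res)
  })
  emit(behavior$summary, "behavior_summary.csv")
  beh_tbl <- purrr::map_dfr(behavior$tests, function(t) {
    dplyr::mutate(t$pairwise,
      phase_type = t$phase_type,
      anova_F = t$anova_F, anova_p = t$anova_p, .before = 1
    )
  })
  emit(beh_tbl, "behavior_tests.csv")
  say(
    "behavior: dark ANOVA p = %.3g, light ANOVA p = %.3g",
    behavior$tests$dark$anova_p, behavior$tests$light$anova_p
  )
  manifest$stages$behavior <- list(
    dark_anova_p = behavior$tests$dark$anova_p,
    light_anova_p = behavior$tests$light$anova_p
  )

  # --- abnormalities -------------------------------------------------
  screening_res <- run_stage(
    "abnormalities",
    screening_tests(sim_out$screening,
      control_concentration = config$control_concentration,
      alpha = config$alpha
    )
  )
  emit(screening_res, "screening_tests.csv")
  say(
    "abnormalities: %d endpoint comparisons, %d significant",
    nrow(screening_res), sum(screening_res$significant)
  )
  manifest$stages$abnormalities <- list(
    n_comparisons = nrow(screening_res),
    n_significant = sum(screening_res$significant)
  )

  # --- DEG accounting ------------------------------------------------
  deg <- run_stage("deg", {
    sig <- filter_degs(sim_out$deg$records,
      lfc_cut = config$lfc_cut, padj_cut = config$padj_cut
    )
    counts <- count_by_condition(sig, config$dedup_policy)
    sets <- combine_condition_sets(sig)
    overlaps <- if (length(sets) >= 2L) overlap_sets(sets) else NULL
    list(sig = sig, counts = counts, overlaps = overlaps)
  })
  emit(deg$counts$per_concentration, "deg_counts_per_concentration.csv")
  emit(deg$counts$per_duration, "deg_counts_per_duration.csv")
  if (!is.null(deg$overlaps)) {
    emit(
      deg$overlaps[, c("region", "degree", "n", "genes")],
      "deg_overlaps.json",
      function(x, p) jsonlite::write_json(x, p, dataframe = "rows", auto_unbox = TRUE)
    )
  }
  say("deg: %d significant records after filtering", nrow(deg$sig))
  manifest$stages$deg <- list(
    n_significant = nrow(deg$sig),
    n_untested = attr(deg$sig, "n_untested")
  )

  # --- unit conversion -----------------------------------------------
  conv <- run_stage("convert", {
    design <- unique(config$sim$groups[, c("chemical", "concentration_nM")])
    design <- design[design$concentration_nM > 0, ]
    design$ugL <- purrr::map2_dbl(
      design$chemical, design$concentration_nM, nM_to_ugL
    )
    design
  })
  emit(conv, "concentration_conversions.csv")
  manifest$stages$convert <- list(n_conversions = nrow(conv))

  manifest$outputs <- purrr::map(
    stats::setNames(outputs, basename(outputs)),
    ~ unname(tools::md5sum(.x))
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  say("manifest written to %s", manifest_path)
  invisible(manifest)
}
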