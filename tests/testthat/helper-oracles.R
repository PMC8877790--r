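# Independent brute-force oracles and fixture builders shared across the
# suite. Oracles deliberately avoid the package's own code paths.

# Pearson chi-square by direct sum over cells.
oracle_chisq <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - expected)^2 / expected)
}

# Serial-exceedance by explicit enumeration of every window of
# `run_len` consecutive bins.
oracle_serial_run <- function(candidate, run_len) {
  n <- length(candidate)
  if (n < run_len) return(FALSE)
  for (start in seq_len(n - run_len + 1L)) {
    if (all(candidate[start:(start + run_len - 1L)])) return(TRUE)
  }
  FALSE
}

# Light-rule oracle for a labeled trace: recomputes the threshold and
# scans windows directly.
oracle_light_flag <- function(trace, k = 1.5, run_len = 2L, burn_in = 60) {
  v <- trace$distance_cm[trace$phase == "light"]
  q1 <- stats::quantile(v, 0.25, type = 7, names = FALSE)
  q3 <- stats::quantile(v, 0.75, type = 7, names = FALSE)
  threshold <- q3 + k * (q3 - q1)
  candidate <- trace$phase == "light" &
    trace$within_phase_elapsed_s > burn_in &
    trace$distance_cm > threshold
  oracle_serial_run(candidate, run_len)
}

oracle_dark_flag <- function(trace, run_len = 2L) {
  m <- stats::median(trace$distance_cm[trace$phase == "light"])
  candidate <- trace$phase == "dark" & trace$distance_cm < m
  oracle_serial_run(candidate, run_len)
}

# Venn decomposition via explicit membership vectors.
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  keys <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
      collapse = "&"
    )
  }, character(1))
  table(keys)
}

# DEG filter by explicit row scan.
oracle_filter <- function(records, lfc_cut = 0.75, padj_cut = 0.1) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    keep[i] <- !is.na(records$padj[i]) &&
      abs(records$log2fc[i]) >= lfc_cut &&
      records$padj[i] < padj_cut
  }
  records$gene_id[keep]
}

# A small schedule for cheap cohort-level property tests:
# 2 cycles x 30 s phases x 6 s bins = 20 bins, 10 light.
small_schedule <- function() {
  photoperiod_schedule(phase_length_s = 30, n_cycles = 2, bin_width_s = 6)
}

# Thresholds matched to the small schedule (burn-in short enough that
# later bins of each light phase are eligible).
small_thresholds <- function(...) {
  qc_thresholds(light_burn_in_s = 12, ...)
}

# Random cohort on the small schedule: lognormal distances, a fraction
# of larvae perturbed to trip each rule.
random_cohort <- function(n_larvae = 6L, schedule = small_schedule()) {
  layout <- schedule_phases(schedule)
  purrr::map_dfr(seq_len(n_larvae), function(j) {
    d <- exp(rnorm(nrow(layout), mean = ifelse(layout$phase == "dark", 0.6, -0.6), sd = 0.7))
    tr <- label_phases(d, schedule, larva_id = sprintf("L%02d", j))
    tr$group <- "g"
    tr
  })
}

# Trace builder from explicit per-phase values (light phases then dark
# phases interleaved per the schedule).
trace_from_values <- function(light_vals, dark_vals, schedule, larva_id = "t1") {
  layout <- schedule_phases(schedule)
  d <- numeric(nrow(layout))
  d[layout$phase == "light"] <- light_vals
  d[layout$phase == "dark"] <- dark_vals
  label_phases(d, schedule, larva_id = larva_id)
}

# DEG records realizing given per-concentration up/down counts with
# globally unique gene ids; used to reproduce count-table arithmetic.
records_from_counts <- function(counts, prefix = "g") {
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    for (dir in c("down", "up")) {
      n <- counts[[paste0("n_", dir)]][i]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = sprintf("%s%05d", prefix, k + seq_len(n)),
        chemical = counts$chemical[i],
        concentration_nM = counts$concentration_nM[i],
        duration = counts$duration[i],
        log2fc = ifelse(dir == "up", 1, -1),
        padj = 0.01
      )
      k <- k + n
    }
  }
  dplyr::bind_rows(rows)
}
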