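#' Read and write the tidy trace format
#'
#' Traces travel as tidy CSV: one row per larva x bin with columns
#' `larva_id`, `group`, `bin_index`, `time_s`, `phase`, `distance_cm`
#' (plus any condition metadata columns). `read_traces()` also accepts a
#' tracker-style wide export (one column per larva, one row per bin, in
#' schedule order) via `dialect = "wide"`, in which case phases are
#' labeled from the supplied schedule.
#'
#' @param path File path.
#' @param dialect `"tidy"` (default) or `"wide"`.
#' @param schedule A [photoperiod_schedule()]; required for the wide
#'   dialect, used for validation otherwise.
#' @return A tidy trace tibble with phase timing columns.
#' @export
read_traces <- function(path, dialect = c("tidy", "wide"),
                        schedule = photoperiod_schedule()) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    wide <- readr::read_csv(path, show_col_types = FALSE)
    return(purrr::map_dfr(names(wide), function(id) {
      label_phases(wide[[id]], schedule, larva_id = id)
    }))
  }
  tr <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("larva_id", "bin_index", "phase", "distance_cm")
  if (!all(needed %in% names(tr))) {
    stop(sprintf(
      "tidy trace file must have columns %s", paste(needed, collapse = ", ")
    ), call. = FALSE)
  }
  if (!"within_phase_elapsed_s" %in% names(tr)) {
    layout <- schedule_phases(schedule)
    tr <- dplyr::left_join(tr, layout[, c("bin_index", "within_phase_elapsed_s")],
      by = "bin_index"
    )
  }
  tr
}

#' @rdname read_traces
#' @param traces A tidy trace tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read and write screening count tables
#'
#' Schema: `endpoint`, `chemical`, `concentration_nM`, `duration`,
#' `timepoint_hpf`, `n_affected`, `n_total` (extra columns pass
#' through).
#'
#' @param path File path.
#' @return A screening tibble.
#' @export
read_screening <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c(
    "endpoint", "chemical", "concentration_nM", "duration",
    "timepoint_hpf", "n_affected", "n_total"
  )
  if (!all(needed %in% names(tbl))) {
    stop(sprintf(
      "screening file must have columns %s", paste(needed, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(tbl$n_affected < 0 | tbl$n_affected > tbl$n_total)) {
    stop("screening counts must satisfy 0 <= n_affected <= n_total", call. = FALSE)
  }
  tbl
}

#' @rdname read_screening
#' @param screening A screening tibble.
#' @export
write_screening <- function(screening, path) {
  readr::write_csv(screening, path)
  invisible(path)
}

#' Read per-gene differential-expression tables
#'
#' The tidy dialect is a TSV with header `gene_id`, `chemical`,
#' `concentration_nM`, `duration`, `log2fc`, `padj` (optionally
#' `raw_p`). The `"deseq2"` dialect accepts a one-condition results file
#' with columns `log2FoldChange` and `padj` and a gene-id first column;
#' the condition must then be supplied.
#'
#' @param path File path.
#' @param dialect `"tidy"` or `"deseq2"`.
#' @param chemical,concentration_nM,duration Condition labels for the
#'   `"deseq2"` dialect.
#' @return A tidy DEG record tibble.
#' @export
read_deg_table <- function(path, dialect = c("tidy", "deseq2"),
                           chemical = NULL, concentration_nM = NULL,
                           duration = NULL) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (dialect == "deseq2") {
    if (is.null(chemical) || is.null(concentration_nM) || is.null(duration)) {
      stop("deseq2 dialect needs chemical, concentration_nM and duration labels",
        call. = FALSE
      )
    }
    if (!all(c("log2FoldChange", "padj") %in% names(tbl))) {
      stop("deseq2-style file must have columns log2FoldChange, padj", call. = FALSE)
    }
    tbl <- tibble::tibble(
      gene_id = tbl[[1]],
      chemical = chemical,
      concentration_nM = concentration_nM,
      duration = duration,
      log2fc = tbl$log2FoldChange,
      padj = tbl$padj
    )
  }
  needed <- c("gene_id", "chemical", "concentration_nM", "duration", "log2fc", "padj")
  if (!all(needed %in% names(tbl))) {
    stop(sprintf(
      "DEG table must have columns %s", paste(needed, collapse = ", ")
    ), call. = FALSE)
  }
  tbl
}

#' @rdname read_deg_table
#' @param records A tidy DEG record tibble.
#' @export
write_deg_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
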