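#' Quality-control thresholds for photomotor response traces
#'
#' Bundles the tunable constants of the trace-exclusion algorithm. The
#' defaults implement the published protocol: a light-cycle series is
#' excluded when two serial bins exceed Q3 + 1.5 x IQR of that trace's
#' light-phase distances after the 1:00 min mark of the phase; a
#' dark-cycle series when two serial dark bins fall below the median of
#' the light series; and a whole trace when its light:dark mean ratio is
#' 0.9 or larger (a non-responder).
#'
#' @param iqr_multiplier Multiplier on the IQR added to Q3 for the light
#'   exceedance threshold.
#' @param serial_run_length Number of consecutive bins required to
#'   trigger the serial rules.
#' @param light_burn_in_s Within-phase time (seconds) that light bins
#'   must exceed before they count toward the exceedance rule; skips the
#'   startle artifact right after the dark-to-light transition.
#' @param ratio_cutoff Light:dark mean ratio at or above which the trace
#'   is removed (boundary inclusive).
#'
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(iqr_multiplier = 1.5, serial_run_length = 2L,
                          light_burn_in_s = 60, ratio_cutoff = 0.9) {
  stopifnot(
    iqr_multiplier > 0, serial_run_length >= 1,
    light_burn_in_s > 0, ratio_cutoff > 0
  )
  structure(
    list(
      iqr_multiplier = iqr_multiplier,
      serial_run_length = as.integer(serial_run_length),
      light_burn_in_s = light_burn_in_s,
      ratio_cutoff = ratio_cutoff
    ),
    class = "qc_thresholds"
  )
}

# TRUE when `candidate` contains a run of at least `run_length`
# consecutive TRUE positions (bins are contiguous in time, and candidacy
# already encodes phase membership and burn-in, so rle() suffices).
has_run <- function(candidate, run_length) {
  r <- rle(candidate)
  any(r$values & r$lengths >= run_length)
}

#' Light-cycle serial-exceedance flag
#'
#' Flags a trace whose light-phase series contains `serial_run_length`
#' consecutive bins, all past the within-phase burn-in, each strictly
#' above T = Q3 + `iqr_multiplier` x IQR of the trace's own light-phase
#' distances. Quantiles use linear interpolation between order statistics
#' (R type 7), the common scientific default; the threshold is returned
#' so reports are auditable.
#'
#' @param trace A labeled single-larva trace from [label_phases()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `flag` (logical) and `threshold` (T, in cm).
#' @export
light_serial_exceedance_flag <- function(trace, thresholds = qc_thresholds()) {
  light <- trace$phase == "light"
  v <- trace$distance_cm[light]
  if (sum(light) < 4L) {
    warning("insufficient light-phase data for the exceedance rule; flag set FALSE",
      call. = FALSE
    )
    return(list(flag = FALSE, threshold = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2] + thresholds$iqr_multiplier * (q[2] - q[1])
  eligible <- light & trace$within_phase_elapsed_s > thresholds$light_burn_in_s
  candidate <- eligible & trace$distance_cm > threshold
  list(
    flag = has_run(candidate, thresholds$serial_run_length),
    threshold = unname(threshold)
  )
}

#' Dark-cycle below-light-median flag
#'
#' Flags a trace in which `serial_run_length` consecutive dark bins are
#' each strictly below the median of that trace's light-phase distances
#' (larvae normally move much more in the dark; serial dark bins quieter
#' than typical light movement indicate a tracking or health problem).
#'
#' @inheritParams light_serial_exceedance_flag
#' @return A list with `flag` and `light_median`.
#' @export
dark_below_median_flag <- function(trace, thresholds = qc_thresholds()) {
  light <- trace$phase == "light"
  dark <- trace$phase == "dark"
  if (sum(light) < 1L || sum(dark) < thresholds$serial_run_length) {
    warning("insufficient data for the dark-cycle rule; flag set FALSE", call. = FALSE)
    return(list(flag = FALSE, light_median = NA_real_))
  }
  m <- stats::median(trace$distance_cm[light])
  candidate <- dark & trace$distance_cm < m
  list(flag = has_run(candidate, thresholds$serial_run_length), light_median = m)
}

#' Light:dark mean-ratio flag (non-responder removal)
#'
#' Flags a trace whose mean light-phase distance is at least
#' `ratio_cutoff` times its mean dark-phase distance (boundary
#' inclusive). A larva that does not move in the dark at all has an
#' undefined ratio and is flagged as a degenerate non-responder.
#'
#' @inheritParams light_serial_exceedance_flag
#' @return A list with `flag` and `ratio` (light mean / dark mean;
#'   `Inf` when the dark mean is zero).
#' @export
light_dark_ratio_flag <- function(trace, thresholds = qc_thresholds()) {
  ml <- mean(trace$distance_cm[trace$phase == "light"])
  md <- mean(trace$distance_cm[trace$phase == "dark"])
  if (!is.finite(ml) || !is.finite(md)) {
    warning("missing light or dark phase; ratio rule cannot be evaluated", call. = FALSE)
    return(list(flag = FALSE, ratio = NA_real_))
  }
  if (md == 0) {
    warning("zero dark-phase mean: degenerate ratio, trace flagged as non-responder",
      call. = FALSE
    )
    return(list(flag = TRUE, ratio = Inf))
  }
  ratio <- ml / md
  list(flag = ratio >= thresholds$ratio_cutoff, ratio = ratio)
}

#' Apply the full trace-exclusion algorithm to a cohort
#'
#' Evaluates each larva independently with the three rules (light serial
#' exceedance, dark below light median, light:dark ratio) and excludes a
#' trace when any rule fires. All three flags are always computed — no
#' short-circuiting — so the report shows the complete picture. Flags are
#' per-trace functions of that trace alone, so the result of a larva is
#' unchanged by which other larvae are in the cohort, and re-applying QC
#' to the retained traces removes nothing.
#'
#' @param traces Tidy cohort tibble: one row per larva x bin with at
#'   least `larva_id`, `phase`, `within_phase_elapsed_s`, `distance_cm`
#'   and (optionally) `group`. All larvae must share one bin layout.
#' @param thresholds A [qc_thresholds()].
#'
#' @return A list of class `qc_result`: `retained` (rows of `traces` for
#'   non-excluded larvae), `report` (one row per larva with the three
#'   flags, the thresholds used and the exclusion decision),
#'   `retention` (per-group retained/excluded counts) and `thresholds`.
#' @export
apply_qc <- function(traces, thresholds = qc_thresholds()) {
  stopifnot(all(c("larva_id", "phase", "within_phase_elapsed_s", "distance_cm")
  %in% names(traces)))
  per_larva <- split(traces, traces$larva_id)
  layouts <- vapply(
    per_larva,
    function(tr) paste(tr$phase, tr$within_phase_elapsed_s, collapse = ";"),
    character(1)
  )
  if (length(unique(layouts)) > 1L) {
    stop("mixed schedules: all traces must share one phase layout", call. = FALSE)
  }
  report <- purrr::map_dfr(per_larva, function(tr) {
    lf <- light_serial_exceedance_flag(tr, thresholds)
    df <- dark_below_median_flag(tr, thresholds)
    rf <- light_dark_ratio_flag(tr, thresholds)
    tibble::tibble(
      larva_id = tr$larva_id[1],
      group = if ("group" %in% names(tr)) tr$group[1] else NA_character_,
      light_rule_flag = lf$flag,
      dark_rule_flag = df$flag,
      ratio_flag = rf$flag,
      light_threshold = lf$threshold,
      light_median = df$light_median,
      light_dark_ratio = rf$ratio,
      excluded = lf$flag || df$flag || rf$flag
    )
  })
  report <- dplyr::arrange(report, match(.data$larva_id, unique(traces$larva_id)))
  retained_ids <- report$larva_id[!report$excluded]
  retention <- report |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_input = dplyr::n(),
      n_retained = sum(!.data$excluded),
      n_excluded = sum(.data$excluded),
      .groups = "drop"
    )
  structure(
    list(
      retained = dplyr::filter(traces, .data$larva_id %in% retained_ids),
      report = report,
      retention = retention,
      thresholds = thresholds
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "QC result: %d of %d traces retained (%d excluded)\n",
    length(unique(x$retained$larva_id)), nrow(x$report), sum(x$report$excluded)
  ))
  cat(sprintf(
    "  rules fired: light %d, dark %d, ratio %d\n",
    sum(x$report$light_rule_flag), sum(x$report$dark_rule_flag),
    sum(x$report$ratio_flag)
  ))
  invisible(x)
}
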