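#' Photoperiod schedule for the larval photomotor response assay
#'
#' Describes the alternating light/dark protocol used in the behavioral
#' assay: `n_cycles` light-dark pairs of `phase_length_s` seconds each,
#' with locomotion integrated over `bin_width_s`-second bins. The default
#' is the standard protocol of four 3-minute light-dark cycles (24 min
#' total) at a 6-second integration time, i.e. 8 phases x 30 bins = 240
#' bins, starting in light (larvae are acclimated under visible light).
#'
#' @param phase_length_s Length of each light or dark phase in seconds.
#' @param n_cycles Number of light-dark cycles (a cycle is one light and
#'   one dark phase).
#' @param bin_width_s Integration time of the tracker in seconds; must
#'   divide `phase_length_s`.
#' @param first_phase `"light"` or `"dark"`; phase the session starts in.
#'
#' @return An object of class `photoperiod_schedule`: a list with the
#'   inputs plus `bins_per_phase`, `n_phases`, `n_bins` and
#'   `total_duration_s`.
#' @export
#' @examples
#' sched <- photoperiod_schedule()
#' sched$n_bins # 240
photoperiod_schedule <- function(phase_length_s = 180, n_cycles = 4,
                                 bin_width_s = 6, first_phase = c("light", "dark")) {
  first_phase <- match.arg(first_phase)
  stopifnot(phase_length_s > 0, n_cycles > 0, bin_width_s > 0)
  if (phase_length_s %% bin_width_s != 0) {
    stop("`phase_length_s` must be divisible by `bin_width_s`", call. = FALSE)
  }
  bins_per_phase <- phase_length_s %/% bin_width_s
  n_phases <- 2L * as.integer(n_cycles)
  structure(
    list(
      phase_length_s = phase_length_s,
      n_cycles = as.integer(n_cycles),
      bin_width_s = bin_width_s,
      first_phase = first_phase,
      bins_per_phase = as.integer(bins_per_phase),
      n_phases = n_phases,
      n_bins = n_phases * as.integer(bins_per_phase),
      total_duration_s = 2 * n_cycles * phase_length_s
    ),
    class = "photoperiod_schedule"
  )
}

#' @export
print.photoperiod_schedule <- function(x, ...) {
  cat(sprintf(
    "Photoperiod schedule: %d x (%ds %s / %ds %s), %ds bins, %d bins total\n",
    x$n_cycles, x$phase_length_s, x$first_phase, x$phase_length_s,
    setdiff(c("light", "dark"), x$first_phase), x$bin_width_s, x$n_bins
  ))
  invisible(x)
}

#' Per-bin phase layout of a schedule
#'
#' Expands a [photoperiod_schedule()] into one row per bin with its phase
#' label and timing. `within_phase_elapsed_s` is the elapsed time at the
#' *end* of the bin since its phase began; the light-rule burn-in
#' compares against this value, so with 6-s bins and a 60-s burn-in the
#' first 10 bins of each light phase are ineligible.
#'
#' @param schedule A [photoperiod_schedule()].
#' @return A tibble with columns `bin_index` (1-based), `time_s` (session
#'   time at bin start), `phase` (`"light"`/`"dark"`), `phase_index`
#'   (1-based) and `within_phase_elapsed_s`.
#' @export
schedule_phases <- function(schedule) {
  stopifnot(inherits(schedule, "photoperiod_schedule"))
  i <- seq_len(schedule$n_bins)
  phase_index <- ((i - 1L) %/% schedule$bins_per_phase) + 1L
  phases <- if (schedule$first_phase == "light") c("light", "dark") else c("dark", "light")
  within <- ((i - 1L) %% schedule$bins_per_phase + 1L) * schedule$bin_width_s
  tibble::tibble(
    bin_index = i,
    time_s = (i - 1L) * schedule$bin_width_s,
    phase = phases[(phase_index - 1L) %% 2L + 1L],
    phase_index = phase_index,
    within_phase_elapsed_s = within
  )
}

#' Attach phase labels to a raw locomotion series
#'
#' Converts one larva's raw distance-per-bin vector into a labeled
#' locomotion trace by aligning it with the schedule's light/dark layout.
#'
#' @param distances Numeric vector of distance moved (cm) per bin,
#'   non-negative, of length `schedule$n_bins`.
#' @param schedule A [photoperiod_schedule()].
#' @param larva_id Optional identifier carried into the result.
#'
#' @return A tibble (one row per bin): `larva_id`, `bin_index`, `time_s`,
#'   `phase`, `phase_index`, `within_phase_elapsed_s`, `distance_cm`.
#' @export
#' @examples
#' sched <- photoperiod_schedule(phase_length_s = 12, n_cycles = 1, bin_width_s = 6)
#' label_phases(c(1, 2, 3, 4), sched)$phase # "light" "light" "dark" "dark"
label_phases <- function(distances, schedule, larva_id = "larva_1") {
  stopifnot(inherits(schedule, "photoperiod_schedule"))
  if (length(distances) == 0L) {
    stop("empty distance series: nothing to label", call. = FALSE)
  }
  if (length(distances) != schedule$n_bins) {
    stop(sprintf(
      "malformed trace: %d bins supplied but schedule defines %d",
      length(distances), schedule$n_bins
    ), call. = FALSE)
  }
  if (anyNA(distances) || any(!is.finite(distances))) {
    stop("malformed trace: non-finite distances", call. = FALSE)
  }
  if (any(distances < 0)) {
    stop("malformed trace: negative distances", call. = FALSE)
  }
  out <- schedule_phases(schedule)
  out$distance_cm <- as.numeric(distances)
  tibble::add_column(out, larva_id = larva_id, .before = 1L)
}
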