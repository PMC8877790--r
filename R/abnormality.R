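#' Global chi-square across concentration groups
#'
#' Pearson chi-square (no continuity correction by default) on the
#' 2 x k affected/unaffected table for one endpoint slice. Expected
#' counts below 5 trigger a warning but the statistic is still computed,
#' matching common screening practice at n = 150 per group.
#'
#' @param n_affected,n_total Integer vectors, one entry per concentration
#'   group (including control).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A list with `chi2`, `df`, `p` and the `expected` matrix.
#' @export
#' @examples
#' global_chi_square(c(10, 30), c(100, 100))$chi2 # 12.5
global_chi_square <- function(n_affected, n_total, correct = FALSE) {
  stopifnot(length(n_affected) == length(n_total))
  if (length(n_affected) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(n_total <= 0)) stop("every group must have n_total > 0", call. = FALSE)
  if (any(n_affected < 0) || any(n_affected > n_total)) {
    stop("counts must satisfy 0 <= n_affected <= n_total", call. = FALSE)
  }
  m <- rbind(affected = n_affected, unaffected = n_total - n_affected)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("degenerate table: a margin is all zero, chi-square undefined", call. = FALSE)
  }
  if (any(expected < 5)) {
    warning("expected cell count below 5: chi-square approximation may be poor",
      call. = FALSE
    )
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(
    chi2 = unname(fit$statistic), df = unname(fit$parameter),
    p = unname(fit$p.value), expected = expected
  )
}

#' Pairwise comparisons versus control with Bonferroni correction
#'
#' For one endpoint slice (one endpoint x duration x timepoint), runs
#' the global chi-square across all groups and then a 2 x 2 chi-square
#' of each treatment concentration against the control. The Bonferroni
#' family is the set of non-control comparisons within the slice:
#' adjusted p = min(1, m x raw p) with m = number of treatment groups.
#'
#' @param tbl Tibble with one row per group: columns `group`,
#'   `n_affected`, `n_total`.
#' @param control_label The `group` value of the control.
#' @param alpha Significance level applied to adjusted p-values.
#' @param correct Yates correction flag passed to the 2 x 2 tests.
#' @return A list of class `endpoint_test`: `global` (chi2, df, p),
#'   `pairwise` (tibble: group, chi2, raw_p, adj_p, significant),
#'   `m`, `alpha`.
#' @export
pairwise_vs_control <- function(tbl, control_label, alpha = 0.05, correct = FALSE) {
  stopifnot(all(c("group", "n_affected", "n_total") %in% names(tbl)))
  if (!control_label %in% tbl$group) {
    stop(sprintf("control group '%s' not present", control_label), call. = FALSE)
  }
  ctrl <- tbl[tbl$group == control_label, ]
  trt <- tbl[tbl$group != control_label, ]
  m <- nrow(trt)
  global <- global_chi_square(tbl$n_affected, tbl$n_total, correct = correct)
  pairwise <- purrr::map_dfr(seq_len(m), function(i) {
    fit <- global_chi_square(
      c(ctrl$n_affected, trt$n_affected[i]),
      c(ctrl$n_total, trt$n_total[i]),
      correct = correct
    )
    tibble::tibble(
      group = trt$group[i],
      chi2 = fit$chi2,
      raw_p = fit$p,
      adj_p = min(1, m * fit$p),
      significant = min(1, m * fit$p) < alpha
    )
  })
  structure(
    list(
      global = global[c("chi2", "df", "p")],
      pairwise = pairwise, m = m, alpha = alpha, control = control_label
    ),
    class = "endpoint_test"
  )
}

#' @export
print.endpoint_test <- function(x, ...) {
  cat(sprintf(
    "Global chi-square: X2 = %.3f, df = %d, p = %.4g; %d pairwise vs %s (Bonferroni m = %d)\n",
    x$global$chi2, x$global$df, x$global$p, nrow(x$pairwise), x$control, x$m
  ))
  invisible(x)
}

#' Mark groups with complete mortality as non-evaluable
#'
#' Exposure groups in which every embryo has died by the final screening
#' timepoint cannot be evaluated for abnormalities or behavior; this
#' gate marks them so downstream analyses skip them explicitly rather
#' than silently producing empty comparisons.
#'
#' @param screening Tidy screening tibble with columns `chemical`,
#'   `concentration_nM`, `duration`, `timepoint_hpf`, `endpoint`,
#'   `n_affected`, `n_total`; must contain the `mortality` endpoint.
#' @return A tibble with one row per group: `chemical`,
#'   `concentration_nM`, `duration`, `mortality_final`, `n_total`,
#'   `evaluable` (FALSE only at 100% mortality).
#' @export
mortality_gate <- function(screening) {
  mort <- dplyr::filter(screening, .data$endpoint == "mortality")
  if (nrow(mort) == 0L) {
    return(tibble::tibble(
      chemical = character(), concentration_nM = numeric(),
      duration = character(), mortality_final = integer(),
      n_total = integer(), evaluable = logical()
    ))
  }
  mort |>
    dplyr::group_by(.data$chemical, .data$concentration_nM, .data$duration) |>
    dplyr::filter(.data$timepoint_hpf == max(.data$timepoint_hpf)) |>
    dplyr::summarise(
      mortality_final = .data$n_affected[1],
      n_total = .data$n_total[1],
      evaluable = .data$n_affected[1] < .data$n_total[1],
      .groups = "drop"
    )
}

#' Screening statistics for every endpoint of one chemical x duration
#'
#' Convenience driver: applies [pairwise_vs_control()] per endpoint at
#' one screening timepoint (default the final, cumulative 120 hpf view),
#' skipping groups gated out by 100% mortality for the non-mortality
#' endpoints.
#'
#' @inheritParams mortality_gate
#' @param control_concentration Concentration (nM) of the control group
#'   (default 0, the vehicle).
#' @param timepoint_hpf Screening timepoint to analyze.
#' @param alpha,correct Passed to [pairwise_vs_control()].
#' @return A tibble with one row per endpoint x comparison plus global
#'   test columns.
#' @export
screening_tests <- function(screening, control_concentration = 0,
                            timepoint_hpf = 120, alpha = 0.05, correct = FALSE) {
  gate <- mortality_gate(screening)
  slice <- dplyr::filter(screening, .data$timepoint_hpf == !!timepoint_hpf)
  purrr::map_dfr(
    split(slice, list(slice$chemical, slice$duration, slice$endpoint), drop = TRUE),
    function(s) {
      if (s$endpoint[1] != "mortality" && nrow(gate) > 0L) {
        bad <- gate[!gate$evaluable & gate$chemical == s$chemical[1] &
          gate$duration == s$duration[1], ]
        s <- dplyr::anti_join(s, bad, by = c("chemical", "concentration_nM", "duration"))
      }
      s <- dplyr::filter(s, .data$n_total > 0)
      if (!control_concentration %in% s$concentration_nM || nrow(s) < 2L) {
        return(NULL)
      }
      s$group <- as.character(s$concentration_nM)
      fit <- tryCatch(
        suppressWarnings(
          pairwise_vs_control(s, as.character(control_concentration),
            alpha = alpha, correct = correct
          )
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(NULL)
      }
      tibble::tibble(
        chemical = s$chemical[1],
        duration = s$duration[1],
        endpoint = s$endpoint[1],
        timepoint_hpf = timepoint_hpf,
        global_chi2 = fit$global$chi2,
        global_df = fit$global$df,
        global_p = fit$global$p,
        concentration_nM = as.numeric(fit$pairwise$group),
        pair_chi2 = fit$pairwise$chi2,
        raw_p = fit$pairwise$raw_p,
        adj_p = fit$pairwise$adj_p,
        significant = fit$pairwise$significant
      )
    }
  )
}
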