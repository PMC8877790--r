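#' Per-larva movement summaries by phase type
#'
#' Collapses QC-retained traces to one row per larva: mean distance
#' moved per bin over all light bins and over all dark bins. The
#' per-larva phase mean is the unit of analysis for the group
#' comparisons, which avoids pseudo-replicating the 6-s bins.
#'
#' @param traces Tidy trace tibble (rows = larva x bin) with `larva_id`,
#'   `phase`, `distance_cm` and optionally `group`.
#' @return A tibble with `larva_id`, `group`, `mean_distance_light`,
#'   `mean_distance_dark` (cm/bin).
#' @export
summarize_movement <- function(traces) {
  if (nrow(traces) == 0L) {
    warning("no traces to summarize", call. = FALSE)
    return(tibble::tibble(
      larva_id = character(), group = character(),
      mean_distance_light = numeric(), mean_distance_dark = numeric()
    ))
  }
  if (!"group" %in% names(traces)) traces$group <- NA_character_
  traces |>
    dplyr::group_by(.data$larva_id, .data$group) |>
    dplyr::summarise(
      mean_distance_light = mean(.data$distance_cm[.data$phase == "light"]),
      mean_distance_dark = mean(.data$distance_cm[.data$phase == "dark"]),
      .groups = "drop"
    )
}

#' Shapiro-Wilk normality diagnostic
#'
#' Reported alongside the ANOVA as a diagnostic only; it never gates the
#' analysis (behavioral distance data are typically non-normal, and the
#' group comparison is still run as ANOVA + Tukey HSD).
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return A list with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 non-missing values", call. = FALSE)
  }
  fit <- stats::shapiro.test(values)
  list(W = unname(fit$statistic), p = unname(fit$p.value))
}

#' Group comparison of movement: one-way ANOVA with Tukey HSD
#'
#' Runs a one-way ANOVA on per-larva phase means across all groups, then
#' Tukey's HSD over all pairs, reported filtered to each treatment group
#' versus the control. Light and dark phases are analyzed as separate
#' families. Direction is labeled `hypo` when the group's mean is below
#' the control mean and `hyper` otherwise.
#'
#' @param summary A [summarize_movement()] tibble.
#' @param control_label The `group` value of the control.
#' @param phase_type `"dark"` or `"light"`: which phase mean to compare.
#' @param alpha Significance level for the Tukey-adjusted p-values.
#' @return A list of class `behavior_test`: `phase_type`, `anova_F`,
#'   `anova_p`, `normality` (W, p of the pooled residual diagnostic),
#'   `pairwise` (tibble: group, mean_diff, tukey_p, significant,
#'   direction) and `alpha`.
#' @export
compare_groups <- function(summary, control_label, phase_type = c("dark", "light"),
                           alpha = 0.05) {
  phase_type <- match.arg(phase_type)
  value_col <- paste0("mean_distance_", phase_type)
  stopifnot(value_col %in% names(summary))
  groups <- unique(summary$group)
  if (length(groups) < 2L) {
    stop("need at least two groups (control plus one treatment)", call. = FALSE)
  }
  if (!control_label %in% groups) {
    stop(sprintf("control group '%s' not present", control_label), call. = FALSE)
  }
  sizes <- table(summary$group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 larvae", call. = FALSE)
  }
  df <- tibble::tibble(
    value = summary[[value_col]],
    group = factor(summary$group)
  )
  within_var <- tapply(df$value, df$group, stats::var)
  if (all(within_var == 0, na.rm = TRUE)) {
    stop("degenerate variance: no within-group variation in any group", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit)$group
  pairs <- rownames(tukey)
  halves <- strsplit(pairs, "-", fixed = TRUE)
  ctrl_means <- mean(df$value[df$group == control_label])
  pairwise <- purrr::map_dfr(seq_along(pairs), function(i) {
    a <- halves[[i]][1]
    b <- halves[[i]][2]
    if (!(a == control_label || b == control_label)) {
      return(NULL)
    }
    grp <- if (a == control_label) b else a
    # TukeyHSD reports a - b; orient so diff = group mean - control mean
    diff <- if (b == control_label) tukey[i, "diff"] else -tukey[i, "diff"]
    p <- tukey[i, "p adj"]
    tibble::tibble(
      group = grp,
      mean_diff = unname(diff),
      tukey_p = unname(p),
      significant = p < alpha,
      direction = ifelse(diff < 0, "hypo", "hyper")
    )
  })
  resid_diag <- tryCatch(normality_check(stats::residuals(fit)),
    error = function(e) list(W = NA_real_, p = NA_real_)
  )
  structure(
    list(
      phase_type = phase_type,
      anova_F = unname(tab[["F value"]][1]),
      anova_p = unname(tab[["Pr(>F)"]][1]),
      normality = resid_diag,
      pairwise = pairwise,
      alpha = alpha,
      control = control_label
    ),
    class = "behavior_test"
  )
}

#' @export
print.behavior_test <- function(x, ...) {
  cat(sprintf(
    "%s-phase movement: ANOVA F = %.3f, p = %.4g (alpha = %g)\n",
    x$phase_type, x$anova_F, x$anova_p, x$alpha
  ))
  sig <- x$pairwise[x$pairwise$significant, ]
  if (nrow(sig) == 0L) {
    cat("  no group differs from control after Tukey adjustment\n")
  } else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf(
        "  %s: %sactive vs %s (diff %.3f cm/bin, Tukey p = %.4g)\n",
        sig$group[i], sig$direction[i], x$control, sig$mean_diff[i], sig$tukey_p[i]
      ))
    }
  }
  invisible(x)
}
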