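# Sub-seed derivation: one RNG stream per generator, so adding a
# generator never perturbs the draws of another. Kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(traces = 1L, screening = 2L, deg = 3L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 1000003L) * 1009L + offsets[[stream]]
}

#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the three generators (locomotion traces,
#' screening count tables, per-gene DE tables) with the study's group
#' sizes as defaults: 24 larvae per group in the behavioral assay, 150
#' embryos per chemical x concentration x duration in screening.
#' Identical configurations (including `seed`) produce bit-identical
#' outputs.
#'
#' @param seed Master seed; each generator derives its own stream.
#' @param n_larvae_per_group Larvae per behavioral exposure group.
#' @param groups Tibble describing the exposure groups: columns `group`
#'   (label), `chemical`, `concentration_nM`, `duration`, and per-group
#'   `effect_multiplier_dark`, `effect_multiplier_light` (1 = no
#'   effect). Default: vehicle control plus the triclocarban design at
#'   120 h, all null.
#' @param baseline_dark_mean,baseline_light_mean Control mean distance
#'   moved (cm per 6-s bin) in dark and light phases. Larvae normally
#'   move several-fold more in the dark.
#' @param noise_cv Coefficient of variation of per-bin movement noise.
#' @param outlier_rate Per-bin probability of a tracking artifact.
#' @param outlier_scale Multiplier applied to artifact bins.
#' @param nonresponder_rate Per-larva probability of a non-responder
#'   whose light activity is rescaled to 0.95 x its dark activity (so
#'   the QC ratio rule must remove it).
#' @param n_embryos_per_condition Embryos per screening condition.
#' @param n_genes Genes per simulated DE table.
#' @param n_true_deg Planted differentially expressed genes per
#'   condition (shared plantings count toward this).
#' @param lfc_effect_mean,lfc_effect_sd Mean and SD of planted absolute
#'   log2 fold changes (sign random).
#' @param null_lfc_sd SD of null-gene log2 fold changes.
#' @param planted_p_max Upper bound of planted genes' raw p-values
#'   (drawn uniformly on (0, `planted_p_max`)).
#' @param shared_deg_counts Named list mapping chemical sets (names
#'   joined by `"&"`, e.g. `"triclosan&4-nonylphenol"`) to the number of
#'   genes planted as DEGs in exactly those chemicals.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_larvae_per_group = 24L,
                              groups = NULL,
                              baseline_dark_mean = 2.0,
                              baseline_light_mean = 0.4,
                              noise_cv = 0.3,
                              outlier_rate = 0.01,
                              outlier_scale = 5,
                              nonresponder_rate = 0.05,
                              n_embryos_per_condition = 150L,
                              n_genes = 20000L,
                              n_true_deg = 50L,
                              lfc_effect_mean = 2,
                              lfc_effect_sd = 0.5,
                              null_lfc_sd = 0.2,
                              planted_p_max = 1e-6,
                              shared_deg_counts = NULL) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      chemical = "triclocarban",
      concentration_nM = c(0, 0.01, 0.1, 1, 10, 100),
      duration = "120h"
    )
    groups$group <- ifelse(groups$concentration_nM == 0, "control",
      paste0("tcc_", groups$concentration_nM, "nM")
    )
    groups$effect_multiplier_dark <- 1
    groups$effect_multiplier_light <- 1
  }
  stopifnot(all(c(
    "group", "chemical", "concentration_nM", "duration",
    "effect_multiplier_dark", "effect_multiplier_light"
  ) %in% names(groups)))
  rates <- c(outlier_rate, nonresponder_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  means <- c(baseline_dark_mean, baseline_light_mean)
  if (any(!is.finite(means)) || any(means < 0)) {
    stop("baseline means must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(groups$effect_multiplier_dark)) ||
    any(!is.finite(groups$effect_multiplier_light)) ||
    any(groups$effect_multiplier_dark < 0) ||
    any(groups$effect_multiplier_light < 0)) {
    stop("effect multipliers must be finite and non-negative", call. = FALSE)
  }
  stopifnot(
    n_larvae_per_group >= 1, n_embryos_per_condition >= 1,
    n_genes >= 0, n_true_deg >= 0, n_true_deg <= n_genes,
    noise_cv >= 0, outlier_scale >= 0, planted_p_max > 0, planted_p_max <= 1
  )
  if (!is.null(shared_deg_counts)) {
    if (is.null(names(shared_deg_counts)) || any(names(shared_deg_counts) == "")) {
      stop("shared_deg_counts must be a named list", call. = FALSE)
    }
    if (any(unlist(shared_deg_counts) < 0)) {
      stop("shared_deg_counts must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      n_larvae_per_group = as.integer(n_larvae_per_group),
      groups = groups,
      baseline_dark_mean = baseline_dark_mean,
      baseline_light_mean = baseline_light_mean,
      noise_cv = noise_cv,
      outlier_rate = outlier_rate,
      outlier_scale = outlier_scale,
      nonresponder_rate = nonresponder_rate,
      n_embryos_per_condition = as.integer(n_embryos_per_condition),
      n_genes = as.integer(n_genes),
      n_true_deg = as.integer(n_true_deg),
      lfc_effect_mean = lfc_effect_mean,
      lfc_effect_sd = lfc_effect_sd,
      null_lfc_sd = null_lfc_sd,
      planted_p_max = planted_p_max,
      shared_deg_counts = shared_deg_counts
    ),
    class = "simulation_config"
  )
}

#' Simulate larval locomotion traces
#'
#' Draws one distance-per-bin trace per larva per group. Dark-phase bins
#' are drawn from a normal with mean `baseline_dark_mean x
#' effect_multiplier_dark` and SD `noise_cv x mean`, clipped at zero
#' (movement cannot be negative); light-phase bins analogously. With
#' probability `outlier_rate` a bin is multiplied by `outlier_scale`
#' (tracking artifact). With probability `nonresponder_rate` a larva is
#' a non-responder: its realized light bins are rescaled so the realized
#' light:dark mean ratio equals 0.95, which guarantees the QC ratio rule
#' (cutoff 0.9) removes it. Bins are independent given phase; no
#' within-larva temporal autocorrelation is modeled.
#'
#' @param config A [simulation_config()].
#' @param schedule A [photoperiod_schedule()].
#' @return A list: `traces` (tidy tibble: `larva_id`, `group`,
#'   `chemical`, `concentration_nM`, `duration`, `bin_index`, `time_s`,
#'   `phase`, `within_phase_elapsed_s`, `distance_cm`) and `truth`
#'   (list with `larvae` — per-larva `nonresponder` flag — and
#'   `outlier_bins` — `larva_id`, `bin_index` of artifact bins).
#' @export
simulate_traces <- function(config, schedule = photoperiod_schedule()) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- schedule_phases(schedule)
  if (nrow(layout) == 0L) stop("schedule has no bins", call. = FALSE)
  set.seed(derive_seed(config$seed, "traces"))
  is_light <- layout$phase == "light"
  n_bins <- nrow(layout)
  out <- vector("list", nrow(config$groups))
  truth_larvae <- vector("list", nrow(config$groups))
  outlier_rows <- vector("list", nrow(config$groups))
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    mu_dark <- config$baseline_dark_mean * grp$effect_multiplier_dark
    mu_light <- config$baseline_light_mean * grp$effect_multiplier_light
    ids <- sprintf("%s_larva%02d", grp$group, seq_len(config$n_larvae_per_group))
    mats <- vector("list", config$n_larvae_per_group)
    nonresp <- logical(config$n_larvae_per_group)
    outl <- vector("list", config$n_larvae_per_group)
    for (j in seq_len(config$n_larvae_per_group)) {
      mu <- ifelse(is_light, mu_light, mu_dark)
      d <- stats::rnorm(n_bins, mean = mu, sd = config$noise_cv * mu)
      d <- pmax(d, 0)
      is_out <- stats::runif(n_bins) < config$outlier_rate
      d[is_out] <- d[is_out] * config$outlier_scale
      nonresp[j] <- stats::runif(1) < config$nonresponder_rate
      if (nonresp[j]) {
        md <- mean(d[!is_light])
        ml <- mean(d[is_light])
        target <- 0.95 * md
        d[is_light] <- if (ml > 0) d[is_light] * (target / ml) else target
      }
      mats[[j]] <- d
      outl[[j]] <- which(is_out)
    }
    out[[g]] <- tibble::tibble(
      larva_id = rep(ids, each = n_bins),
      group = grp$group,
      chemical = grp$chemical,
      concentration_nM = grp$concentration_nM,
      duration = grp$duration,
      bin_index = rep(layout$bin_index, config$n_larvae_per_group),
      time_s = rep(layout$time_s, config$n_larvae_per_group),
      phase = rep(layout$phase, config$n_larvae_per_group),
      within_phase_elapsed_s = rep(layout$within_phase_elapsed_s, config$n_larvae_per_group),
      distance_cm = unlist(mats)
    )
    truth_larvae[[g]] <- tibble::tibble(
      larva_id = ids, group = grp$group, nonresponder = nonresp
    )
    outlier_rows[[g]] <- tibble::tibble(
      larva_id = rep(ids, lengths(outl)),
      bin_index = unlist(outl, use.names = FALSE)
    )
  }
  list(
    traces = dplyr::bind_rows(out),
    truth = list(
      larvae = dplyr::bind_rows(truth_larvae),
      outlier_bins = dplyr::bind_rows(outlier_rows)
    )
  )
}

or_adjust <- function(p, or) {
  if (is.infinite(or)) {
    return(ifelse(p > 0, 1, 0))
  }
  or * p / (1 - p + or * p)
}

#' Simulate an abnormality/mortality screening table
#'
#' Per-larva simulation of the screening protocol: death occurs per
#' 24-h interval with a baseline hazard (cumulative over the 24–120 hpf
#' timepoints; the dead stay dead), and each abnormality endpoint is a
#' per-larva latent Bernoulli observed among survivors at every
#' screening timepoint. Group effects act on the odds of each baseline
#' probability. "Total abnormalities" counts larvae with at least one
#' morphological abnormality, so a multiply-abnormal larva counts once
#' and the count can never exceed the survivors.
#'
#' @param config A [simulation_config()] (supplies group table, embryo
#'   count and seed).
#' @param baseline_probs Named numeric: `mortality` (per-interval
#'   hazard) plus per-endpoint abnormality probabilities.
#' @param effect_or Optional tibble `group`, `endpoint`, `odds_ratio`
#'   (missing combinations default to 1).
#' @param timepoints_hpf Screening timepoints.
#' @return Tidy tibble: `group`, `chemical`, `concentration_nM`,
#'   `duration`, `timepoint_hpf`, `endpoint`, `n_affected`, `n_total`.
#'   Mortality is counted among all embryos; abnormality endpoints among
#'   survivors at that timepoint.
#' @export
simulate_screening <- function(config,
                               baseline_probs = c(
                                 mortality = 0.01, unhatched = 0.10,
                                 skeletal = 0.03, uninflated_swim_bladder = 0.08,
                                 yolk_sac_edema = 0.05, cardiac_edema = 0.05
                               ),
                               effect_or = NULL,
                               timepoints_hpf = c(24, 48, 72, 96, 120)) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(baseline_probs < 0 | baseline_probs > 1)) {
    stop("baseline probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!"mortality" %in% names(baseline_probs)) {
    stop("baseline_probs must include a 'mortality' hazard", call. = FALSE)
  }
  if (!is.null(effect_or) && any(effect_or$odds_ratio < 0)) {
    stop("odds ratios must be non-negative", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "screening"))
  abn_endpoints <- setdiff(names(baseline_probs), "mortality")
  morph_endpoints <- setdiff(abn_endpoints, "unhatched")
  n <- config$n_embryos_per_condition
  get_or <- function(group, endpoint) {
    if (is.null(effect_or)) {
      return(1)
    }
    hit <- effect_or[effect_or$group == group & effect_or$endpoint == endpoint, ]
    if (nrow(hit) == 1L) hit$odds_ratio else 1
  }
  purrr::map_dfr(seq_len(nrow(config$groups)), function(g) {
    grp <- config$groups[g, ]
    haz <- or_adjust(baseline_probs[["mortality"]], get_or(grp$group, "mortality"))
    # death interval per embryo; Inf = survives the study
    alive <- matrix(TRUE, nrow = n, ncol = length(timepoints_hpf))
    dead_now <- rep(FALSE, n)
    for (t in seq_along(timepoints_hpf)) {
      dies <- !dead_now & (stats::runif(n) < haz)
      dead_now <- dead_now | dies
      alive[, t] <- !dead_now
    }
    latent <- vapply(abn_endpoints, function(ep) {
      p <- or_adjust(baseline_probs[[ep]], get_or(grp$group, ep))
      stats::runif(n) < p
    }, logical(n))
    any_morph <- if (length(morph_endpoints)) {
      rowSums(latent[, morph_endpoints, drop = FALSE]) > 0
    } else {
      rep(FALSE, n)
    }
    purrr::map_dfr(seq_along(timepoints_hpf), function(t) {
      surv <- alive[, t]
      counts <- c(
        mortality = sum(!surv),
        vapply(abn_endpoints, function(ep) sum(latent[, ep] & surv), integer(1)),
        total_abnormalities = sum(any_morph & surv)
      )
      totals <- c(
        mortality = n,
        stats::setNames(rep(sum(surv), length(abn_endpoints)), abn_endpoints),
        total_abnormalities = sum(surv)
      )
      tibble::tibble(
        group = grp$group, chemical = grp$chemical,
        concentration_nM = grp$concentration_nM, duration = grp$duration,
        timepoint_hpf = timepoints_hpf[t],
        endpoint = names(counts),
        n_affected = as.integer(counts),
        n_total = as.integer(totals)
      )
    })
  })
}

#' Simulate per-gene differential-expression tables with planted truth
#'
#' For every non-control condition (chemical x concentration x
#' duration), draws a genome-scale results table: null genes get
#' log2 fold changes from a small centered normal and raw p ~ U(0, 1);
#' planted DEGs get |log2FC| ~ N(`lfc_effect_mean`, `lfc_effect_sd`)
#' with random sign and raw p ~ U(0, `planted_p_max`). Adjusted p-values
#' are Benjamini-Hochberg within each condition. `shared_deg_counts`
#' plants genes as DEGs in exactly the named chemical sets (in the first
#' condition of each member chemical), disjointly from the per-condition
#' exclusive plantings, so cross-chemical overlap regions are known by
#' construction.
#'
#' @param config A [simulation_config()].
#' @return A list: `records` (tibble `gene_id`, `chemical`,
#'   `concentration_nM`, `duration`, `log2fc`, `raw_p`, `padj`) and
#'   `truth` (tibble `gene_id`, `chemical`, `concentration_nM`,
#'   `duration`, `planted_set`).
#' @export
simulate_deg_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "deg"))
  conds <- dplyr::filter(config$groups, .data$concentration_nM > 0)
  if (nrow(conds) == 0L) stop("no non-control conditions to simulate", call. = FALSE)
  chems <- unique(conds$chemical)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  # allocate shared genes first, then exclusive per-condition plantings
  shared <- config$shared_deg_counts
  shared_assign <- list() # chemical -> genes planted via shared sets
  next_gene <- 1L
  truth_shared <- NULL
  if (!is.null(shared) && length(shared)) {
    for (k in names(shared)) {
      members <- strsplit(k, "&", fixed = TRUE)[[1]]
      if (!all(members %in% chems)) {
        stop(sprintf("shared_deg_counts set '%s' names unknown chemicals", k),
          call. = FALSE
        )
      }
      cnt <- shared[[k]]
      if (next_gene + cnt - 1L > config$n_genes) {
        stop("shared_deg_counts exceed n_genes", call. = FALSE)
      }
      genes <- gene_ids[next_gene:(next_gene + cnt - 1L)]
      next_gene <- next_gene + cnt
      for (ch in members) {
        shared_assign[[ch]] <- c(shared_assign[[ch]], genes)
      }
      truth_shared <- dplyr::bind_rows(
        truth_shared,
        tibble::tibble(gene_id = genes, planted_set = k)
      )
    }
    for (ch in chems) {
      n_shared_ch <- length(shared_assign[[ch]])
      if (n_shared_ch > config$n_true_deg) {
        stop(sprintf(
          "shared plantings for '%s' (%d) exceed n_true_deg (%d)",
          ch, n_shared_ch, config$n_true_deg
        ), call. = FALSE)
      }
    }
  }
  first_cond <- conds |>
    dplyr::group_by(.data$chemical) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  records <- vector("list", nrow(conds))
  truth <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cd <- conds[i, ]
    is_first <- any(first_cond$chemical == cd$chemical &
      first_cond$concentration_nM == cd$concentration_nM &
      first_cond$duration == cd$duration)
    planted_shared <- if (is_first) shared_assign[[cd$chemical]] else NULL
    n_excl <- config$n_true_deg - length(planted_shared)
    excl <- character(0)
    if (n_excl > 0L) {
      if (next_gene + n_excl - 1L > config$n_genes) {
        stop("n_true_deg plantings exceed n_genes", call. = FALSE)
      }
      excl <- gene_ids[next_gene:(next_gene + n_excl - 1L)]
      next_gene <- next_gene + n_excl
    }
    planted <- c(planted_shared, excl)
    lfc <- stats::rnorm(config$n_genes, 0, config$null_lfc_sd)
    raw_p <- stats::runif(config$n_genes)
    idx <- match(planted, gene_ids)
    if (length(idx)) {
      lfc[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
        abs(stats::rnorm(length(idx), config$lfc_effect_mean, config$lfc_effect_sd))
      raw_p[idx] <- stats::runif(length(idx), 0, config$planted_p_max)
    }
    padj <- stats::p.adjust(raw_p, method = "BH")
    records[[i]] <- tibble::tibble(
      gene_id = gene_ids, chemical = cd$chemical,
      concentration_nM = cd$concentration_nM, duration = cd$duration,
      log2fc = lfc, raw_p = raw_p, padj = padj
    )
    if (length(planted)) {
      truth[[i]] <- tibble::tibble(
        gene_id = planted, chemical = cd$chemical,
        concentration_nM = cd$concentration_nM, duration = cd$duration,
        planted_set = ifelse(gene_id %in% (truth_shared$gene_id %||% character(0)),
          truth_shared$planted_set[match(gene_id, truth_shared$gene_id)],
          cd$chemical
        )
      )
    }
  }
  list(records = dplyr::bind_rows(records), truth = dplyr::bind_rows(truth))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
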