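two_group_config <- function(seed, mult_dark = 1, ...) {
  groups <- tibble::tibble(
    group = c("control", "treated"),
    chemical = "triclocarban",
    concentration_nM = c(0, 10),
    duration = "120h",
    effect_multiplier_dark = c(1, mult_dark),
    effect_multiplier_light = 1
  )
  simulation_config(seed = seed, groups = groups, ...)
}

test_that("identical configurations reproduce bit-identical outputs", {
  cfg <- two_group_config(99)
  s1 <- simulate_traces(cfg)
  s2 <- simulate_traces(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_screening(cfg), simulate_screening(cfg))
  expect_identical(simulate_deg_table(cfg), simulate_deg_table(cfg))
  # a different seed perturbs the draws
  expect_false(identical(s1$traces$distance_cm,
    simulate_traces(two_group_config(100))$traces$distance_cm))
})

test_that("with noise, outliers and nonresponders off, bins equal their means", {
  cfg <- two_group_config(1,
    noise_cv = 0, outlier_rate = 0, nonresponder_rate = 0
  )
  s <- simulate_traces(cfg)
  dark <- s$traces$distance_cm[s$traces$phase == "dark" & s$traces$group == "control"]
  light <- s$traces$distance_cm[s$traces$phase == "light" & s$traces$group == "control"]
  expect_true(all(dark == cfg$baseline_dark_mean))
  expect_true(all(light == cfg$baseline_light_mean))
  expect_false(any(s$truth$larvae$nonresponder))
  expect_equal(nrow(s$truth$outlier_bins), 0)
})

test_that("invalid generator settings are rejected", {
  expect_error(two_group_config(1, outlier_rate = 1.2), "rates")
  expect_error(two_group_config(1, baseline_dark_mean = -1), "finite and non-negative")
  expect_error(two_group_config(1, baseline_dark_mean = Inf), "finite")
  expect_error(two_group_config(1, mult_dark = -2), "multipliers")
  expect_error(simulation_config(n_true_deg = 10, n_genes = 5), "n_true_deg")
})

test_that("a dark-phase multiplier of 0.5 depresses the group mean almost surely", {
  below <- vapply(1:200, function(i) {
    s <- simulate_traces(two_group_config(1000 + i, mult_dark = 0.5))
    m <- s$traces |>
      dplyr::filter(phase == "dark") |>
      dplyr::group_by(group) |>
      dplyr::summarise(mean_d = mean(distance_cm), .groups = "drop")
    m$mean_d[m$group == "treated"] < m$mean_d[m$group == "control"]
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("planted nonresponders have a light:dark ratio of exactly 0.95", {
  cfg <- two_group_config(7, nonresponder_rate = 0.5)
  s <- simulate_traces(cfg)
  planted <- s$truth$larvae$larva_id[s$truth$larvae$nonresponder]
  expect_gt(length(planted), 0)
  for (id in planted) {
    tr <- s$traces[s$traces$larva_id == id, ]
    ratio <- mean(tr$distance_cm[tr$phase == "light"]) /
      mean(tr$distance_cm[tr$phase == "dark"])
    expect_equal(ratio, 0.95, tolerance = 1e-10)
  }
})

test_that("null screening effects differ only by binomial noise", {
  cfg <- two_group_config(3)
  sc <- simulate_screening(cfg, baseline_probs = c(mortality = 0, skeletal = 0.2))
  skel <- sc[sc$endpoint == "skeletal" & sc$timepoint_hpf == 120, ]
  # equal true proportions: difference within 4 binomial SDs
  p_hat <- skel$n_affected / skel$n_total
  se <- sqrt(2 * 0.2 * 0.8 / 150)
  expect_lt(abs(diff(p_hat)), 4 * se)
})

test_that("certain mortality is absorbing and empties the survivor pool", {
  cfg <- two_group_config(5)
  sc <- simulate_screening(cfg, baseline_probs = c(mortality = 1, skeletal = 0.1))
  mort <- sc[sc$endpoint == "mortality", ]
  expect_true(all(mort$n_affected == mort$n_total))
  abn <- sc[sc$endpoint == "skeletal", ]
  expect_true(all(abn$n_total == 0))
  gate <- mortality_gate(sc)
  expect_true(all(!gate$evaluable))
})

test_that("screening counts match the analytic logit-adjusted binomial mean", {
  or <- tibble::tibble(group = "treated", endpoint = "skeletal", odds_ratio = 5)
  p0 <- 0.05
  p1 <- 5 * p0 / (1 - p0 + 5 * p0) # odds-ratio adjustment
  counts <- vapply(1:1000, function(i) {
    sc <- simulate_screening(two_group_config(2000 + i),
      baseline_probs = c(mortality = 0, skeletal = p0),
      effect_or = or, timepoints_hpf = 120
    )
    sc$n_affected[sc$endpoint == "skeletal" & sc$group == "treated"]
  }, integer(1))
  analytic_mean <- 150 * p1
  se_mean <- sqrt(150 * p1 * (1 - p1)) / sqrt(1000)
  expect_lt(abs(mean(counts) - analytic_mean), 3 * se_mean)
})

test_that("single-gene tables leave the BH adjustment as the identity", {
  cfg <- two_group_config(11, n_genes = 1, n_true_deg = 0)
  d <- simulate_deg_table(cfg)
  expect_equal(d$records$padj, d$records$raw_p)
})

test_that("BH adjustment is monotone in raw p and bounded by 1", {
  cfg <- two_group_config(13, n_genes = 500, n_true_deg = 20)
  d <- simulate_deg_table(cfg)
  for (cond in split(d$records, d$records$concentration_nM)) {
    o <- order(cond$raw_p)
    expect_true(all(diff(cond$padj[o]) >= -1e-12))
    expect_true(all(cond$padj <= 1))
    expect_true(all(cond$padj >= cond$raw_p - 1e-12))
  }
})

test_that("shared plantings construct exact chemical-set membership", {
  groups <- tidyr::expand_grid(
    chemical = c("A", "B", "C"),
    concentration_nM = c(0, 1, 10),
    duration = "120h"
  )
  groups$group <- paste0(groups$chemical, "_", groups$concentration_nM)
  groups$effect_multiplier_dark <- 1
  groups$effect_multiplier_light <- 1
  cfg <- simulation_config(
    seed = 17, groups = groups, n_genes = 2000, n_true_deg = 30,
    shared_deg_counts = list("A&B&C" = 6, "A&B" = 4)
  )
  d <- simulate_deg_table(cfg)
  triple <- d$truth$gene_id[d$truth$planted_set == "A&B&C"]
  expect_equal(length(unique(triple)), 6)
  by_chem <- split(d$truth$gene_id, d$truth$chemical)
  for (g in unique(triple)) {
    expect_true(all(vapply(by_chem, function(x) g %in% x, logical(1))))
  }
  pair <- unique(d$truth$gene_id[d$truth$planted_set == "A&B"])
  expect_equal(length(pair), 4)
  expect_true(all(pair %in% by_chem$A) && all(pair %in% by_chem$B))
  expect_false(any(pair %in% by_chem$C))
  # inconsistent shared counts are rejected
  expect_error(
    simulate_deg_table(simulation_config(
      seed = 1, groups = groups, n_genes = 2000, n_true_deg = 3,
      shared_deg_counts = list("A&B&C" = 6)
    )),
    "exceed n_true_deg"
  )
})

test_that("with nothing planted the filter passes essentially no genes", {
  counts <- vapply(1:100, function(i) {
    cfg <- two_group_config(3000 + i, n_genes = 1000, n_true_deg = 0)
    d <- simulate_deg_table(cfg)
    nrow(filter_degs(d$records))
  }, numeric(1))
  # per-gene pass probability is bounded by
  # P(|lfc| >= 0.75) * P(padj < 0.1) <= 2*pnorm(-0.75/0.2) * 0.1 ~ 1.8e-5,
  # so over 1e5 gene-condition draws a handful of passes at most
  expect_lte(sum(counts), 12)
})

test_that("strongly planted genes are recovered by the downstream filter", {
  recovered <- total <- 0
  for (i in 1:20) {
    cfg <- two_group_config(4000 + i,
      n_genes = 5000, n_true_deg = 50,
      lfc_effect_mean = 2, lfc_effect_sd = 0.2, planted_p_max = 1e-4
    )
    d <- simulate_deg_table(cfg)
    sig <- filter_degs(d$records)
    planted <- dplyr::semi_join(
      d$records,
      d$truth,
      by = c("gene_id", "chemical", "concentration_nM", "duration")
    )
    strong <- planted[abs(planted$log2fc) >= 1.5, ]
    hit <- dplyr::semi_join(
      strong, sig,
      by = c("gene_id", "chemical", "concentration_nM", "duration")
    )
    recovered <- recovered + nrow(hit)
    total <- total + nrow(strong)
  }
  expect_gt(total, 500)
  expect_gte(recovered / total, 0.9)
})
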