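# Quality-control statistics: germination formula, class summaries,
# FPR/FNR recovery, Kruskal-Wallis with a permutation oracle, single-marker
# regression and the CRD ANOVA.

make_calls <- function(classes, marker = "K_1", pop = "P") {
  tibble::tibble(population_id = pop,
                 progeny_id = paste0(pop, "_", seq_along(classes)),
                 marker_id = marker, called_class = classes)
}

test_that("germination formula reproduces the printed extremes", {
  expect_equal(germination_percent(1, 12), 8.33)
  expect_equal(germination_percent(0, 12), 0)
  expect_equal(germination_percent(11, 12), 91.67)
  expect_equal(germination_percent(3, 18), 16.67)  # counts (1, 0, 2) of 6x3
  expect_error(germination_percent(5, 0), class = "kaspanel_validation_error")
  expect_error(germination_percent(13, 12),
               class = "kaspanel_validation_error")
})

test_that("allele-class summaries count homozygote classes only", {
  calls <- make_calls(c(rep("recipient_hom", 156), rep("donor_hom", 166),
                        rep("het", 50), rep(NA_character_, 2)))
  s <- allele_class_summary(calls)
  expect_equal(s$n_tested, 374L)
  expect_equal(s$freq_negative_pct, 41.7)  # 156/374
  expect_equal(s$freq_positive_pct, 44.4)  # 166/374
  expect_equal(s$n_het, 50L)
  expect_equal(s$n_missing, 2L)
  expect_equal(s$n_negative + s$n_positive + s$n_het + s$n_missing,
               s$n_tested)
  # all-het input: both frequencies zero, empty-class flag set
  s2 <- allele_class_summary(make_calls(rep("het", 20)))
  expect_equal(s2$freq_negative_pct, 0)
  expect_equal(s2$freq_positive_pct, 0)
  expect_true(s2$empty_class)
})

test_that("class means come from the called homozygotes, NA when empty", {
  calls <- make_calls(c("recipient_hom", "recipient_hom", "donor_hom",
                        "het"))
  phen <- tibble::tibble(
    population_id = "P", progeny_id = paste0("P_", 1:4),
    depth_cm = 10, germination_pct = c(10, 20, 80, 50),
    mesocotyl_cm = c(1, 1.4, 4.8, 3))
  s <- allele_class_summary(calls, phen)
  expect_equal(s$mean_negative_germination_pct, 15)
  expect_equal(s$mean_positive_germination_pct, 80)
  expect_equal(s$mean_positive_mesocotyl_cm, 4.8)
  s2 <- allele_class_summary(make_calls(rep("het", 3)),
                             phen[1:3, ] |>
                               dplyr::mutate(progeny_id = paste0("P_", 1:3)))
  expect_true("mean_negative_germination_pct" %in% names(s2))
  expect_true(is.na(s2$mean_negative_germination_pct))
})

test_that("fixture frequencies recompute to the printed percentages", {
  tab <- load_table3()
  flagged <- grepl("imply|gives", tab$provenance)
  expect_equal(sum(flagged), 3L)
  ok <- !flagged
  expect_true(all(abs(tab$freq_negative_pct_a -
                        100 * tab$n_negative_a / tab$n_tested_a)[ok] <= 0.1))
  expect_true(all(abs(tab$freq_positive_pct_a -
                        100 * tab$n_positive_a / tab$n_tested_a)[ok] <= 0.1))
  expect_true(all(abs(tab$freq_negative_pct_b -
                        100 * tab$n_negative_b / tab$n_tested_b) <= 0.1))
  expect_true(all(abs(tab$freq_positive_pct_b -
                        100 * tab$n_positive_b / tab$n_tested_b) <= 0.1))
})

test_that("error-rate estimators recover injected rates across a grid", {
  n <- 10000L
  for (rate in c(0.01, 0.05, 0.10)) {
    truth <- tibble::tibble(
      population_id = "P", progeny_id = paste0("p", 1:n),
      marker_id = "K_1", region_id = "r",
      true_class = rep(c("recipient_hom", "het", "donor_hom"),
                       length.out = n))
    calls <- inject_assay_error(truth,
                                list(false_positive = rate,
                                     false_negative = rate, missing = 0),
                                seed = round(1000 * rate) + 7)
    fpr <- false_positive_rate(calls)
    fnr <- false_negative_rate(calls)
    n_rec <- fpr$n_truth
    n_car <- fnr$n_truth
    expect_lt(abs(fpr$rate - rate), 3 * sqrt(rate * (1 - rate) / n_rec))
    expect_lt(abs(fnr$rate - rate), 3 * sqrt(rate * (1 - rate) / n_car))
  }
})

test_that("error-rate edge cases behave exactly", {
  calls <- make_calls(rep("recipient_hom", 10)) |>
    dplyr::mutate(true_class = "recipient_hom")
  expect_equal(false_positive_rate(calls)$rate, 0)
  flipped <- dplyr::mutate(calls, called_class = "het")
  expect_equal(false_positive_rate(flipped)$rate, 1)
  # no truth-recipient lines: undefined and flagged
  donor_only <- make_calls(rep("donor_hom", 5)) |>
    dplyr::mutate(true_class = "donor_hom")
  fp <- false_positive_rate(donor_only)
  expect_equal(nrow(fp), 0L)
  expect_equal(false_negative_rate(donor_only)$rate, 0)
  # missing calls count as discordant by default, not when toggled off
  half_missing <- make_calls(c(rep("recipient_hom", 5),
                               rep(NA_character_, 5))) |>
    dplyr::mutate(true_class = "recipient_hom")
  expect_equal(false_positive_rate(half_missing)$rate, 0.5)
  expect_equal(false_positive_rate(half_missing,
                                   missing_as_discordant = FALSE)$rate, 0)
})

test_that("all calls missing leaves QC metrics undefined, not zero", {
  calls <- make_calls(rep(NA_character_, 12)) |>
    dplyr::mutate(true_class = rep(c("recipient_hom", "donor_hom"), 6))
  expect_equal(false_positive_rate(calls)$rate, 1)  # strict default
  s <- allele_class_summary(calls)
  expect_true(s$empty_class)
  expect_equal(s$n_missing, 12L)
})

# independent oracle: exact permutation distribution of the Kruskal-Wallis
# statistic for two small groups
kw_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  H_of <- function(idx) {
    r <- rank(pooled)
    R1 <- sum(r[idx]); R2 <- sum(r[-idx])
    n1 <- length(idx); n2 <- n - n1
    H <- 12 / (n * (n + 1)) * (R1^2 / n1 + R2^2 / n2) - 3 * (n + 1)
    ties <- table(pooled)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  obs <- H_of(seq_along(x))
  combos <- utils::combn(n, length(x))
  ps <- apply(combos, 2, H_of)
  mean(ps >= obs - 1e-12)
}

test_that("Kruskal-Wallis H matches the hand formula and permutation p", {
  calls <- make_calls(c(rep("recipient_hom", 3), rep("donor_hom", 3)))
  phen <- tibble::tibble(population_id = "P",
                         progeny_id = paste0("P_", 1:6), depth_cm = 10,
                         germination_pct = c(1, 2, 3, 4, 5, 6))
  kw <- kruskal_wallis_effect(calls, phen)
  expect_equal(round(kw$kw_H, 3), 3.857)
  expect_equal(kw_perm_p(1:3, 4:6), 0.1, tolerance = 1e-9)
  # identical groups give H = 0, p = 1
  phen2 <- dplyr::mutate(phen, germination_pct = 5)
  kw2 <- kruskal_wallis_effect(calls, phen2)
  expect_equal(kw2$kw_H, 0)
  expect_equal(kw2$kw_p, 1)
  # significance tiers
  expect_equal(significance_tier(c(0.0004, 0.004, 0.04, 0.4)),
               c("***", "**", "*", "ns"))
})

test_that("chi-square p agrees with exact permutation p on small groups", {
  # the chi-square approximation tracks the exact permutation distribution
  # for groups of <= 10; at these sizes the two p values can differ by up
  # to about 0.1 in absolute terms, so agreement is asserted at that scale
  # along with rank agreement of significance at the 5% tier
  withr::with_seed(31, {
    for (rep in 1:8) {
      n1 <- sample(6:10, 1); n2 <- sample(6:10, 1)
      x <- sample(1:40, n1); y <- sample(1:40, n2)
      calls <- make_calls(c(rep("recipient_hom", n1),
                            rep("donor_hom", n2)))
      phen <- tibble::tibble(population_id = "P",
                             progeny_id = calls$progeny_id, depth_cm = 10,
                             germination_pct = c(x, y))
      kw <- kruskal_wallis_effect(calls, phen)
      p_exact <- kw_perm_p(x, y)
      expect_lt(abs(kw$kw_p - p_exact), 0.1)
    }
  })
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  withr::with_seed(12, {
    y <- rnorm(24)
  })
  calls <- make_calls(rep(c("recipient_hom", "donor_hom"), each = 12))
  ph <- function(v) tibble::tibble(population_id = "P",
                                   progeny_id = calls$progeny_id,
                                   depth_cm = 10, germination_pct = v)
  h0 <- kruskal_wallis_effect(calls, ph(y))$kw_H
  expect_equal(kruskal_wallis_effect(calls, ph(exp(y)))$kw_H, h0)
  expect_equal(kruskal_wallis_effect(calls, ph(y^3))$kw_H, h0)
})

test_that("single-marker regression matches its algebraic identities", {
  calls <- make_calls(rep(c("recipient_hom", "het", "donor_hom"), 10))
  dosage <- kaspanel:::class_to_dosage(calls$called_class)
  # exactly linear phenotype: r2 = 1
  phen <- tibble::tibble(population_id = "P", progeny_id = calls$progeny_id,
                         depth_cm = 10, germination_pct = 10 + 5 * dosage)
  s <- single_marker_analysis(calls, phen)
  expect_equal(s$r2, 1)
  # r2 equals the squared Pearson correlation
  withr::with_seed(9, {
    y <- 10 + 5 * dosage + rnorm(30, sd = 4)
  })
  phen2 <- dplyr::mutate(phen, germination_pct = y)
  s2 <- single_marker_analysis(calls, phen2)
  expect_equal(s2$r2, cor(dosage, y)^2, tolerance = 1e-12)
})

test_that("single-marker p values are uniform under the null", {
  n_sim <- 1500L
  n <- 30L
  withr::with_seed(77, {
    dosage <- rep(c(0, 1, 2), each = 10)
    calls <- purrr::map_dfr(seq_len(n_sim), function(k) {
      tibble::tibble(population_id = "P",
                     progeny_id = paste0("s", k, "_", 1:n),
                     marker_id = paste0("K_", k),
                     called_class = kaspanel:::dosage_to_class(
                       sample(dosage)))
    })
    phen <- calls |>
      dplyr::distinct(population_id, progeny_id) |>
      dplyr::mutate(depth_cm = 10, germination_pct = rnorm(dplyr::n()))
  })
  s <- single_marker_analysis(calls, phen)
  ks <- suppressWarnings(stats::ks.test(s$smr_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("CRD ANOVA reports the model table and CV%", {
  # all observations equal: treatment SS 0, F = 0, p = 1
  d0 <- tibble::tibble(y = rep(5, 6), g = rep(c("a", "b"), each = 3))
  a0 <- anova_crd(d0, "y", "g")
  expect_equal(a0$table$statistic[1], 0)
  expect_equal(a0$table$p.value[1], 1)
  # zero error variance with distinct means: MSE-zero flag
  d1 <- tibble::tibble(y = c(10, 10, 10, 20, 20, 20),
                       g = rep(c("a", "b"), each = 3))
  a1 <- anova_crd(d1, "y", "g")
  expect_true(a1$mse_zero)
  # CV% ~ 100 * sigma / mean
  withr::with_seed(21, {
    d2 <- tibble::tibble(
      g = rep(paste0("g", 1:40), each = 3),
      y = 20 + rnorm(120, sd = 2))
  })
  a2 <- anova_crd(d2, "y", "g")
  expect_lt(abs(a2$cv_pct - 10), 2.5)
  # single-replicate genotypes are dropped with a warning
  d3 <- dplyr::bind_rows(d1, tibble::tibble(y = 3, g = "c"))
  expect_warning(a3 <- anova_crd(d3, "y", "g"), "single replicate")
  expect_equal(a3$n_dropped, 1L)
  # broom-style accessors
  expect_s3_class(tidy(a2), "tbl_df")
  expect_equal(glance(a2)$cv_pct, a2$cv_pct)
})

test_that("the assembled QC table carries one row per marker and class", {
  n <- 60L
  truth <- tibble::tibble(
    population_id = rep(c("F3:F4", "BC3F2:3"), each = n),
    progeny_id = paste0("p", 1:(2 * n)),
    marker_id = "K_9", region_id = "r",
    true_class = rep(c("recipient_hom", "donor_hom", "het"),
                     length.out = 2 * n))
  calls <- inject_assay_error(truth, list(false_positive = 0.1,
                                          false_negative = 0.05,
                                          missing = 0.02), seed = 5)
  withr::with_seed(6, {
    phen <- tibble::tibble(
      population_id = truth$population_id, progeny_id = truth$progeny_id,
      depth_cm = 10,
      germination_pct = ifelse(truth$true_class == "donor_hom", 70, 22) +
        rnorm(2 * n, sd = 8),
      mesocotyl_cm = ifelse(truth$true_class == "donor_hom", 4.8, 1.1) +
        rnorm(2 * n, sd = 0.4))
  })
  qc <- marker_qc_table(calls, phen)
  expect_equal(nrow(qc), 2L)
  expect_true(all(c("fpr", "fnr", "kw_H", "kw_p", "significance", "r2",
                    "smr_p") %in% names(qc)))
  expect_true(all(qc$n_negative + qc$n_positive + qc$n_het + qc$n_missing ==
                    qc$n_tested))
  expect_true(all(qc$significance == significance_tier(qc$kw_p)))
  expect_true(all(qc$mean_positive_germination_pct >
                    qc$mean_negative_germination_pct))
})
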