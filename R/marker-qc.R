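# Per-marker, per-population quality control: allele-class counts and
# frequencies, phenotypic class means, false-positive / false-negative
# rates against a truth channel, Kruskal-Wallis allelic effects,
# single-marker regression, and the CRD ANOVA with CV%.

#' Significance tier symbol
#'
#' Maps a p value to the printed tiers: `***` below 0.1%, `**` below 1%,
#' `*` below 5%, otherwise `ns`.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of symbols.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Allele-class counts, frequencies and phenotypic class means
#'
#' The negative class collects recipient-homozygous calls, the positive
#' class donor-homozygous calls; heterozygotes and missing calls belong to
#' neither but are counted in `n_tested`, so the two frequencies do not sum
#' to 100%. Frequencies are percentages of `n_tested` to one decimal. Class
#' means are computed for each requested trait; an empty class yields `NA`
#' (flagged), never zero.
#'
#' @param calls Long tibble with `marker_id`, `progeny_id`, `called_class`
#'   (and optionally `population_id`, used as an extra grouping key).
#' @param phenotypes Optional phenotype tibble (long by depth, as from
#'   [simulate_phenotypes()]); class means are taken at `depth_cm = depth`.
#' @param traits Phenotype columns to average per class.
#' @param depth Sowing depth at which class means are taken (default 10).
#' @return A tibble with one row per marker (x population).
#' @export
allele_class_summary <- function(calls, phenotypes = NULL,
                                 traits = c("germination_pct",
                                            "mesocotyl_cm"),
                                 depth = 10) {
  grp <- intersect(c("population_id", "marker_id"), names(calls))
  base <- calls |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(
      n_tested = dplyr::n(),
      n_negative = sum(.data$called_class == "recipient_hom", na.rm = TRUE),
      n_positive = sum(.data$called_class == "donor_hom", na.rm = TRUE),
      n_het = sum(.data$called_class == "het", na.rm = TRUE),
      n_missing = sum(is.na(.data$called_class)),
      .groups = "drop"
    ) |>
    mutate(
      freq_negative_pct = round(100 * .data$n_negative / .data$n_tested, 1),
      freq_positive_pct = round(100 * .data$n_positive / .data$n_tested, 1),
      empty_class = .data$n_negative == 0 | .data$n_positive == 0
    )
  if (is.null(phenotypes)) return(base)
  ph <- filter(phenotypes, .data$depth_cm == depth)
  classed <- calls |>
    filter(.data$called_class %in% c("recipient_hom", "donor_hom")) |>
    mutate(class = if_else(.data$called_class == "donor_hom",
                           "positive", "negative")) |>
    left_join(ph, by = intersect(c("population_id", "progeny_id"),
                                 intersect(names(calls), names(ph))))
  means <- classed |>
    group_by(across(dplyr::all_of(c(grp, "class")))) |>
    summarise(across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop") |>
    pivot_wider(names_from = "class",
                values_from = dplyr::all_of(traits),
                names_glue = "mean_{class}_{.value}")
  want <- as.vector(outer(c("mean_negative_", "mean_positive_"), traits,
                          paste0))
  for (col in setdiff(want, names(means))) means[[col]] <- NA_real_
  left_join(base, means, by = grp)
}

fraction_rate <- function(calls, denom_filter, discordant,
                          missing_as_discordant = TRUE) {
  grp <- intersect(c("population_id", "marker_id"), names(calls))
  calls |>
    filter(denom_filter(.data$true_class)) |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(
      n_truth = dplyr::n(),
      n_discordant = sum(
        ifelse(is.na(.data$called_class), missing_as_discordant,
               discordant(.data$called_class))),
      .groups = "drop"
    ) |>
    mutate(rate = ifelse(.data$n_truth > 0,
                         .data$n_discordant / .data$n_truth, NA_real_),
           undefined = .data$n_truth == 0)
}

#' False positive rate of a marker assay
#'
#' The proportion of lines whose truth is recipient-homozygous but whose
#' call is not recipient-homozygous, per marker (and population). Missing
#' calls count as discordant by default (strict).
#'
#' @param calls Long tibble with `marker_id`, `true_class`, `called_class`
#'   (and optionally `population_id`).
#' @param missing_as_discordant Count missing calls in the numerator.
#' @return Tibble with `n_truth`, `n_discordant`, `rate` per marker; groups
#'   with no truth-recipient lines have `rate = NA` and `undefined = TRUE`.
#' @export
false_positive_rate <- function(calls, missing_as_discordant = TRUE) {
  fraction_rate(calls,
                denom_filter = function(t) t == "recipient_hom",
                discordant = function(c) c != "recipient_hom",
                missing_as_discordant)
}

#' False negative rate of a marker assay
#'
#' The proportion of lines whose truth carries the donor (favorable) allele
#' but whose call lacks it.
#'
#' @inheritParams false_positive_rate
#' @return As [false_positive_rate()].
#' @export
false_negative_rate <- function(calls, missing_as_discordant = TRUE) {
  fraction_rate(calls,
                denom_filter = function(t) t %in% c("het", "donor_hom"),
                discordant = function(c) !c %in% c("het", "donor_hom"),
                missing_as_discordant)
}

#' Marker utility across recipient backgrounds
#'
#' The set of recipient backgrounds against which a marker distinguishes
#' the donor allele (donor homozygous for an allele, recipient homozygous
#' for the other), computed from parental genotype calls.
#'
#' @param parents Parental variant table.
#' @param donor_id Donor sample id.
#' @param recipient_ids Recipient sample ids.
#' @return Tibble `marker_id`, `utility_set`, `n_utility` for every site
#'   where the donor call is homozygous (markers with empty utility have
#'   `n_utility = 0`).
#' @export
kasp_utility <- function(parents, donor_id, recipient_ids) {
  cand <- find_donor_specific(parents, donor_id, recipient_ids)
  all_hom <- parents[parents[[donor_id]] %in% c("0/0", "1/1"), ]
  tibble(marker_id = paste0("K_", all_hom$position_bp)) |>
    left_join(select(cand, "marker_id", "utility_set", "n_utility"),
              by = "marker_id") |>
    mutate(utility_set = dplyr::coalesce(.data$utility_set, ""),
           n_utility = dplyr::coalesce(.data$n_utility, 0L))
}

#' Kruskal-Wallis allelic-effect test per marker
#'
#' Rank test of the phenotype across allele classes (negative and positive
#' homozygote classes by default; heterozygotes can be included as a third
#' group). H uses the tie-corrected statistic and p the chi-square
#' approximation with k-1 degrees of freedom; the significance symbol uses
#' the printed tiers (see [significance_tier()]).
#'
#' @param calls Long call tibble (as in [allele_class_summary()]).
#' @param phenotypes Phenotype tibble, long by depth.
#' @param trait Phenotype column to test.
#' @param depth Sowing depth (default 10).
#' @param include_het Include heterozygotes as a third group.
#' @return Tibble with `kw_H`, `kw_p`, `significance` per marker (x
#'   population); groups with fewer than two non-empty classes or constant
#'   phenotype give `H = 0`, `p = 1`.
#' @export
kruskal_wallis_effect <- function(calls, phenotypes,
                                  trait = "germination_pct", depth = 10,
                                  include_het = FALSE) {
  keep <- c("recipient_hom", "donor_hom", if (include_het) "het")
  grp <- intersect(c("population_id", "marker_id"), names(calls))
  ph <- filter(phenotypes, .data$depth_cm == depth)
  dat <- calls |>
    filter(.data$called_class %in% keep) |>
    left_join(ph, by = intersect(c("population_id", "progeny_id"),
                                 intersect(names(calls), names(ph)))) |>
    filter(!is.na(.data[[trait]]))
  dat |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(.kw = list({
      y <- .data[[trait]]
      g <- factor(.data$called_class)
      if (nlevels(droplevels(g)) < 2 || length(unique(y)) < 2) {
        list(H = 0, p = 1)
      } else {
        k <- kruskal.test(y, droplevels(g))
        list(H = unname(k$statistic), p = k$p.value)
      }
    }), .groups = "drop") |>
    mutate(kw_H = purrr::map_dbl(.data$.kw, "H"),
           kw_p = purrr::map_dbl(.data$.kw, "p"),
           significance = significance_tier(.data$kw_p)) |>
    select(-".kw")
}

#' Single-marker regression analysis
#'
#' Least-squares regression of the phenotype on the additive genotype
#' coding (recipient-hom 0, het 1, donor-hom 2). `r2` is the explained
#' sum-of-squares fraction and `smr_p` the F-test p value with (1, n-2)
#' degrees of freedom.
#'
#' @inheritParams kruskal_wallis_effect
#' @return Tibble with `r2`, `smr_p`, `n_used` per marker (x population).
#' @export
single_marker_analysis <- function(calls, phenotypes,
                                   trait = "germination_pct", depth = 10) {
  grp <- intersect(c("population_id", "marker_id"), names(calls))
  ph <- filter(phenotypes, .data$depth_cm == depth)
  dat <- calls |>
    mutate(dosage = class_to_dosage(.data$called_class)) |>
    filter(!is.na(.data$dosage)) |>
    left_join(ph, by = intersect(c("population_id", "progeny_id"),
                                 intersect(names(calls), names(ph)))) |>
    filter(!is.na(.data[[trait]]))
  dat |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(.fit = list({
      y <- .data[[trait]]
      x <- .data$dosage
      if (length(unique(x)) < 2 || length(y) < 3) {
        list(r2 = NA_real_, p = NA_real_, n = length(y))
      } else {
        f <- lm(y ~ x)
        s <- suppressWarnings(summary(f))  # perfect fits handled below
        pv <- if (s$sigma == 0) 0 else
          pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
             lower.tail = FALSE)
        list(r2 = unname(s$r.squared), p = unname(pv), n = length(y))
      }
    }), .groups = "drop") |>
    mutate(r2 = purrr::map_dbl(.data$.fit, "r2"),
           smr_p = purrr::map_dbl(.data$.fit, "p"),
           n_used = purrr::map_int(.data$.fit, ~ as.integer(.x$n))) |>
    select(-".fit")
}

#' One-way ANOVA for a completely randomized design, with CV%
#'
#' Fits `y ~ genotype` (the CRD model: observation = general mean +
#' treatment effect + error) on replicate-level observations and reports
#' the ANOVA table plus the coefficient of variation
#' `CV% = 100 sqrt(MSE) / grand mean`. Genotypes with fewer than two
#' replicates are dropped with a warning.
#'
#' @param data Tibble of replicate observations.
#' @param response Response column name.
#' @param genotype Grouping column name.
#' @return Object of class `crd_anova`: list with `table` (term, df, sumsq,
#'   meansq, statistic, p.value), `cv_pct`, `grand_mean`, `n_dropped`.
#' @export
anova_crd <- function(data, response, genotype) {
  data <- as_tibble(data)
  counts <- table(data[[genotype]])
  drop_geno <- names(counts)[counts < 2]
  if (length(drop_geno)) {
    warn(sprintf("anova_crd: dropped %d genotype(s) with a single replicate",
                 length(drop_geno)))
    data <- data[!data[[genotype]] %in% drop_geno, ]
  }
  if (length(unique(data[[genotype]])) < 2) {
    stop_kaspanel("anova_crd needs at least two genotypes with replicates",
                  "kaspanel_validation_error")
  }
  y <- data[[response]]
  g <- factor(data[[genotype]])
  fit <- aov(y ~ g)
  an <- suppressWarnings(as.data.frame(anova(fit)))
  mse <- an["Residuals", "Mean Sq"]
  fstat <- an[1, "F value"]
  pval <- an[1, "Pr(>F)"]
  if (an[1, "Sum Sq"] < 1e-12 && mse < 1e-12) { fstat <- 0; pval <- 1 }
  tab <- tibble(
    term = c("genotype", "residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = c(fstat, NA_real_), p.value = c(pval, NA_real_)
  )
  structure(list(
    table = tab,
    grand_mean = mean(y),
    cv_pct = 100 * sqrt(mse) / mean(y),
    mse_zero = mse < 1e-12,
    n_dropped = length(drop_geno)
  ), class = "crd_anova")
}

#' @export
print.crd_anova <- function(x, ...) {
  cat("CRD one-way ANOVA\n")
  print(x$table)
  cat(sprintf("grand mean %.4g, CV%% %.3g%s\n", x$grand_mean, x$cv_pct,
              if (x$mse_zero) " (MSE = 0: F undefined/infinite)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crd_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.crd_anova <- function(x, ...) {
  tibble(grand_mean = x$grand_mean, cv_pct = x$cv_pct,
         statistic = x$table$statistic[1], p.value = x$table$p.value[1],
         n_dropped = x$n_dropped)
}

#' Assemble the full per-marker QC table
#'
#' Combines class summaries, FPR/FNR (when a truth channel is present),
#' Kruskal-Wallis allelic effects on the requested traits and the
#' single-marker regression into one record per marker and population
#' class — the layout of the published 54-marker QC table.
#'
#' @param calls Long call tibble with `marker_id`, `progeny_id`,
#'   `called_class`, optionally `true_class` and `population_id`.
#' @param phenotypes Phenotype tibble (long by depth).
#' @param utility Optional utility tibble from [kasp_utility()].
#' @param depth Depth for phenotypic class means and tests (default 10).
#' @param traits Traits to summarise; the first is used for the tests.
#' @param missing_as_discordant Passed to the FPR/FNR estimators.
#' @return A `marker_qc` tibble.
#' @export
marker_qc_table <- function(calls, phenotypes, utility = NULL, depth = 10,
                            traits = c("germination_pct", "mesocotyl_cm"),
                            missing_as_discordant = TRUE) {
  grp <- intersect(c("population_id", "marker_id"), names(calls))
  out <- allele_class_summary(calls, phenotypes, traits, depth)
  if ("true_class" %in% names(calls)) {
    out <- out |>
      left_join(rename(false_positive_rate(calls, missing_as_discordant),
                       fpr = "rate", fpr_undefined = "undefined") |>
                  select(dplyr::all_of(grp), "fpr", "fpr_undefined"),
                by = grp) |>
      left_join(rename(false_negative_rate(calls, missing_as_discordant),
                       fnr = "rate", fnr_undefined = "undefined") |>
                  select(dplyr::all_of(grp), "fnr", "fnr_undefined"),
                by = grp)
  }
  out <- out |>
    left_join(kruskal_wallis_effect(calls, phenotypes, traits[1], depth),
              by = grp) |>
    left_join(single_marker_analysis(calls, phenotypes, traits[1], depth),
              by = grp)
  if (!is.null(utility)) {
    out <- left_join(out, utility, by = "marker_id")
  }
  class(out) <- c("marker_qc", class(out))
  out
}
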