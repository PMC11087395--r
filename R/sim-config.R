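#' Simulation configuration for synthetic breeding populations
#'
#' Bundles every knob of the synthetic-data generator: the master seed, a
#' miniature genome (chromosome lengths and a proportionally scaled QTL
#' window registry), the parental panel (5 donors, 6 recipients), planted
#' candidate-SNP density, per-region phenotypic effects, assay error rates,
#' and the population specifications (seven F3:F4 families totalling 256
#' progeny and eight BC3F2:3 families totalling 713 progeny, mirroring the
#' validation material).
#'
#' All downstream generators draw their randomness from `seed` through named
#' substreams, so a fixed configuration is fully reproducible.
#'
#' @param seed Master seed (integer).
#' @param chromosome_lengths Named integer vector of chromosome lengths in
#'   bp. The default is a 1:100 miniature of the four rice chromosomes that
#'   carry the QTL windows.
#' @param qtl_regions Region registry used by the simulation; defaults to
#'   [sim_qtl_regions()], the published windows scaled to the miniature
#'   genome.
#' @param donors,recipients Parental sample ids.
#' @param gc GC fraction of the generated reference (default 0.44).
#' @param snp_density Background SNPs per Mb outside planted candidates.
#' @param candidates_per_region Donor-specific candidate loci planted per
#'   QTL window.
#' @param population_specs Tibble from [default_population_specs()].
#' @param qtl_effects Tibble from [default_qtl_effects()].
#' @param error_rates List with `false_positive`, `false_negative`,
#'   `missing` assay error rates (fractions in \[0, 1\]).
#' @param phenotype Baseline phenotype parameters, see
#'   [default_phenotype_params()].
#' @param replicates Germination replicates per progeny and depth (2 or 3).
#' @param seeds_per_replicate Seeds sown per replicate tray (default 6).
#' @param parental_het_rate,parental_missing_rate Rates of heterozygous and
#'   missing parental calls injected at background SNPs.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosome_lengths = c(
                                "3" = 400000L, "4" = 250000L,
                                "7" = 280000L, "8" = 220000L),
                              qtl_regions = sim_qtl_regions(),
                              donors = c("N22", "Aus344", "KulaKaruppan",
                                         "NCS237", "IRGC128442"),
                              recipients = c("PR121", "PR126", "PR128",
                                             "PR129", "PB1509", "MTU1010"),
                              gc = 0.44,
                              snp_density = 60,
                              candidates_per_region = 6L,
                              population_specs = default_population_specs(),
                              qtl_effects = default_qtl_effects(),
                              error_rates = list(false_positive = 0,
                                                 false_negative = 0,
                                                 missing = 0),
                              phenotype = default_phenotype_params(),
                              replicates = 3L,
                              seeds_per_replicate = 6L,
                              parental_het_rate = 0.02,
                              parental_missing_rate = 0.02) {
  rates <- unlist(error_rates)
  if (any(rates < 0 | rates > 1)) {
    stop_kaspanel("error rates must lie in [0, 1]", "kaspanel_config_error")
  }
  if (error_rates$false_positive + error_rates$missing > 1 ||
      error_rates$false_negative + error_rates$missing > 1) {
    stop_kaspanel("error rates for a truth class sum to more than 1",
                  "kaspanel_config_error")
  }
  if (any(population_specs$n_progeny <= 0)) {
    stop_kaspanel("n_progeny must be positive", "kaspanel_config_error")
  }
  if (!replicates %in% c(2L, 3L)) {
    stop_kaspanel("replicates must be 2 or 3", "kaspanel_config_error")
  }
  if (any(chromosome_lengths <= 0)) {
    stop_kaspanel("chromosome lengths must be positive",
                  "kaspanel_config_error")
  }
  structure(list(
    seed = as.integer(seed),
    chromosome_lengths = chromosome_lengths,
    qtl_regions = qtl_regions,
    donors = donors, recipients = recipients,
    gc = gc, snp_density = snp_density,
    candidates_per_region = as.integer(candidates_per_region),
    population_specs = population_specs,
    qtl_effects = qtl_effects,
    error_rates = error_rates,
    phenotype = phenotype,
    replicates = as.integer(replicates),
    seeds_per_replicate = as.integer(seeds_per_replicate),
    parental_het_rate = parental_het_rate,
    parental_missing_rate = parental_missing_rate
  ), class = "sim_config")
}

#' Miniature QTL registry for the synthetic genome
#'
#' The published QTL windows divided by `scale` (default 100), so the
#' simulated chromosomes stay around a few hundred kb while keeping the
#' windows' relative layout.
#'
#' @param scale Divisor applied to the published coordinates.
#' @return A region tibble (see [qtl_regions()]).
#' @export
sim_qtl_regions <- function(scale = 100) {
  full <- default_qtl_regions()
  qtl_regions(mutate(full,
                     start_bp = as.integer(round(.data$start_bp / scale)),
                     end_bp = as.integer(round(.data$end_bp / scale))))
}

#' Default population specifications
#'
#' Seven F3:F4 biparental families (256 progeny in total) and eight BC3F2:3
#' backcross families (713 progeny), each with its donor, recipient and the
#' QTL region targeted by foreground selection in the backcrosses.
#'
#' @return A tibble with columns `population_id`, `cross_type`, `donor`,
#'   `recipient`, `n_progeny`, `target_region`.
#' @export
default_population_specs <- function() {
  tibble::tribble(
    ~population_id, ~cross_type, ~donor, ~recipient, ~n_progeny, ~target_region,
    "PR121/N22", "F3:F4", "N22", "PR121", 37L, "qSD3.1",
    "PR126/N22", "F3:F4", "N22", "PR126", 37L, "qSD3.1",
    "PR128/N22", "F3:F4", "N22", "PR128", 37L, "qSD3.1",
    "PB1509/N22", "F3:F4", "N22", "PB1509", 37L, "qSD3.1",
    "PR121/Aus344", "F3:F4", "Aus344", "PR121", 36L, "qSD7.1",
    "PR129/Aus344", "F3:F4", "Aus344", "PR129", 36L, "qSD7.1",
    "PR128/IRGC128442", "F3:F4", "IRGC128442", "PR128", 36L, "qSD8.1",
    "N22/4*PR121", "BC3F2:3", "N22", "PR121", 90L, "qSD3.1",
    "N22/4*PR126", "BC3F2:3", "N22", "PR126", 90L, "qSD3.1",
    "N22/4*PR128", "BC3F2:3", "N22", "PR128", 89L, "qSD3.1",
    "N22/4*PB1509", "BC3F2:3", "N22", "PB1509", 89L, "qSD3.1",
    "Aus344/4*PR121", "BC3F2:3", "Aus344", "PR121", 89L, "qSD7.1",
    "Aus344/4*PR129", "BC3F2:3", "Aus344", "PR129", 89L, "qSD7.1",
    "IRGC128442/4*PR126", "BC3F2:3", "IRGC128442", "PR126", 89L, "qSD8.1",
    "IRGC128442/4*PR128", "BC3F2:3", "IRGC128442", "PR128", 88L, "qSD8.1"
  )
}

#' Default per-region phenotypic effects of the donor allele
#'
#' Effects are expressed as the donor-homozygote minus recipient-homozygote
#' difference; heterozygotes receive half (additive model). Germination
#' effects are on the logit scale of per-seed emergence probability; length
#' effects are in cm. Each donor contributes one major-effect region (the
#' region its crosses target); the remaining windows carry markers but no
#' phenotypic effect. The defaults are calibrated so that at 10 cm sowing
#' depth donor-homozygous progeny average about 70% germination and 4.8 cm
#' mesocotyl against about 22% and 1.1 cm for recipient homozygotes — inside
#' the ranges reported for the validation populations.
#'
#' @return A tibble with columns `region_id`, `donor`, `germ_logit_4`,
#'   `germ_logit_10`, `ml_cm_4`, `ml_cm_10`, `root_cm_10`, `total_cm_10`.
#' @export
default_qtl_effects <- function() {
  tibble::tribble(
    ~region_id, ~donor, ~germ_logit_4, ~germ_logit_10, ~ml_cm_4, ~ml_cm_10,
    ~root_cm_10, ~total_cm_10,
    "qSD3.1", "N22", 0.4, 2.1, 1.0, 3.7, 0.5, 2.5,
    "qSD3.2", "N22", 0, 0, 0, 0, 0, 0,
    "qSD4.1", "Aus344", 0, 0, 0, 0, 0, 0,
    "qSD7.1", "Aus344", 0.4, 2.1, 1.0, 3.7, 0.5, 2.5,
    "qSD7.2", "IRGC128442", 0, 0, 0, 0, 0, 0,
    "qSD8.1", "IRGC128442", 0.4, 2.1, 1.0, 3.7, 0.5, 2.5
  )
}

#' Default phenotype baselines
#'
#' Baselines describe the recipient-homozygote class. Germination baselines
#' are emergence probabilities per seed; lengths are class means in cm with
#' Gaussian progeny-level noise (`*_sd`), truncated at zero.
#'
#' @return A named list.
#' @export
default_phenotype_params <- function() {
  list(
    germ_p_4 = 0.44, germ_p_10 = 0.22,
    ml_4 = 1.8, ml_sd_4 = 0.25,
    ml_10 = 1.1, ml_sd_10 = 0.45,
    root_4 = 4.5, root_sd_4 = 1.2,
    root_10 = 3.2, root_sd_10 = 1.0,
    total_4 = 22, total_sd_4 = 4,
    total_10 = 19, total_sd_10 = 4
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genome:", paste0(names(x$chromosome_lengths), ":",
                          x$chromosome_lengths, collapse = " "), "\n")
  cat("  parents:", length(x$donors), "donors,",
      length(x$recipients), "recipients\n")
  cat("  populations:", nrow(x$population_specs), "(",
      sum(x$population_specs$n_progeny), "progeny )\n")
  cat("  error rates: fp", x$error_rates$false_positive,
      "fn", x$error_rates$false_negative,
      "missing", x$error_rates$missing, "\n")
  invisible(x)
}
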