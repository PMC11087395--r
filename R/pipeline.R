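# End-to-end drivers: dataset simulation, the screen -> design -> call ->
# QC -> select pipeline, and the fixture report recomputing the published
# panel summaries.

#' Simulate a complete synthetic dataset to disk
#'
#' Writes the reference FASTA, the 11-parent VCF, genotype truth + calls
#' and phenotype CSVs, and a JSON metadata sidecar recording the
#' configuration, seed and file checksums. Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  reference <- generate_reference(config)
  parents <- generate_parents(config, reference)
  progeny <- simulate_populations(config, parents)
  phenotypes <- simulate_phenotypes(progeny, config)
  calls <- inject_assay_error(progeny, config$error_rates,
                              seed = sub_seed(config$seed, "calls"))
  paths <- list(
    reference = file.path(outdir, "reference.fasta"),
    parents_vcf = file.path(outdir, "parents.vcf"),
    truth = file.path(outdir, "candidate_truth.csv"),
    genotypes = file.path(outdir, "genotypes.csv"),
    phenotypes = file.path(outdir, "phenotypes.csv"),
    metadata = file.path(outdir, "metadata.json")
  )
  write_reference(reference, paths$reference)
  write_vcf(parents, paths$parents_vcf)
  readr::write_csv(attr(parents, "truth"), paths$truth)
  readr::write_csv(calls, paths$genotypes)
  readr::write_csv(phenotypes, paths$phenotypes)
  meta <- list(
    package = "kaspanel",
    version = as.character(utils::packageVersion("kaspanel")),
    seed = config$seed,
    config = config[setdiff(names(config), c("qtl_regions",
                                             "population_specs",
                                             "qtl_effects"))],
    qtl_regions = config$qtl_regions,
    population_specs = config$population_specs,
    qtl_effects = config$qtl_effects,
    md5 = lapply(paths[setdiff(names(paths), "metadata")],
                 function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Run the full marker-panel pipeline on synthetic data
#'
#' Executes candidate screening (quality filter, QTL-window extraction,
#' donor-specificity), assay design with specificity rejection, population
#' simulation with assay-error injection, per-marker QC against the
#' simulation truth, and core-panel selection. Returns all intermediate
#' products plus a stage funnel with non-increasing marker counts.
#'
#' @param config A [simulation_config()].
#' @param criteria [panel_criteria()] for the core-panel step.
#' @param design [design_params()].
#' @return A list with `reference`, `parents`, `candidates`, `assays`,
#'   `calls`, `phenotypes`, `qc`, `panel`, `favorable`, `funnel`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         criteria = panel_criteria(max_fpr = 0.25,
                                                   max_fnr = 0.12,
                                                   min_utility = 3L,
                                                   require_significance = "*"),
                         design = design_params()) {
  reference <- generate_reference(config)
  parents <- generate_parents(config, reference)

  filtered <- filter_variants(parents)
  windowed <- extract_region_variants(filtered, config$qtl_regions)
  donors_of <- unique(config$qtl_effects$donor)
  crossing <- attr(parents, "crossing_recipients")
  candidates <- purrr::map_dfr(donors_of, function(d) {
    # screen each donor against its own windows: a locus planted for one
    # donor can look "donor-specific" for another with an inverted utility
    # set, which is not a usable introgression marker
    own <- config$qtl_effects$region_id[config$qtl_effects$donor == d]
    find_donor_specific(windowed, d, crossing) |>
      filter(.data$region_id %in% own)
  }) |>
    distinct(.data$marker_id, .keep_all = TRUE) |>
    arrange(.data$chromosome, .data$position_bp)

  assays <- design_assays(candidates, reference, design)

  progeny <- simulate_populations(config, parents)
  phenotypes <- simulate_phenotypes(progeny, config)
  calls <- inject_assay_error(progeny, config$error_rates,
                              seed = sub_seed(config$seed, "calls"))
  calls <- left_join(calls,
                     select(config$population_specs, "population_id",
                            "cross_type"),
                     by = "population_id")

  # each marker is validated on the populations that introgress its donor's
  # material: a population contributes to a marker's QC only if its donor
  # owns the marker's window
  region_donor <- select(config$qtl_effects, "region_id", "donor")
  by_class <- calls |>
    left_join(select(config$population_specs, "population_id", "donor"),
              by = "population_id") |>
    left_join(region_donor, by = "region_id", suffix = c("", ".region")) |>
    filter(.data$donor == .data$donor.region) |>
    mutate(population_id = .data$cross_type) |>
    select(-"cross_type", -"donor", -"donor.region")
  qc <- marker_qc_table(by_class,
                        select(phenotypes, -"population_id"),
                        utility = select(candidates, "marker_id",
                                         "utility_set", "n_utility"))
  qc <- left_join(qc, select(candidates, "marker_id", "region_id"),
                  by = "marker_id")

  # selection considers accepted assays only and uses the worst (max)
  # error rate across population classes
  accepted_ids <- assays$marker_id[assays$status == "accepted"]
  qc_marker <- qc |>
    filter(.data$marker_id %in% accepted_ids) |>
    group_by(.data$marker_id) |>
    summarise(
      n_utility = .data$n_utility[1],
      region_id = .data$region_id[1],
      fpr = max(.data$fpr, na.rm = TRUE),
      fnr = max(.data$fnr, na.rm = TRUE),
      kw_p = min(.data$kw_p, na.rm = TRUE),
      significance = .data$significance[which.min(.data$kw_p)],
      .groups = "drop")
  panel <- select_core_panel(qc_marker, criteria)
  favorable <- favorable_allele_matrix(calls)

  segregating <- calls |>
    group_by(.data$marker_id) |>
    summarise(poly = dplyr::n_distinct(.data$true_class) > 1,
              .groups = "drop")
  funnel <- tibble(
    stage = c("candidates", "designed", "accepted", "polymorphic_in_progeny",
              "validated", "selected"),
    n_markers = c(
      nrow(candidates),
      sum(assays$status != "rejected_design"),
      sum(assays$status == "accepted"),
      sum(assays$status == "accepted" &
            assays$marker_id %in% segregating$marker_id[segregating$poly]),
      sum(assays$status == "accepted" &
            assays$marker_id %in% segregating$marker_id[segregating$poly] &
            assays$marker_id %in% qc$marker_id),
      sum(panel$panel$marker_id %in%
            assays$marker_id[assays$status == "accepted"] &
          panel$panel$marker_id %in%
            segregating$marker_id[segregating$poly])
    )
  )
  list(reference = reference, parents = parents, candidates = candidates,
       assays = assays, calls = calls, phenotypes = phenotypes, qc = qc,
       panel = panel, favorable = favorable, funnel = funnel)
}

#' Recompute the published panel summaries from the packaged fixture
#'
#' From the packaged 54-marker transcription and the QTL registry,
#' recomputes the per-chromosome assay counts, the utility histogram, the
#' chromosome distribution of the published 12-marker core panel, the
#' allele-class frequency percentages, the window spacing summaries that
#' are recoverable from the marker positions, and the kb -> cM conversion
#' table, and compares them with the printed values.
#'
#' @return Object of class `fixture_report`: list with `checks` (name,
#'   expected, computed, pass), `frequency_deviation` (max |printed -
#'   recomputed| over unflagged fields), `cm_table`, `spacing`.
#' @export
fixture_report <- function() {
  tab <- load_table3()
  registry <- default_qtl_regions()
  asg <- assign_regions(tab, registry)
  cc <- setNames(asg$chromosome_counts$n_markers,
                 asg$chromosome_counts$chromosome)
  uh <- utility_histogram(tab)
  uhv <- setNames(uh$n_markers, uh$n_utility)
  panel_tab <- tab[tab$marker_id %in% core_panel_ids(), ]
  pc <- table(panel_tab$chromosome)
  flagged <- grepl("imply|gives", tab$provenance)
  dev <- tab |>
    mutate(
      d_na = abs(.data$freq_negative_pct_a -
                   100 * .data$n_negative_a / .data$n_tested_a),
      d_pa = abs(.data$freq_positive_pct_a -
                   100 * .data$n_positive_a / .data$n_tested_a),
      d_nb = abs(.data$freq_negative_pct_b -
                   100 * .data$n_negative_b / .data$n_tested_b),
      d_pb = abs(.data$freq_positive_pct_b -
                   100 * .data$n_positive_b / .data$n_tested_b))
  max_dev <- max(c(dev$d_na[!flagged], dev$d_pa[!flagged],
                   dev$d_nb, dev$d_pb))
  spacing <- spacing_summary(tab, registry)
  cm_table <- check_cm_conversions()
  checks <- tibble::tribble(
    ~check, ~expected, ~computed,
    "assays_chr3", 16, unname(cc["3"]),
    "assays_chr4", 9, unname(cc["4"]),
    "assays_chr7", 23, unname(cc["7"]),
    "assays_chr8", 6, unname(cc["8"]),
    "utility_5_backgrounds", 13, unname(uhv["5"]),
    "utility_4_backgrounds", 15, unname(uhv["4"]),
    "utility_3_backgrounds", 5, unname(uhv["3"]),
    "utility_2_backgrounds", 8, unname(uhv["2"]),
    "utility_1_background", 13, unname(uhv["1"]),
    "panel_size", 12, nrow(panel_tab),
    "panel_chr3", 5, unname(pc["3"]),
    "panel_chr4", 1, unname(pc["4"]),
    "panel_chr7", 3, unname(pc["7"]),
    "panel_chr8", 3, unname(pc["8"]),
    "spacing_qSD3.2_kb", 13.16,
    round(spacing$mean_kb[spacing$region_id == "qSD3.2"], 2),
    "spacing_qSD4.1_kb", 35.17,
    round(spacing$mean_kb[spacing$region_id == "qSD4.1"], 2),
    "max_frequency_deviation_pct", 0.1, round(max_dev, 3)
  ) |>
    mutate(pass = .data$computed <= .data$expected + 1e-9 &
             .data$computed >= .data$expected - 1e-9 |
             (.data$check == "max_frequency_deviation_pct" &
                .data$computed <= .data$expected + 1e-9))
  structure(list(checks = checks, frequency_deviation = max_dev,
                 cm_table = cm_table, spacing = spacing,
                 n_flagged_rows = sum(flagged)),
            class = "fixture_report")
}

#' @export
print.fixture_report <- function(x, ...) {
  cat("Fixture report: recomputed panel summaries\n")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %-28s expected %-8.4g computed %-8.4g\n",
                if (x$checks$pass[i]) "PASS" else "FAIL",
                x$checks$check[i], x$checks$expected[i],
                x$checks$computed[i]))
  }
  bad_cm <- x$cm_table[!x$cm_table$consistent, ]
  if (nrow(bad_cm)) {
    cat(sprintf("  flagged cM conversion(s): %s (printed %.3f, expected %.3f)\n",
                paste(bad_cm$region_id, collapse = ", "),
                bad_cm$printed_cm[1], round(bad_cm$computed_cm[1], 3)))
  }
  cat(sprintf("  %d fixture row(s) carry printed-value inconsistency flags\n",
              x$n_flagged_rows))
  invisible(x)
}
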