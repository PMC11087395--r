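# Pedigree simulation for biparental and backcross populations.
#
# Segregation model: candidate loci within one QTL window cosegregate as a
# single unit (windows are short against recombination distances, and the
# whole marker-QC design presumes markers tag their window's QTL); distinct
# windows segregate independently. Genotypes are recorded at the generation
# the study genotyped: F3:F4 progeny carry the genotype after three selfing
# meioses from the F1 (heterozygosity (1/2)^3), BC3F2:3 progeny the genotype
# of the BC3F2 plant (BC3F1 kept heterozygous at the target window by
# foreground selection, then selfed once).

self_once <- function(class, n = length(class)) {
  out <- class
  het <- which(class == "het")
  if (length(het)) {
    u <- runif(length(het))
    out[het] <- ifelse(u < 0.25, "recipient_hom",
                       ifelse(u < 0.75, "het", "donor_hom"))
  }
  out
}

#' Simulate one breeding population
#'
#' @param spec One row of [default_population_specs()] (data frame or list
#'   with `population_id`, `cross_type`, `donor`, `recipient`, `n_progeny`,
#'   `target_region`).
#' @param parents Parental variant table from [generate_parents()].
#' @param seed Integer seed for this population's draws.
#' @return A long tibble with columns `population_id`, `progeny_id`,
#'   `marker_id`, `region_id`, `true_class`, plus attributes
#'   `region_dosage` (per-progeny dosage of each window's functional
#'   variant) and `segregating` (per-locus status for this cross).
#' @export
simulate_cross <- function(spec, parents, seed) {
  spec <- as.list(as_tibble(spec)[1, ])
  truth <- attr(parents, "truth")
  if (is.null(truth)) {
    stop_kaspanel("parents lack planted-candidate truth; use generate_parents()",
                  "kaspanel_config_error")
  }
  if (!all(c(spec$donor, spec$recipient) %in% variant_samples(parents))) {
    stop_kaspanel("donor or recipient absent from parent table",
                  "kaspanel_config_error")
  }
  loci <- truth |>
    left_join(
      select(parents, "chromosome", "position_bp",
             donor_gt = dplyr::all_of(spec$donor),
             recipient_gt = dplyr::all_of(spec$recipient)),
      by = c("chromosome", "position_bp")
    ) |>
    mutate(
      segregating = .data$donor_gt %in% c("0/0", "1/1") &
        .data$recipient_gt %in% c("0/0", "1/1") &
        .data$donor_gt != .data$recipient_gt,
      fixed_class = dplyr::case_when(
        .data$segregating ~ NA_character_,
        .data$recipient_gt == "1/1" ~ "donor_hom",
        TRUE ~ "recipient_hom"
      )
    )

  n <- spec$n_progeny
  progeny_id <- sprintf("%s_P%03d", spec$population_id, seq_len(n))
  seg_regions <- unique(loci$region_id[loci$segregating])

  unit <- with_sub_seed(seed, paste0("cross/", spec$population_id), {
    purrr::map(setNames(seg_regions, seg_regions), function(r) {
      if (spec$cross_type == "BC3F2:3") {
        if (identical(r, spec$target_region)) {
          g <- rep("het", n)  # foreground selection retains the donor allele
        } else {
          g <- ifelse(runif(n) < (1 / 2)^3, "het", "recipient_hom")
        }
        self_once(g)
      } else if (spec$cross_type == "F3:F4") {
        g <- rep("het", n)
        for (i in 1:3) g <- self_once(g)
        g
      } else {
        stop_kaspanel(paste0("unknown cross type: ", spec$cross_type),
                      "kaspanel_config_error")
      }
    })
  })

  gt <- purrr::map_dfr(seq_len(nrow(loci)), function(j) {
    cls <- if (loci$segregating[j]) unit[[loci$region_id[j]]]
           else rep(loci$fixed_class[j], n)
    tibble(population_id = spec$population_id,
           progeny_id = progeny_id,
           marker_id = loci$marker_id[j],
           region_id = loci$region_id[j],
           true_class = cls)
  })

  fun_loci <- loci[loci$functional, ]
  dosage <- purrr::map_dfr(seq_len(nrow(fun_loci)), function(j) {
    cls <- if (fun_loci$segregating[j]) unit[[fun_loci$region_id[j]]]
           else rep(fun_loci$fixed_class[j], n)
    tibble(population_id = spec$population_id,
           progeny_id = progeny_id,
           region_id = fun_loci$region_id[j],
           dosage = class_to_dosage(cls))
  })

  attr(gt, "region_dosage") <- dosage
  attr(gt, "segregating") <- select(loci, "marker_id", "region_id",
                                    "segregating", "fixed_class")
  gt
}

#' Simulate all configured populations
#'
#' Applies [simulate_cross()] to every row of the configuration's population
#' specs and binds the results, carrying the per-progeny region dosages
#' along.
#'
#' @param config A [simulation_config()].
#' @param parents Parental variant table from [generate_parents()].
#' @return A long genotype tibble as in [simulate_cross()]; the
#'   `region_dosage` attribute covers all populations.
#' @export
simulate_populations <- function(config, parents) {
  specs <- config$population_specs
  pieces <- purrr::map(seq_len(nrow(specs)), function(i) {
    simulate_cross(specs[i, ], parents,
                   seed = sub_seed(config$seed, paste0("pop", i)))
  })
  out <- purrr::list_rbind(pieces)
  attr(out, "region_dosage") <-
    purrr::list_rbind(purrr::map(pieces, attr, "region_dosage"))
  out
}
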