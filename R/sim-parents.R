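#' Generate parental variant profiles
#'
#' Plants donor-specific candidate SNPs inside each QTL window and scatters
#' background SNPs genome-wide, then emits the 11-parent genotype table.
#'
#' Each window belongs to one donor (the donor whose crosses target it, per
#' `config$qtl_effects`). Within a window the first planted locus is the
#' region's functional variant and is polymorphic against all five crossing
#' recipients; the remaining candidates cycle through utility-set sizes so
#' that marker utility varies by design. Recipients outside a locus's
#' utility set carry the donor allele (the locus cannot distinguish the
#' donor there); non-focal donors carry the reference allele. Background
#' SNPs are split between group-differentiating sites (donors + MTU1010
#' versus the elite recipients, echoing the two-cluster structure of the
#' parental panel) and unstructured sites; heterozygous and missing parental
#' calls are injected at background sites only, so the planted candidate
#' truth stays exact.
#'
#' @param config A [simulation_config()].
#' @param reference Reference genome from [generate_reference()].
#' @return A variant table (see [read_vcf()]) with attributes `truth` (the
#'   planted candidate tibble: `marker_id`, `chromosome`, `position_bp`,
#'   `ref_allele`, `donor_allele`, `donor`, `utility_set`, `region_id`,
#'   `functional`) and `crossing_recipients`.
#' @export
generate_parents <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  regions <- config$qtl_regions
  effects <- config$qtl_effects
  samples <- c(config$donors, config$recipients)
  crossing <- intersect(config$recipients,
                        unique(config$population_specs$recipient))
  bases <- c("A", "C", "G", "T")

  if (config$candidates_per_region == 0L) {
    warn("generate_parents: no candidate loci requested inside the QTL windows; no donor-specific candidates are possible")
  }
  with_sub_seed(config$seed, "parents", {
    # --- planted donor-specific candidates ------------------------------
    cand <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      reg <- regions[i, ]
      donor <- effects$donor[match(reg$region_id, effects$region_id)]
      k <- config$candidates_per_region
      width <- reg$end_bp - reg$start_bp + 1L
      if (width < k * 2L) {
        warn(paste0("window ", reg$region_id, " too narrow for ", k,
                    " candidates"))
      }
      pos <- sort(sample(seq(reg$start_bp, reg$end_bp), k))
      sizes <- rep(c(length(crossing), 4L, 3L, 2L, 1L), length.out = k)
      sizes[1L] <- length(crossing)  # functional variant: full utility
      util <- purrr::map2(sizes, seq_len(k), function(s, j) {
        off <- j %% length(crossing)
        rot <- if (off > 0) c(crossing[-seq_len(off)], crossing[seq_len(off)])
               else crossing
        sort(rot[seq_len(s)])
      })
      tibble(
        region_id = reg$region_id, chromosome = reg$chromosome,
        position_bp = pos, donor = donor,
        utility_set = purrr::map_chr(util, join_set),
        functional = seq_len(k) == 1L
      )
    })
    cand$ref_allele <- purrr::map2_chr(cand$chromosome, cand$position_bp,
                                       ~ reference_base(reference, .x, .y))
    cand$donor_allele <- purrr::map_chr(cand$ref_allele,
                                        ~ sample(setdiff(bases, .x), 1L))
    cand$marker_id <- paste0("K_", cand$position_bp)

    gt_cand <- matrix("0/0", nrow = nrow(cand), ncol = length(samples),
                      dimnames = list(NULL, samples))
    for (r in seq_len(nrow(cand))) {
      util <- split_set(cand$utility_set[r])[[1]]
      gt_cand[r, cand$donor[r]] <- "1/1"
      others <- setdiff(crossing, util)
      if (length(others)) gt_cand[r, others] <- "1/1"
      extra <- setdiff(config$recipients, crossing)
      if (length(extra)) {
        gt_cand[r, extra] <- sample(c("0/0", "1/1"), length(extra),
                                    replace = TRUE, prob = c(0.7, 0.3))
      }
    }

    # --- background SNPs -------------------------------------------------
    bg <- purrr::map_dfr(names(config$chromosome_lengths), function(chr) {
      len <- config$chromosome_lengths[[chr]]
      n <- max(0L, round(config$snp_density * len / 1e6))
      if (n == 0L) return(tibble())
      # keep background variants outside the QTL windows so the planted
      # candidates are the exact in-window truth
      avail <- seq_len(len)
      for (i in seq_len(nrow(regions))) {
        if (regions$chromosome[i] == chr) {
          avail <- avail[avail < regions$start_bp[i] |
                           avail > regions$end_bp[i]]
        }
      }
      n <- min(n, length(avail))
      pos <- sort(sample(avail, n))
      tibble(chromosome = chr, position_bp = pos)
    })
    if (nrow(bg)) {
      bg$ref_allele <- purrr::map2_chr(bg$chromosome, bg$position_bp,
                                       ~ reference_base(reference, .x, .y))
      bg$donor_allele <- purrr::map_chr(bg$ref_allele,
                                        ~ sample(setdiff(bases, .x), 1L))
      grp_like <- c(config$donors, setdiff(config$recipients, crossing))
      gt_bg <- matrix("0/0", nrow = nrow(bg), ncol = length(samples),
                      dimnames = list(NULL, samples))
      structured <- runif(nrow(bg)) < 0.6
      for (r in seq_len(nrow(bg))) {
        if (structured[r]) {
          carriers <- grp_like
          flip <- samples[runif(length(samples)) < 0.05]
          carriers <- union(setdiff(carriers, flip),
                            setdiff(flip, carriers))
        } else {
          p <- runif(1, 0.1, 0.9)
          carriers <- samples[runif(length(samples)) < p]
        }
        if (length(carriers)) gt_bg[r, carriers] <- "1/1"
      }
      het <- matrix(runif(length(gt_bg)) < config$parental_het_rate,
                    nrow = nrow(bg))
      gt_bg[het] <- "0/1"
      miss <- matrix(runif(length(gt_bg)) < config$parental_missing_rate,
                     nrow = nrow(bg))
      gt_bg[miss] <- NA_character_
    }

    tab <- bind_rows(
      bind_cols(select(cand, "chromosome", "position_bp", "ref_allele",
                       alt_allele = "donor_allele"),
                as_tibble(gt_cand)),
      if (nrow(bg)) bind_cols(select(bg, "chromosome", "position_bp",
                                     "ref_allele",
                                     alt_allele = "donor_allele"),
                              as_tibble(gt_bg))
    ) |>
      arrange(.data$chromosome, .data$position_bp)
    validate_variant_table(tab)
    attr(tab, "truth") <- select(cand, "marker_id", "chromosome",
                                 "position_bp", "ref_allele", "donor_allele",
                                 "donor", "utility_set", "region_id",
                                 "functional")
    attr(tab, "crossing_recipients") <- crossing
    tab
  })
}
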