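# Candidate-SNP triage: merge parental variant sets, apply the published
# quality filters (MAF > 2%, call rate >= 80%), restrict to QTL windows and
# screen for donor specificity.

#' Merge variant tables
#'
#' Takes the union of sites across tables; samples absent at a site are
#' missing. A conflicting reference allele at a shared position is an error;
#' records whose alternate allele conflicts at a shared position are dropped
#' with a logged count (only biallelic records are carried).
#'
#' @param tables List of variant tables.
#' @return A merged variant table.
#' @export
merge_variant_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  purrr::walk(tables, validate_variant_table)
  all_samples <- unlist(purrr::map(tables, variant_samples))
  if (anyDuplicated(all_samples)) {
    stop_kaspanel(paste0("sample id collision: ",
                         join_set(all_samples[duplicated(all_samples)])),
                  "kaspanel_validation_error")
  }
  if (length(tables) == 1) return(tables[[1]])
  purrr::reduce(tables, merge_pair)
}

merge_pair <- function(a, b) {
  key <- c("chromosome", "position_bp")
  shared <- inner_join(select(a, dplyr::all_of(key), ref_a = "ref_allele",
                              alt_a = "alt_allele"),
                       select(b, dplyr::all_of(key), ref_b = "ref_allele",
                              alt_b = "alt_allele"),
                       by = key)
  ref_conflict <- shared[shared$ref_a != shared$ref_b, ]
  if (nrow(ref_conflict)) {
    stop_kaspanel(paste0("conflicting reference allele at: ",
                         paste(ref_conflict$chromosome,
                               ref_conflict$position_bp,
                               sep = ":", collapse = ", ")),
                  "kaspanel_validation_error")
  }
  alt_conflict <- shared[shared$alt_a != shared$alt_b, key]
  if (nrow(alt_conflict)) {
    inform(sprintf("merge_variant_tables: dropped %d site(s) with conflicting alternate alleles",
                   nrow(alt_conflict)))
    a <- anti_join(a, alt_conflict, by = key)
    b <- anti_join(b, alt_conflict, by = key)
  }
  out <- full_join(a, b, by = c(key, "ref_allele", "alt_allele"))
  out <- arrange(out, .data$chromosome, .data$position_bp)
  validate_variant_table(out)
  out
}

#' Filter variants by minor allele frequency and call rate
#'
#' Retains sites whose MAF strictly exceeds `maf_min` ("exceeding 2%") and
#' whose per-site call rate is at least `call_rate_min` ("retaining at least
#' 80% of the data", read as a per-site rate across samples). MAF counts
#' diploid alleles over all called samples. Removal counts by reason are
#' attached as the `filter_log` attribute.
#'
#' @param table A variant table.
#' @param maf_min Strict lower bound on MAF (default 0.02).
#' @param call_rate_min Call-rate threshold (default 0.80).
#' @return The filtered variant table.
#' @export
filter_variants <- function(table, maf_min = 0.02, call_rate_min = 0.80) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0,
            call_rate_min <= 1)
  validate_variant_table(table)
  if (nrow(table) == 0) {
    warn("filter_variants: empty variant table")
    attr(table, "filter_log") <- c(maf = 0L, call_rate = 0L)
    return(table)
  }
  samples <- variant_samples(table)
  gt <- as.matrix(table[samples])
  called <- !is.na(gt)
  call_rate <- rowMeans(called)
  alt_count <- rowSums(matrix(
    c(0, 1, 2)[match(gt, c("0/0", "0/1", "1/1"))],
    nrow = nrow(gt)), na.rm = TRUE)
  n_alleles <- 2 * rowSums(called)
  alt_freq <- ifelse(n_alleles > 0, alt_count / n_alleles, 0)
  maf <- pmin(alt_freq, 1 - alt_freq)
  keep <- maf > maf_min & call_rate >= call_rate_min
  log <- c(maf = sum(!(maf > maf_min)),
           call_rate = sum(maf > maf_min & call_rate < call_rate_min))
  out <- table[keep, ]
  attr(out, "filter_log") <- log
  out
}

#' Restrict variants to QTL windows
#'
#' Keeps sites whose position falls inside a registry window (bounds
#' inclusive) and annotates each with its `region_id`.
#'
#' @param table A variant table.
#' @param registry Region tibble (see [qtl_regions()]).
#' @return The windowed variant table with a `region_id` column.
#' @export
extract_region_variants <- function(table, registry) {
  validate_variant_table(table)
  table$region_id <- region_of(table$chromosome, table$position_bp, registry)
  out <- filter(table, !is.na(.data$region_id))
  relocate(out, "region_id", .after = "alt_allele")
}

#' Identify donor-specific SNPs
#'
#' A site is donor-specific when the donor is homozygous for an allele that
#' differs from a recipient's homozygous genotype. The utility set collects
#' the recipients satisfying that; heterozygous or missing parental calls
#' conservatively exclude a recipient (these are inbred parents, so a het
#' call is treated as unreliable). Sites where the donor itself is
#' heterozygous or missing are skipped with a logged reason; sites with an
#' empty utility set are excluded.
#'
#' @param table A variant table (optionally region-annotated).
#' @param donor_id Donor sample id.
#' @param recipient_ids Recipient sample ids.
#' @return Candidate tibble: `marker_id`, `chromosome`, `position_bp`,
#'   `ref_allele`, `donor_allele`, `donor_id`, `utility_set`, `n_utility`,
#'   `region_id` (NA when the input is not region-annotated). Skip counts
#'   are in the `skip_log` attribute.
#' @export
find_donor_specific <- function(table, donor_id, recipient_ids) {
  validate_variant_table(table)
  samples <- variant_samples(table)
  if (!donor_id %in% samples || !all(recipient_ids %in% samples)) {
    stop_kaspanel("donor or recipient absent from variant table",
                  "kaspanel_validation_error")
  }
  dgt <- table[[donor_id]]
  donor_hom <- dgt %in% c("0/0", "1/1")
  skip_log <- c(donor_het = sum(dgt == "0/1", na.rm = TRUE),
                donor_missing = sum(is.na(dgt)))
  rows <- which(donor_hom)
  rec <- as.matrix(table[recipient_ids])
  util <- purrr::map_chr(rows, function(i) {
    opp <- if (dgt[i] == "1/1") "0/0" else "1/1"
    join_set(recipient_ids[!is.na(rec[i, ]) & rec[i, ] == opp])
  })
  out <- tibble(
    marker_id = paste0("K_", table$position_bp[rows]),
    chromosome = table$chromosome[rows],
    position_bp = table$position_bp[rows],
    ref_allele = table$ref_allele[rows],
    donor_allele = ifelse(dgt[rows] == "1/1",
                          table$alt_allele[rows], table$ref_allele[rows]),
    donor_id = donor_id,
    utility_set = util,
    n_utility = lengths(split_set(util)),
    region_id = if ("region_id" %in% names(table)) table$region_id[rows]
                else NA_character_
  )
  out <- filter(out, .data$n_utility > 0)
  attr(out, "skip_log") <- skip_log
  out
}
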