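#' Read a multi-sample VCF into a variant table
#'
#' Reads a plain-text VCF v4.x (only the GT subfield is required), keeps
#' biallelic SNP records, and maps genotypes to `"0/0"`, `"0/1"`, `"1/1"` or
#' `NA` (missing). Phased separators are normalized to `/` and `1/0` to
#' `0/1`. Non-SNP and multiallelic records are dropped; the counts are
#' attached as the `"dropped"` attribute and reported via a message.
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @return A tibble with columns `chromosome`, `position_bp`, `ref_allele`,
#'   `alt_allele`, followed by one column per sample. Rows are sorted by
#'   chromosome then position.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop_kaspanel(paste0("VCF not found: ", path), "kaspanel_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  validate_vcf_lines(lines)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT %||% "") == 1L &
    !is.na(fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  is_multi <- grepl(",", fix$ALT %||% "")
  dropped <- c(non_snp = sum(!is_snp & !is_multi), multiallelic = sum(is_multi))
  keep <- is_snp & !is_multi
  if (any(!keep)) {
    inform(sprintf("read_vcf: dropped %d non-SNP and %d multiallelic record(s)",
                   dropped[["non_snp"]], dropped[["multiallelic"]]))
  }
  gt <- gt[keep, , drop = FALSE]
  tab <- tibble(
    chromosome = as.character(fix$CHROM[keep]),
    position_bp = as.integer(fix$POS[keep]),
    ref_allele = fix$REF[keep],
    alt_allele = fix$ALT[keep]
  )
  for (s in colnames(gt)) tab[[s]] <- normalize_gt(gt[, s])
  tab <- arrange(tab, .data$chromosome, .data$position_bp)
  validate_variant_table(tab)
  attr(tab, "dropped") <- dropped
  tab
}

validate_vcf_lines <- function(lines) {
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop_kaspanel("malformed VCF header at line 1: missing ##fileformat",
                  "kaspanel_parse_error")
  }
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (!length(header_idx)) {
    stop_kaspanel("malformed VCF: no #CHROM header line",
                  "kaspanel_parse_error")
  }
  body <- seq_along(lines) > header_idx[1] & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 10)) {
    bad <- which(body)[which(nfield < 10)[1]]
    stop_kaspanel(sprintf("malformed VCF record at line %d: %d field(s), expected >= 10",
                          bad, nfield[which(nfield < 10)[1]]),
                  "kaspanel_parse_error")
  }
  invisible(TRUE)
}

normalize_gt <- function(x) {
  x <- unname(sub(":.*$", "", x))
  x <- gsub("|", "/", x, fixed = TRUE)
  x[x %in% c(".", "./.", ".|.")] <- NA_character_
  x[x == "1/0"] <- "0/1"
  ok <- is.na(x) | x %in% c("0/0", "0/1", "1/1")
  x[!ok] <- NA_character_
  x
}

#' Write a variant table to a plain-text VCF v4.2 file
#'
#' @param table A variant table as returned by [read_vcf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(table, path) {
  validate_variant_table(table)
  samples <- variant_samples(table)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=kaspanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt <- as.matrix(table[samples])
  gt[is.na(gt)] <- "./."
  body <- paste(
    table$chromosome, table$position_bp,
    paste0("K_", table$position_bp),
    table$ref_allele, table$alt_allele, ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sample columns of a variant table
#'
#' @param table A variant table.
#' @return Character vector of sample ids.
#' @export
variant_samples <- function(table) {
  setdiff(names(table),
          c("chromosome", "position_bp", "ref_allele", "alt_allele",
            "region_id"))
}

validate_variant_table <- function(table) {
  need <- c("chromosome", "position_bp", "ref_allele", "alt_allele")
  if (!all(need %in% names(table))) {
    stop_kaspanel("variant table lacks required columns",
                  "kaspanel_validation_error")
  }
  samples <- variant_samples(table)
  if (anyDuplicated(samples)) {
    stop_kaspanel("duplicated sample ids in variant table",
                  "kaspanel_validation_error")
  }
  key <- paste(table$chromosome, table$position_bp)
  if (anyDuplicated(key)) {
    stop_kaspanel("duplicated (chromosome, position) in variant table",
                  "kaspanel_validation_error")
  }
  invisible(TRUE)
}
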