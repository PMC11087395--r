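# SNP functional-context classification (intergenic / intron / UTR / CDS)
# and synonymous-versus-missense annotation of coding variants.

#' Read gene models from a GFF3 file
#'
#' Extracts gene, exon, CDS and UTR features into a flat interval tibble
#' (1-based inclusive coordinates).
#'
#' @param path GFF3 path.
#' @return A gene-model tibble: `gene_id`, `chromosome`, `strand`,
#'   `feature`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_kaspanel("rtracklayer is required to read GFF3",
                  "kaspanel_config_error")
  }
  g <- rtracklayer::import(path)
  df <- as.data.frame(g)
  keep <- c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
            "three_prime_UTR")
  df <- df[df$type %in% keep, ]
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1])
           else NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  id <- if ("ID" %in% names(df)) as.character(df$ID) else parent
  gene_id <- ifelse(df$type == "gene", id,
                    sub("\\.\\d+$", "", ifelse(is.na(parent), id, parent)))
  tibble(
    gene_id = gene_id,
    chromosome = as.character(df$seqnames),
    strand = as.character(df$strand),
    feature = ifelse(df$type %in% c("five_prime_UTR", "three_prime_UTR"),
                     "UTR", as.character(df$type)),
    start = df$start, end = df$end
  ) |>
    filter(.data$feature %in% c("gene", "exon", "CDS", "UTR"))
}

#' Classify variants by functional context
#'
#' Assigns each variant one of `CDS`, `UTR`, `intron` or `intergenic`:
#' positions in a CDS interval are `CDS`; otherwise UTR intervals; a
#' position inside a gene span hitting neither is `intron`; outside all
#' gene spans, `intergenic`. The precedence resolves overlapping models.
#'
#' @param variants Tibble with `chromosome`, `position_bp`.
#' @param gene_models Gene-model tibble (see [read_gene_models()]).
#' @return The input with a `context` column.
#' @export
classify_variant_context <- function(variants, gene_models) {
  variants <- as_tibble(variants)
  in_feature <- function(chr, pos, feat) {
    iv <- gene_models[gene_models$feature == feat, ]
    purrr::map2_lgl(chr, pos, function(c, p) {
      any(iv$chromosome == c & iv$start <= p & iv$end >= p)
    })
  }
  variants |>
    mutate(context = dplyr::case_when(
      in_feature(.data$chromosome, .data$position_bp, "CDS") ~ "CDS",
      in_feature(.data$chromosome, .data$position_bp, "UTR") ~ "UTR",
      in_feature(.data$chromosome, .data$position_bp, "gene") ~ "intron",
      TRUE ~ "intergenic"
    ))
}

#' Coding effect of a CDS variant
#'
#' Locates the variant's codon via CDS coordinate arithmetic (strand
#' aware; minus-strand alleles are complemented), translates the reference
#' and alternate codons under the standard genetic code, and reports
#' `synonymous`, `missense`, or `other` (stop gain/loss or a stop-involved
#' change).
#'
#' @param variant One-row tibble or list with `chromosome`, `position_bp`,
#'   `ref_allele`, `alt_allele` (or `donor_allele`).
#' @param gene_model Gene-model tibble for one gene (its CDS rows are
#'   used; total CDS length must be divisible by 3).
#' @param reference A `DNAStringSet`.
#' @return A list with `effect`, `ref_aa`, `alt_aa`, `codon_index`,
#'   `codon_pos`.
#' @export
coding_effect <- function(variant, gene_model, reference) {
  variant <- as.list(as_tibble(variant)[1, ])
  alt <- variant$alt_allele %||% variant$donor_allele
  cds <- gene_model[gene_model$feature == "CDS", ]
  if (nrow(cds) == 0) {
    stop_kaspanel("gene model has no CDS", "kaspanel_validation_error")
  }
  gene <- gene_model$gene_id[1]
  strand <- cds$strand[1]
  cds <- cds[order(cds$start), ]
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0) {
    stop_kaspanel(paste0("CDS length of ", gene, " not divisible by 3"),
                  "kaspanel_validation_error")
  }
  pos <- variant$position_bp
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (!length(hit)) {
    stop_kaspanel("variant not inside the model's CDS",
                  "kaspanel_validation_error")
  }
  # CDS coordinate (1-based from the start codon)
  before <- cds[cds$end < pos, ]
  within <- pos - cds$start[hit] + 1
  plus_coord <- sum(before$end - before$start + 1) + within
  cds_coord <- if (strand == "-") total - plus_coord + 1 else plus_coord

  codon_index <- (cds_coord - 1) %/% 3 + 1
  codon_pos <- (cds_coord - 1) %% 3 + 1

  # spliced CDS sequence on the coding strand
  chr_seq <- reference[[variant$chromosome]]
  pieces <- purrr::map_chr(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(chr_seq, cds$start[i], cds$end[i])))
  cds_seq <- paste(pieces, collapse = "")
  if (strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
  }
  codon <- substr(cds_seq, (codon_index - 1) * 3 + 1, codon_index * 3)
  base_alt <- if (strand == "-") {
    as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  } else alt
  codon_alt <- codon
  substr(codon_alt, codon_pos, codon_pos) <- base_alt
  aa <- function(cdn) as.character(Biostrings::translate(
    Biostrings::DNAString(cdn), no.init.codon = TRUE))
  ref_aa <- aa(codon)
  alt_aa <- aa(codon_alt)
  effect <- if (ref_aa == "*" || alt_aa == "*") "other"
            else if (ref_aa == alt_aa) "synonymous" else "missense"
  list(effect = effect, ref_aa = ref_aa, alt_aa = alt_aa,
       codon_index = codon_index, codon_pos = codon_pos)
}
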