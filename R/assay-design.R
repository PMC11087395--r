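# KASP assay construction: flank extraction, bracketed-SNP design input,
# allele-specific primers with fluorophore tails, melting temperature, and
# multi-locus specificity rejection.

#' Design parameters for KASP primer construction
#'
#' @param primer_len Allowed primer core length range in nt.
#' @param tm_window Acceptable melting-temperature window in degrees C.
#' @param tm_target Tm optimum targeted by the greedy extension.
#' @param amplicon Allowed amplicon length range in bp.
#' @param tail_fam,tail_hex 5' tail oligos for the two fluorophores (the
#'   widely published tail sequences; configurable because assays may use
#'   other reporter systems).
#' @param tm_method `"nearest_neighbor"` or `"wallace"`.
#' @param core_len Length of the 3'-anchored core used by the specificity
#'   search (default 16 nt; must be at least 12).
#' @param oligo_conc,na_conc Oligo and monovalent-salt concentrations (M)
#'   for the nearest-neighbour Tm.
#' @return A named list.
#' @export
design_params <- function(primer_len = c(18L, 36L),
                          tm_window = c(57, 63),
                          tm_target = 60,
                          amplicon = c(50L, 120L),
                          tail_fam = "GAAGGTGACCAAGTTCATGCT",
                          tail_hex = "GAAGGTCGGAGTCAACGGATT",
                          tm_method = "nearest_neighbor",
                          core_len = 16L,
                          oligo_conc = 2e-7,
                          na_conc = 0.05) {
  if (core_len < 12L) {
    stop_kaspanel("specificity core must be at least 12 nt",
                  "kaspanel_config_error")
  }
  list(primer_len = as.integer(primer_len), tm_window = tm_window,
       tm_target = tm_target, amplicon = as.integer(amplicon),
       tail_fam = tail_fam, tail_hex = tail_hex, tm_method = tm_method,
       core_len = as.integer(core_len), oligo_conc = oligo_conc,
       na_conc = na_conc)
}

#' Extract SNP flanks as a bracketed design sequence
#'
#' Returns `upstream [ref/alt] downstream` on the reference plus strand,
#' with `flank_len` bases on each side (truncated, with a flag, when the SNP
#' sits closer than `flank_len` to a chromosome end).
#'
#' @param candidate One candidate row (`chromosome`, `position_bp`,
#'   `ref_allele`, `donor_allele` or `alt_allele`).
#' @param reference A `DNAStringSet`.
#' @param flank_len Flank length in bp (default 100).
#' @return A list with `bracket_sequence`, `truncated_left`,
#'   `truncated_right`.
#' @export
extract_flanks <- function(candidate, reference, flank_len = 100L) {
  candidate <- as.list(as_tibble(candidate)[1, ])
  chr <- as.character(candidate$chromosome)
  pos <- candidate$position_bp
  alt <- candidate$donor_allele %||% candidate$alt_allele
  if (!chr %in% names(reference)) {
    stop_kaspanel(paste0("chromosome not in reference: ", chr),
                  "kaspanel_validation_error")
  }
  len <- length(reference[[chr]])
  if (pos < 1 || pos > len) {
    stop_kaspanel("position outside reference", "kaspanel_validation_error")
  }
  ref_base <- reference_base(reference, chr, pos)
  if (!is.null(candidate$ref_allele) && ref_base != candidate$ref_allele) {
    stop_kaspanel(sprintf("reference base %s differs from ref_allele %s at %s:%d",
                          ref_base, candidate$ref_allele, chr, pos),
                  "kaspanel_validation_error")
  }
  left_start <- max(1L, pos - flank_len)
  right_end <- min(len, pos + flank_len)
  left <- as.character(Biostrings::subseq(reference[[chr]], left_start,
                                          pos - 1L))
  right <- as.character(Biostrings::subseq(reference[[chr]], pos + 1L,
                                           right_end))
  list(
    bracket_sequence = paste0(left, "[", ref_base, "/", alt, "]", right),
    truncated_left = (pos - left_start) < flank_len,
    truncated_right = (right_end - pos) < flank_len
  )
}

#' Parse a bracketed design sequence
#'
#' @param bracket_sequence String of the form `LEFT[R/A]RIGHT`.
#' @return A list with `left`, `ref`, `alt`, `right`.
#' @export
parse_bracket <- function(bracket_sequence) {
  m <- regmatches(bracket_sequence,
                  regexec("^([ACGTN]*)\\[([ACGT])/([ACGT])\\]([ACGTN]*)$",
                          bracket_sequence))[[1]]
  if (length(m) != 5) {
    stop_kaspanel("not a valid bracketed SNP sequence",
                  "kaspanel_parse_error")
  }
  list(left = m[2], ref = m[3], alt = m[4], right = m[5])
}

#' Format the primer-design input table
#'
#' One row per candidate with id, chromosome and the bracketed flank
#' sequence — the input dialect of genome-specific KASP design tools.
#'
#' @param assays Tibble with `marker_id`, `chromosome`, `bracket_sequence`.
#' @param path Optional CSV output path (no header comments).
#' @return The design-input tibble, invisibly written to `path` if given.
#' @export
format_design_input <- function(assays, path = NULL) {
  out <- select(as_tibble(assays), id = "marker_id", "chromosome",
                "bracket_sequence")
  if (nrow(out) == 0) warn("format_design_input: no candidates")
  if (!is.null(path)) readr::write_csv(out, path, col_names = TRUE)
  out
}

#' Oligo melting temperature
#'
#' `wallace`: the 2(A+T) + 4(G+C) rule. `nearest_neighbor`: unified
#' nearest-neighbour thermodynamics (stacked-pair enthalpy/entropy sums with
#' initiation terms) at the given oligo concentration, with the entropic
#' monovalent-salt correction `0.368 (N-1) ln[Na+]`. Fluorophore tails must
#' be excluded by the caller.
#'
#' @param oligo Oligo sequence (ACGT only).
#' @param method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param oligo_conc,na_conc Concentrations in M (nearest-neighbour only).
#' @return Temperature in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT", method = "wallace")  # 60
#' @export
melting_temperature <- function(oligo,
                                method = c("nearest_neighbor", "wallace"),
                                oligo_conc = 2e-7, na_conc = 0.05) {
  method <- match.arg(method)
  oligo <- toupper(oligo)
  b <- strsplit(oligo, "", fixed = TRUE)[[1]]
  if (length(b) == 0 || !all(b %in% c("A", "C", "G", "T"))) {
    stop_kaspanel("oligo must be non-empty ACGT", "kaspanel_validation_error")
  }
  if (method == "wallace") {
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  }
  nn <- rbind(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), AC = c(-8.4, -22.4),
    AG = c(-7.8, -21.0), TA = c(-7.2, -21.3), TT = c(-7.9, -22.2),
    TC = c(-8.2, -22.2), TG = c(-8.5, -22.7), CA = c(-8.5, -22.7),
    CT = c(-7.8, -21.0), CC = c(-8.0, -19.9), CG = c(-10.6, -27.2),
    GA = c(-8.2, -22.2), GT = c(-8.4, -22.4), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9))
  pairs <- paste0(b[-length(b)], b[-1])
  dH <- sum(nn[pairs, 1])
  dS <- sum(nn[pairs, 2])
  for (term in c(b[1], b[length(b)])) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  # entropic salt correction of the unified parameter set
  dS <- dS + 0.368 * (length(b) - 1) * log(na_conc)
  R <- 1.987
  tm_k <- dH * 1000 / (dS + R * log(oligo_conc / 4))
  tm_k - 273.15
}

#' Design KASP primers for one bracketed SNP
#'
#' Allele-specific primers end exactly on the SNP base (one per allele) and
#' carry the fluorophore tails 5'; the common primer is chosen on the
#' opposite strand so the amplicon length and Tm window are satisfied,
#' extending or shortening greedily towards the Tm target. Ties are broken
#' by minimal |Tm - target|, then shorter length, then leftmost position.
#'
#' @param bracket_sequence Bracketed flank string (see [parse_bracket()]).
#' @param params [design_params()].
#' @return A one-row tibble with the primer fields (`primer_allele_ref`,
#'   `primer_allele_alt`, `primer_common`, `core_allele_ref`,
#'   `core_allele_alt`, `amplicon_length`, `tm_ref`, `tm_alt`, `tm_common`,
#'   `status`).
#' @export
design_primers <- function(bracket_sequence, params = design_params()) {
  parts <- parse_bracket(bracket_sequence)
  tm_fun <- function(s) melting_temperature(s, method = params$tm_method,
                                            oligo_conc = params$oligo_conc,
                                            na_conc = params$na_conc)
  fail <- function() tibble(
    primer_allele_ref = NA_character_, primer_allele_alt = NA_character_,
    primer_common = NA_character_, core_allele_ref = NA_character_,
    core_allele_alt = NA_character_, amplicon_length = NA_integer_,
    tm_ref = NA_real_, tm_alt = NA_real_, tm_common = NA_real_,
    status = "rejected_design")

  # allele-specific primers: suffix of the left flank plus the allele base
  lens <- seq(params$primer_len[1], params$primer_len[2])
  lens <- lens[lens - 1L <= nchar(parts$left)]
  if (!length(lens)) return(fail())
  cand <- purrr::map_dfr(lens, function(L) {
    core <- paste0(stringr::str_sub(parts$left, -(L - 1L)), parts$ref)
    core_alt <- paste0(stringr::str_sub(parts$left, -(L - 1L)), parts$alt)
    tibble(len = L, core = core, core_alt = core_alt,
           tm_ref = tm_fun(core), tm_alt = tm_fun(core_alt))
  }) |>
    filter(.data$tm_ref >= params$tm_window[1],
           .data$tm_ref <= params$tm_window[2],
           .data$tm_alt >= params$tm_window[1],
           .data$tm_alt <= params$tm_window[2]) |>
    mutate(score = pmax(abs(.data$tm_ref - params$tm_target),
                        abs(.data$tm_alt - params$tm_target))) |>
    arrange(.data$score, .data$len)
  if (nrow(cand) == 0) return(fail())
  as_core <- cand$core[1]
  as_alt <- cand$core_alt[1]
  as_len <- cand$len[1]

  # common primer on the opposite strand, 3' end facing the SNP
  right <- parts$right
  best <- NULL
  for (a in seq_len(max(0L, nchar(right) - params$primer_len[1] + 1L))) {
    for (m in seq(params$primer_len[1], params$primer_len[2])) {
      e <- a + m - 1L
      if (e > nchar(right)) break
      amp <- as_len + a + m - 1L  # 5' end of AS primer .. 3' end of common
      if (amp < params$amplicon[1] || amp > params$amplicon[2]) next
      seq_plus <- stringr::str_sub(right, a, e)
      primer <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq_plus)))
      tm <- tm_fun(primer)
      if (tm < params$tm_window[1] || tm > params$tm_window[2]) next
      sc <- abs(tm - params$tm_target)
      if (is.null(best) || sc < best$sc - 1e-12 ||
          (abs(sc - best$sc) <= 1e-12 && (m < best$m ||
                                          (m == best$m && a < best$a)))) {
        best <- list(primer = primer, tm = tm, amp = amp, a = a, m = m,
                     sc = sc)
      }
    }
  }
  if (is.null(best)) return(fail())
  tibble(
    primer_allele_ref = paste0(params$tail_fam, as_core),
    primer_allele_alt = paste0(params$tail_hex, as_alt),
    primer_common = best$primer,
    core_allele_ref = as_core,
    core_allele_alt = as_alt,
    amplicon_length = as.integer(best$amp),
    tm_ref = cand$tm_ref[1], tm_alt = cand$tm_alt[1], tm_common = best$tm,
    status = "designed"
  )
}

#' Multi-locus specificity check
#'
#' Counts genomic occurrences (both strands) of the 3'-anchored core of the
#' allele-specific primers against the reference (which carries the ref
#' allele). More than one hit of the ref-allele core, or more than one hit
#' of the alt-allele core, rejects the assay as multi-locus; exactly one
#' ref-core hit makes it eligible for acceptance.
#'
#' @param assay One-row assay tibble from [design_primers()] (needs
#'   `core_allele_ref`, `core_allele_alt`, `status`).
#' @param reference A `DNAStringSet`.
#' @param params [design_params()] (supplies `core_len`).
#' @return The assay row with `specificity_hits` and updated `status`
#'   (`accepted` or `rejected_multilocus`).
#' @export
specificity_check <- function(assay, reference, params = design_params()) {
  assay <- as_tibble(assay)[1, ]
  if (identical(assay$status, "rejected_design")) {
    assay$specificity_hits <- NA_integer_
    return(assay)
  }
  if (params$core_len < 12L) {
    stop_kaspanel("specificity core must be at least 12 nt",
                  "kaspanel_config_error")
  }
  hits_of <- function(core) {
    core <- stringr::str_sub(core, -params$core_len)
    pat <- Biostrings::DNAString(core)
    rc <- Biostrings::reverseComplement(pat)
    sum(Biostrings::vcountPattern(pat, reference)) +
      sum(Biostrings::vcountPattern(rc, reference))
  }
  h_ref <- hits_of(assay$core_allele_ref)
  h_alt <- hits_of(assay$core_allele_alt)
  assay$specificity_hits <- h_ref
  assay$status <- if (h_ref == 1L && h_alt <= 1L) "accepted"
                  else "rejected_multilocus"
  assay
}

#' Design assays for a candidate list
#'
#' Runs flank extraction, primer design and the specificity check for every
#' candidate and returns one assay row per candidate.
#'
#' @param candidates Candidate tibble from [find_donor_specific()].
#' @param reference A `DNAStringSet`.
#' @param params [design_params()].
#' @param flank_len Flank length in bp.
#' @return A tibble of `MarkerAssay` rows: candidate columns plus
#'   `bracket_sequence`, primer fields, `specificity_hits`, `status`.
#' @export
design_assays <- function(candidates, reference, params = design_params(),
                          flank_len = 100L) {
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cnd <- candidates[i, ]
    fl <- extract_flanks(cnd, reference, flank_len)
    pr <- design_primers(fl$bracket_sequence, params)
    pr <- specificity_check(pr, reference, params)
    bind_cols(cnd, tibble(bracket_sequence = fl$bracket_sequence), pr)
  })
}
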