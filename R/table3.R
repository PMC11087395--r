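# Packaged transcription of the published 54-marker KASP quality-control
# table, used as an in-package fixture for panel summaries and regression
# checks. Two population classes are reported per marker; they are labelled
# "a" (first printed column pair) and "b" (second) because the printed
# class labels are internally inconsistent with the prose ranges. Rows whose
# printed counts and percentages disagree carry a note in `provenance`.

TABLE3_MD5 <- "2bd3af5416462b67bee20dc8763c4f60"

verify_table3 <- function(path, expected = TABLE3_MD5) {
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, expected)) {
    stop_kaspanel(
      paste0("packaged marker QC table failed its integrity check (md5 ",
             md5, ")"),
      "kaspanel_integrity_error")
  }
  invisible(TRUE)
}

#' Load the packaged 54-marker QC fixture
#'
#' Returns the transcription of the published per-marker quality-control and
#' allelic-effect table: marker identity (id, chromosome, position, reference
#' and donor "positive" allele), the recipient backgrounds in which each
#' marker is usable (`utility_set`), false-positive/false-negative rates for
#' two validation population classes, allele-class counts, frequencies and
#' phenotypic means (percent germination and mesocotyl length at 10 cm
#' sowing depth), and the Kruskal-Wallis significance tier.
#'
#' The packaged file's MD5 checksum is verified on load; a mismatch raises an
#' integrity error.
#'
#' @param path Optional path to an alternative transcription (checksum
#'   verification is skipped for user-supplied files).
#' @return A tibble with 54 rows, one per polymorphic marker.
#' @examples
#' tab <- load_table3()
#' dplyr::count(tab, chromosome)
#' @export
load_table3 <- function(path = NULL) {
  verify <- is.null(path)
  path <- path %||% system.file("extdata", "table3_kasp_qc.csv",
                                package = "kaspanel", mustWork = TRUE)
  if (verify) verify_table3(path)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chromosome = readr::col_character(),
                           provenance = readr::col_character()))
  tab$provenance[is.na(tab$provenance)] <- ""
  if (nrow(tab) != 54L) {
    stop_kaspanel("marker QC fixture must have 54 rows",
                  "kaspanel_integrity_error")
  }
  if (!all(tab$marker_id == paste0("K_", tab$position_bp))) {
    stop_kaspanel("marker ids must encode their positions (K_<position>)",
                  "kaspanel_integrity_error")
  }
  tab$n_utility <- lengths(split_set(tab$utility_set))
  tab
}

#' Identifiers of the published 12-marker core panel
#'
#' The core panel selected from the 54 polymorphic assays on the basis of
#' FPR, FNR, utility across recipient backgrounds and significant allelic
#' effects: five markers on chromosome 3, one on 4, three on 7 and three
#' on 8. Selection thresholds were never published, so the membership is
#' pinned as configuration rather than recomputed from a threshold rule.
#'
#' @return Character vector of 12 marker ids.
#' @export
core_panel_ids <- function() {
  c("K_16856978", "K_19041692", "K_33072076", "K_33079643", "K_33107252",
    "K_20771274", "K_13314239", "K_13430534", "K_14713452",
    "K_19899233", "K_19914183", "K_19914306")
}

#' Identifiers of the four designed assays that showed no polymorphism
#'
#' @return Character vector of 4 marker ids.
#' @export
nonpolymorphic_assay_ids <- function() {
  c("K_10517640", "K_21414536", "K_21515581", "K_19899355")
}
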