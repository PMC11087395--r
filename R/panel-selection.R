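# Marker-to-window assignment, spacing summaries in kb and cM, utility
# histograms, core-panel selection and the favorable-allele frequency
# matrix behind the heat maps.

#' Assign markers to QTL windows
#'
#' Every marker maps to the window containing its position (bounds
#' inclusive); markers outside all windows are listed as unassigned and
#' excluded from per-region counts. Per-chromosome counts tally all markers
#' by their chromosome column (assigned or not), matching how the published
#' per-chromosome assay counts are quoted.
#'
#' @param markers Tibble with `marker_id`, `chromosome`, `position_bp`.
#' @param registry Region tibble (see [default_qtl_regions()]).
#' @return A list with `assigned` (markers + `region_id`), `unassigned`
#'   (markers outside all windows), `region_counts`, `chromosome_counts`.
#' @export
assign_regions <- function(markers, registry) {
  markers <- as_tibble(markers)
  markers$region_id <- region_of(markers$chromosome, markers$position_bp,
                                 registry)
  assigned <- filter(markers, !is.na(.data$region_id))
  unassigned <- filter(markers, is.na(.data$region_id))
  list(
    assigned = assigned,
    unassigned = unassigned,
    region_counts = count(assigned, .data$region_id, name = "n_markers"),
    chromosome_counts = count(markers, .data$chromosome, name = "n_markers")
  )
}

#' Convert physical distance to genetic distance
#'
#' Uses the fixed conversion of about 244 kb per cM reported for rice.
#'
#' @param distance_kb Distance(s) in kb.
#' @param kb_per_cm Conversion constant (default 244).
#' @return Distance(s) in cM.
#' @examples
#' cm_from_kb(505)  # ~2.070
#' @export
cm_from_kb <- function(distance_kb, kb_per_cm = 244) {
  if (kb_per_cm <= 0) {
    stop_kaspanel("kb_per_cm must be positive", "kaspanel_config_error")
  }
  distance_kb / kb_per_cm
}

#' Check the published kb to cM conversions
#'
#' Recomputes the printed kb -> cM pairs under the 244 kb/cM constant and
#' flags the one pair (228.86 kb -> 0.978 cM) that is internally
#' inconsistent with that constant (it recomputes to ~0.938 cM).
#'
#' @param kb_per_cm Conversion constant (default 244).
#' @return Tibble with `region_id`, `distance_kb`, `printed_cm`,
#'   `computed_cm`, `consistent`.
#' @export
check_cm_conversions <- function(kb_per_cm = 244) {
  tibble::tribble(
    ~region_id, ~distance_kb, ~printed_cm, ~printed_digits,
    "qSD3.1", 505, 2.070, 3,
    "qSD3.2", 13.16, 0.0539, 4,
    "qSD4.1", 35.17, 0.144, 3,
    "qSD7.1", 228.86, 0.978, 3,
    "qSD7.2", 293.43, 1.203, 3,
    "qSD8.1", 30.17, 0.124, 3
  ) |>
    mutate(
      computed_cm = cm_from_kb(.data$distance_kb, kb_per_cm),
      consistent = abs(round(.data$computed_cm, .data$printed_digits) -
                         .data$printed_cm) <
        1.5 * 10^(-.data$printed_digits)
    )
}

#' Mean adjacent-marker spacing per QTL window
#'
#' Sorts markers within each window and averages the adjacent-position
#' differences ("the average physical distance between two markers" read as
#' consecutive markers), in kb and cM. Windows with fewer than two markers
#' get `NA` with a flag.
#'
#' @param markers Tibble with `marker_id`, `chromosome`, `position_bp`.
#' @param registry Region tibble.
#' @param kb_per_cm Conversion constant (default 244).
#' @return Tibble `region_id`, `n_markers`, `mean_kb`, `mean_cm`,
#'   `undefined`.
#' @export
spacing_summary <- function(markers, registry, kb_per_cm = 244) {
  asg <- assign_regions(markers, registry)$assigned
  purrr::map_dfr(registry$region_id, function(r) {
    pos <- sort(asg$position_bp[asg$region_id == r])
    if (length(pos) >= 2) {
      mkb <- mean(diff(pos)) / 1000
      tibble(region_id = r, n_markers = length(pos), mean_kb = mkb,
             mean_cm = cm_from_kb(mkb, kb_per_cm), undefined = FALSE)
    } else {
      tibble(region_id = r, n_markers = length(pos), mean_kb = NA_real_,
             mean_cm = NA_real_, undefined = TRUE)
    }
  })
}

#' Histogram of marker utility
#'
#' Counts markers by the number of recipient backgrounds in which they are
#' usable. Markers with zero utility are excluded (they are non-polymorphic
#' and leave the pipeline upstream).
#'
#' @param utility Either a tibble with an `n_utility` (or `utility_set`)
#'   column, or an integer vector of utility counts.
#' @return Tibble `n_utility`, `n_markers`, sorted by decreasing utility.
#' @export
utility_histogram <- function(utility) {
  n <- if (is.data.frame(utility)) {
    if ("n_utility" %in% names(utility)) utility$n_utility
    else lengths(split_set(utility$utility_set))
  } else as.integer(utility)
  n <- n[n > 0]
  if (!length(n)) return(tibble(n_utility = integer(), n_markers = integer()))
  tab <- table(n)
  tibble(n_utility = as.integer(names(tab)),
         n_markers = as.integer(tab)) |>
    arrange(dplyr::desc(.data$n_utility))
}

#' Core-panel selection criteria
#'
#' @param max_fpr,max_fnr Upper bounds on the error rates.
#' @param min_utility Minimum number of usable recipient backgrounds.
#' @param require_significance Minimum significance tier (`"ns"`, `"*"`,
#'   `"**"`, `"***"`).
#' @param per_region_quota Optional named vector truncating the panel
#'   within each region after ranking.
#' @return A named list of class `panel_criteria`.
#' @export
panel_criteria <- function(max_fpr = 1, max_fnr = 1, min_utility = 0L,
                           require_significance = "ns",
                           per_region_quota = NULL) {
  stopifnot(max_fpr >= 0, max_fpr <= 1, max_fnr >= 0, max_fnr <= 1,
            min_utility >= 0,
            require_significance %in% c("ns", "*", "**", "***"))
  structure(list(max_fpr = max_fpr, max_fnr = max_fnr,
                 min_utility = as.integer(min_utility),
                 require_significance = require_significance,
                 per_region_quota = per_region_quota),
            class = "panel_criteria")
}

tier_rank <- function(sig) {
  match(sig, c("ns", "*", "**", "***")) - 1L
}

#' Select a core marker panel
#'
#' Applies the criteria to per-marker QC records and ranks the survivors by
#' utility (descending), FPR, FNR and Kruskal-Wallis p (ascending). The
#' audit trail records the pass/fail of every criterion for every marker.
#' Published selection thresholds were never printed, so reproducing the
#' published 12-marker panel uses [core_panel_ids()] as configuration
#' rather than a threshold rule.
#'
#' @param qc Tibble with one row per marker: `marker_id`, `n_utility`,
#'   `fpr`, `fnr`, `significance`, optionally `kw_p` and `region_id`.
#' @param criteria A [panel_criteria()].
#' @return Object of class `kasp_panel`: list with `panel` (ordered
#'   tibble), `audit` (per-marker criterion flags) and `criteria`.
#' @export
select_core_panel <- function(qc, criteria = panel_criteria()) {
  qc <- as_tibble(qc)
  if (!"kw_p" %in% names(qc)) qc$kw_p <- NA_real_
  audit <- qc |>
    mutate(
      pass_fpr = .data$fpr <= criteria$max_fpr,
      pass_fnr = .data$fnr <= criteria$max_fnr,
      pass_utility = .data$n_utility >= criteria$min_utility,
      pass_significance = tier_rank(.data$significance) >=
        tier_rank(criteria$require_significance),
      pass_all = .data$pass_fpr & .data$pass_fnr & .data$pass_utility &
        .data$pass_significance
    )
  panel <- audit |>
    filter(.data$pass_all) |>
    arrange(dplyr::desc(.data$n_utility), .data$fpr, .data$fnr, .data$kw_p,
            .data$marker_id)
  quota <- criteria$per_region_quota
  if (!is.null(quota) && "region_id" %in% names(panel)) {
    panel <- panel |>
      group_by(.data$region_id) |>
      filter(row_number() <=
               dplyr::coalesce(quota[dplyr::cur_group()$region_id][[1]],
                               Inf)) |>
      ungroup() |>
      arrange(dplyr::desc(.data$n_utility), .data$fpr, .data$fnr,
              .data$kw_p, .data$marker_id)
  }
  structure(list(
    panel = select(panel, -dplyr::starts_with("pass_")),
    audit = select(audit, "marker_id", dplyr::starts_with("pass_")),
    criteria = criteria
  ), class = "kasp_panel")
}

#' @export
print.kasp_panel <- function(x, ...) {
  cat("<kasp_panel> ", nrow(x$panel), " marker(s) selected of ",
      nrow(x$audit), "\n", sep = "")
  print(x$panel)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kasp_panel <- function(x, ...) x$panel

#' @exportS3Method generics::glance
glance.kasp_panel <- function(x, ...) {
  tibble(n_selected = nrow(x$panel), n_candidates = nrow(x$audit),
         max_fpr = x$criteria$max_fpr, max_fnr = x$criteria$max_fnr,
         min_utility = x$criteria$min_utility,
         require_significance = x$criteria$require_significance)
}

#' Favorable-allele frequency matrix
#'
#' The frequency of donor-allele carriers (heterozygous or donor-
#' homozygous calls) among non-missing calls, per population and marker —
#' the matrix behind the favorable-allele heat maps. Markers with only
#' missing calls in a population are `NA` (masked).
#'
#' @param calls Long call tibble with `population_id`, `marker_id`,
#'   `called_class`.
#' @return A `favorable_allele_matrix` tibble: `population_id`,
#'   `marker_id`, `n_called`, `carrier_freq`.
#' @export
favorable_allele_matrix <- function(calls) {
  out <- calls |>
    group_by(.data$population_id, .data$marker_id) |>
    summarise(
      n_called = sum(!is.na(.data$called_class)),
      carrier_freq = {
        cc <- .data$called_class[!is.na(.data$called_class)]
        if (length(cc)) mean(cc %in% c("het", "donor_hom")) else NA_real_
      },
      .groups = "drop"
    )
  class(out) <- c("favorable_allele_matrix", class(out))
  out
}
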