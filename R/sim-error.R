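#' Inject assay genotyping error into true genotypes
#'
#' Creates the truth/call discrepancy that the marker quality-control
#' metrics measure. With probability `false_positive` a recipient-homozygous
#' truth is mis-called as carrying the donor allele (a heterozygous call);
#' with probability `false_negative` a donor-allele carrier (heterozygote or
#' donor homozygote) is mis-called recipient-homozygous; independently, with
#' probability `missing` the call is lost. Every flip is logged in the
#' `error_log` attribute.
#'
#' @param progeny Genotype tibble with a `true_class` column (from
#'   [simulate_cross()] / [simulate_populations()]).
#' @param error_rates List with `false_positive`, `false_negative`,
#'   `missing`; either scalars applied to all markers or a tibble with
#'   `marker_id` plus those columns for per-marker rates.
#' @param seed Integer seed.
#' @return The input tibble with a `called_class` column added (`NA` =
#'   missing call); attribute `error_log` counts injected events per marker.
#' @export
inject_assay_error <- function(progeny, error_rates, seed) {
  if (is.data.frame(error_rates)) {
    rates <- progeny |>
      left_join(as_tibble(error_rates), by = "marker_id")
    fp <- rates$false_positive %||% 0
    fn <- rates$false_negative %||% 0
    ms <- rates$missing %||% 0
    fp[is.na(fp)] <- 0; fn[is.na(fn)] <- 0; ms[is.na(ms)] <- 0
  } else {
    fp <- rep(error_rates$false_positive %||% 0, nrow(progeny))
    fn <- rep(error_rates$false_negative %||% 0, nrow(progeny))
    ms <- rep(error_rates$missing %||% 0, nrow(progeny))
  }
  if (any(fp + ms > 1) || any(fn + ms > 1)) {
    stop_kaspanel("error rates for a truth class sum to more than 1",
                  "kaspanel_config_error")
  }
  out <- with_sub_seed(seed, "assay_error", {
    called <- progeny$true_class
    is_rec <- progeny$true_class == "recipient_hom"
    is_car <- progeny$true_class %in% c("het", "donor_hom")
    u <- runif(nrow(progeny))
    flip_fp <- is_rec & u < fp
    flip_fn <- is_car & u < fn
    called[flip_fp] <- "het"
    called[flip_fn] <- "recipient_hom"
    drop <- runif(nrow(progeny)) < ms
    called[drop] <- NA_character_
    res <- mutate(progeny, called_class = called)
    attr(res, "error_log") <- res |>
      mutate(fp_event = flip_fp, fn_event = flip_fn, missing_event = drop) |>
      group_by(.data$marker_id) |>
      summarise(n_fp = sum(.data$fp_event), n_fn = sum(.data$fn_event),
                n_missing = sum(.data$missing_event), .groups = "drop")
    res
  })
  attr(out, "region_dosage") <- attr(progeny, "region_dosage")
  out
}
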