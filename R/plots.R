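# ggplot2 displays for the main result types.

#' Plot an endpoint-fluorescence plate
#'
#' The two-channel scatter with samples coloured by call (the familiar
#' three-cluster KASP picture: recipient homozygotes along x, donor
#' homozygotes along y, heterozygotes on the diagonal).
#'
#' @param plate Plate tibble (`sample_id`, `signal_x`, `signal_y`).
#' @param calls Optional call tibble from [call_genotypes()].
#' @return A ggplot object.
#' @export
plot_fluorescence <- function(plate, calls = NULL) {
  dat <- as_tibble(plate)
  if (!is.null(calls)) {
    dat <- left_join(dat, select(calls, "sample_id", "call"),
                     by = "sample_id")
    dat$call <- dplyr::coalesce(dat$call, "no_call")
  } else {
    dat$call <- "uncalled"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$signal_x, y = .data$signal_y,
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      recipient_hom = "#d62728", het = "#2ca02c", donor_hom = "#1f77b4",
      no_call = "grey60", uncalled = "grey40")) +
    ggplot2::labs(x = "recipient-allele fluorophore",
                  y = "donor-allele fluorophore", colour = "call") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.favorable_allele_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$marker_id,
                                       y = .data$population_id,
                                       fill = .data$carrier_freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "favorable-allele\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.marker_qc <- function(object, trait = "germination_pct", ...) {
  neg <- paste0("mean_negative_", trait)
  pos <- paste0("mean_positive_", trait)
  if (!all(c(neg, pos) %in% names(object))) {
    stop_kaspanel("QC table lacks class means for this trait",
                  "kaspanel_validation_error")
  }
  dat <- object |>
    select(dplyr::any_of(c("population_id", "marker_id", "significance")),
           negative = dplyr::all_of(neg), positive = dplyr::all_of(pos)) |>
    pivot_longer(c("negative", "positive"), names_to = "class",
                 values_to = "mean")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$marker_id,
                                         y = .data$mean,
                                         colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = trait, colour = "allele class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  if ("population_id" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~population_id, ncol = 1)
  }
  p
}
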