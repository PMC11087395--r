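# Endpoint-fluorescence genotype calling.
#
# KASP genotypes appear as three clusters in two-channel signal space:
# recipient homozygotes along the x fluorophore, donor homozygotes along y,
# heterozygotes on the diagonal. Calls are made on the signal angle
# theta = atan2(y, x), which makes them invariant to uniform scaling of both
# channels; a guard band around the cluster boundaries produces no-calls.

#' Caller parameters
#'
#' @param min_intensity Samples with radial intensity below this are
#'   no-calls (default 0.2, on the unit-intensity scale of
#'   [render_fluorescence()]).
#' @param guard_deg Half-width in degrees of the no-call band around each
#'   cluster boundary (default 10).
#' @return A named list.
#' @export
caller_params <- function(min_intensity = 0.2, guard_deg = 10) {
  list(min_intensity = min_intensity, guard_deg = guard_deg)
}

# Deterministic 1-D Lloyd iteration on angles, seeded at the canonical
# cluster centres 0/45/90 degrees.
refine_centers <- function(theta, centers = c(0, 45, 90), iters = 25L) {
  for (i in seq_len(iters)) {
    assign <- max.col(-abs(outer(theta, centers, "-")), ties.method = "first")
    upd <- vapply(seq_along(centers), function(k) {
      if (any(assign == k)) mean(theta[assign == k]) else centers[k]
    }, numeric(1))
    if (max(abs(upd - centers)) < 1e-9) break
    centers <- upd
  }
  list(centers = centers, assign = assign,
       empty = vapply(seq_along(centers),
                      function(k) !any(assign == k), logical(1)))
}

#' Call genotypes from endpoint fluorescence
#'
#' @param plate Tibble with columns `sample_id`, `signal_x`, `signal_y` and
#'   optionally `control` (logical; control wells are excluded from
#'   clustering and calling). Channel x is the recipient-allele fluorophore.
#' @param params [caller_params()].
#' @return A tibble `sample_id`, `theta_deg`, `call` with `call` in
#'   `recipient_hom`/`het`/`donor_hom` or `NA` (no-call).
#' @export
call_genotypes <- function(plate, params = caller_params()) {
  plate <- as_tibble(plate)
  if (!all(c("sample_id", "signal_x", "signal_y") %in% names(plate))) {
    stop_kaspanel("plate needs sample_id, signal_x, signal_y",
                  "kaspanel_validation_error")
  }
  if (!"control" %in% names(plate)) plate$control <- FALSE
  if (any(plate$signal_x < 0 | plate$signal_y < 0, na.rm = TRUE)) {
    stop_kaspanel("intensities must be non-negative",
                  "kaspanel_validation_error")
  }
  work <- plate[!plate$control, ]
  if (nrow(work) < 3) {
    stop_kaspanel("need at least 3 non-control samples",
                  "kaspanel_validation_error")
  }
  r <- sqrt(work$signal_x^2 + work$signal_y^2)
  theta <- atan2(work$signal_y, work$signal_x) * 180 / pi
  ok <- r >= params$min_intensity & is.finite(theta)
  call <- rep(NA_character_, nrow(work))
  if (sum(ok) >= 3) {
    fit <- refine_centers(theta[ok])
    centers <- sort(fit$centers)
    labels <- c("recipient_hom", "het", "donor_hom")
    bounds <- (centers[-1] + centers[-3]) / 2
    assign <- findInterval(theta[ok], bounds) + 1L
    cl <- labels[assign]
    near_boundary <- purrr::map_lgl(theta[ok], function(t)
      any(abs(t - bounds) < params$guard_deg))
    cl[near_boundary] <- NA_character_
    if (any(fit$empty)) {
      warn("call_genotypes: fewer than 3 distinct clusters; het-adjacent calls set to missing")
      cl[cl == "het"] <- NA_character_
    }
    call[ok] <- cl
  } else {
    warn("call_genotypes: too few samples above min_intensity; all no-calls")
  }
  tibble(sample_id = work$sample_id, theta_deg = theta, call = call)
}

#' Render synthetic endpoint fluorescence from genotype truth
#'
#' Truth classes map to canonical angles (recipient-hom 0, het 45,
#' donor-hom 90 degrees) at unit intensity, with Gaussian angular noise of
#' `noise x 45` degrees and radial noise of relative sd `noise`. Missing
#' truth renders as low-intensity points. Deterministic per seed.
#'
#' @param truth Character vector of classes (`recipient_hom`/`het`/
#'   `donor_hom`, `NA` allowed) or a tibble with columns `progeny_id` and
#'   `true_class`.
#' @param noise Noise fraction in \[0, 0.5).
#' @param seed Integer seed.
#' @return A plate tibble (`sample_id`, `signal_x`, `signal_y`, `control`)
#'   with the truth attached as attribute `truth`.
#' @export
render_fluorescence <- function(truth, noise = 0.05, seed = 1L) {
  if (is.data.frame(truth)) {
    ids <- truth$progeny_id
    cls <- truth$true_class
  } else {
    ids <- paste0("S", seq_along(truth))
    cls <- truth
  }
  if (noise < 0 || noise >= 0.5) {
    stop_kaspanel("noise must lie in [0, 0.5)", "kaspanel_config_error")
  }
  ang0 <- c(recipient_hom = 0, het = 45, donor_hom = 90)[cls]
  with_sub_seed(seed, "fluorescence", {
    ang <- ang0 + rnorm(length(cls), sd = noise * 45)
    ang <- pmin(pmax(ang, 0), 90)
    rad <- pmax(1 + rnorm(length(cls), sd = noise), 0.05)
    rad[is.na(ang0)] <- 0.02  # failed wells
    ang[is.na(ang0)] <- runif(sum(is.na(ang0)), 0, 90)
    plate <- tibble(
      sample_id = ids,
      signal_x = rad * cos(ang * pi / 180),
      signal_y = rad * sin(ang * pi / 180),
      control = FALSE
    )
    attr(plate, "truth") <- tibble(sample_id = ids, true_class = cls)
    plate
  })
}
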