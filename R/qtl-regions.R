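#' QTL window registry
#'
#' The candidate-SNP screen is restricted to published QTL windows associated
#' with percent germination and mesocotyl elongation under deep sowing. Six
#' windows on rice chromosomes 3, 4, 7 and 8 ship as the default registry;
#' custom registries can be loaded from a YAML or CSV file with
#' [load_qtl_registry()].
#'
#' Coordinates are 1-based and inclusive at both ends; bounds given in Mb are
#' converted as Mb x 1e6.
#'
#' @return A tibble with columns `region_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `trait`.
#' @examples
#' default_qtl_regions()
#' @export
default_qtl_regions <- function() {
  qtl_regions(tibble::tribble(
    ~region_id, ~chromosome, ~start_mb, ~end_mb,
    "qSD3.1", "3", 16.67, 24.65,
    "qSD3.2", "3", 32.31, 35.46,
    "qSD4.1", "4", 15.91, 21.50,
    "qSD7.1", "7", 10.18, 15.01,
    "qSD7.2", "7", 20.93, 24.26,
    "qSD8.1", "8", 19.86, 20.01
  ) |>
    mutate(
      start_bp = as.integer(round(.data$start_mb * 1e6)),
      end_bp = as.integer(round(.data$end_mb * 1e6)),
      trait = "germination;mesocotyl"
    ) |>
    select("region_id", "chromosome", "start_bp", "end_bp", "trait"))
}

#' Construct and validate a QTL region table
#'
#' @param x A data frame with columns `region_id`, `chromosome`, `start_bp`,
#'   `end_bp` and optionally `trait`.
#' @return The validated tibble.
#' @export
qtl_regions <- function(x) {
  x <- as_tibble(x)
  need <- c("region_id", "chromosome", "start_bp", "end_bp")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop_kaspanel(paste0("registry is missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  class = "kaspanel_validation_error")
  }
  if (nrow(x) == 0) {
    stop_kaspanel("registry contains no regions",
                  class = "kaspanel_validation_error")
  }
  if (!"trait" %in% names(x)) x$trait <- NA_character_
  x$chromosome <- as.character(x$chromosome)
  if (anyDuplicated(x$region_id)) {
    stop_kaspanel("duplicated region ids in registry",
                  class = "kaspanel_validation_error")
  }
  if (any(x$start_bp >= x$end_bp)) {
    bad <- x$region_id[x$start_bp >= x$end_bp]
    stop_kaspanel(paste0("start_bp must be < end_bp for: ",
                         paste(bad, collapse = ", ")),
                  class = "kaspanel_validation_error")
  }
  # no overlapping windows on one chromosome
  by_chr <- split(x, x$chromosome)
  for (chr in by_chr) {
    chr <- chr[order(chr$start_bp), ]
    if (nrow(chr) > 1 && any(chr$start_bp[-1] <= chr$end_bp[-nrow(chr)])) {
      stop_kaspanel(paste0("overlapping regions on chromosome ",
                           chr$chromosome[1]),
                    class = "kaspanel_validation_error")
    }
  }
  x[order(x$chromosome, x$start_bp), ]
}

#' Load a QTL window registry from file
#'
#' Accepts either a YAML file (a list of records with fields `region_id`,
#' `chromosome`, and either `start_mb`/`end_mb` or `start_bp`/`end_bp`) or a
#' CSV file with the same columns.
#'
#' @param path Path to the registry file.
#' @return A validated region tibble (see [qtl_regions()]).
#' @export
load_qtl_registry <- function(path) {
  if (!file.exists(path)) {
    stop_kaspanel(paste0("registry file not found: ", path),
                  class = "kaspanel_validation_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (length(y) == 0) {
      stop_kaspanel("registry file is empty",
                    class = "kaspanel_validation_error")
    }
    purrr::map_dfr(y, ~ as_tibble(.x))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (nrow(raw) == 0) {
    stop_kaspanel("registry file is empty",
                  class = "kaspanel_validation_error")
  }
  if (!"start_bp" %in% names(raw) && "start_mb" %in% names(raw)) {
    raw$start_bp <- as.integer(round(raw$start_mb * 1e6))
    raw$end_bp <- as.integer(round(raw$end_mb * 1e6))
  }
  qtl_regions(raw)
}

# Region lookup for positions; returns region_id or NA.
region_of <- function(chromosome, position_bp, registry) {
  out <- rep(NA_character_, length(position_bp))
  for (i in seq_len(nrow(registry))) {
    hit <- chromosome == registry$chromosome[i] &
      position_bp >= registry$start_bp[i] &
      position_bp <= registry$end_bp[i]
    out[hit] <- registry$region_id[i]
  }
  out
}
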