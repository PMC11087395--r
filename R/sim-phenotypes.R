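#' Percent germination
#'
#' Germination is scored as emerged seeds over planted seeds, times 100,
#' reported to two decimals.
#'
#' @param emerged,planted Seed counts (vectorized).
#' @return Percentages in \[0, 100\].
#' @examples
#' germination_percent(3, 18)   # 16.67
#' germination_percent(11, 12)  # 91.67
#' @export
germination_percent <- function(emerged, planted) {
  if (any(planted <= 0)) {
    stop_kaspanel("planted must be positive", "kaspanel_validation_error")
  }
  if (any(emerged < 0 | emerged > planted)) {
    stop_kaspanel("emerged must lie in [0, planted]",
                  "kaspanel_validation_error")
  }
  round(100 * emerged / planted, 2)
}

#' Simulate progeny phenotypes
#'
#' Germination is modelled as replicate trays of Bernoulli seeds: each
#' progeny is sown as `replicates` trays of `seeds_per_replicate` seeds per
#' depth, and a seed emerges with probability
#' `plogis(baseline + sum of region effects x dosage / 2)`. Mesocotyl, root
#' and total lengths are Gaussian around additive genotype-class means and
#' truncated at zero (truncations are counted and reported).
#'
#' @param progeny Genotype tibble from [simulate_cross()] or
#'   [simulate_populations()] (its `region_dosage` attribute supplies the
#'   per-progeny dosages of the functional variants).
#' @param config A [simulation_config()] providing effects, baselines and
#'   the tray layout.
#' @param seed Seed for the phenotype draws; defaults to the configuration
#'   master seed.
#' @return A tibble with one row per progeny and depth: `population_id`,
#'   `progeny_id`, `depth_cm`, emerged counts per replicate (`rep_1`, ...),
#'   `emerged_total`, `seeds_planted`, `germination_pct`, `mesocotyl_cm`,
#'   `root_cm`, `total_cm`.
#' @export
simulate_phenotypes <- function(progeny, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  dos <- attr(progeny, "region_dosage")
  if (is.null(dos)) {
    stop_kaspanel("progeny lack the region_dosage attribute",
                  "kaspanel_config_error")
  }
  eff <- config$qtl_effects
  ph <- config$phenotype
  reps <- config$replicates
  spr <- config$seeds_per_replicate

  load_of <- function(effect_col) {
    e <- eff[[effect_col]][match(dos$region_id, eff$region_id)]
    stats::aggregate(e * dos$dosage / 2,
                     by = list(population_id = dos$population_id,
                               progeny_id = dos$progeny_id),
                     FUN = sum) |>
      as_tibble() |>
      rename(load = "x")
  }

  base <- distinct(dos, .data$population_id, .data$progeny_id)
  out <- with_sub_seed(seed, "phenotype", {
    trunc_count <- 0L
    res <- purrr::map_dfr(c(4, 10), function(depth) {
      sfx <- if (depth == 4) "_4" else "_10"
      g_load <- load_of(paste0("germ_logit", sfx))
      ml_load <- load_of(paste0("ml_cm", sfx))
      rt_load <- load_of(paste0("root_cm", if (depth == 4) "_10" else "_10"))
      tl_load <- load_of(paste0("total_cm", if (depth == 4) "_10" else "_10"))
      d <- base |>
        left_join(g_load, by = c("population_id", "progeny_id")) |>
        rename(g_load = "load") |>
        left_join(ml_load, by = c("population_id", "progeny_id")) |>
        rename(ml_load = "load") |>
        left_join(rt_load, by = c("population_id", "progeny_id")) |>
        rename(rt_load = "load") |>
        left_join(tl_load, by = c("population_id", "progeny_id")) |>
        rename(tl_load = "load")
      p <- stats::plogis(stats::qlogis(ph[[paste0("germ_p", sfx)]]) + d$g_load)
      counts <- matrix(rbinom(nrow(d) * reps, spr, rep(p, each = reps)),
                       ncol = reps, byrow = TRUE)
      colnames(counts) <- paste0("rep_", seq_len(reps))
      ml <- ph[[paste0("ml", sfx)]] + d$ml_load +
        rnorm(nrow(d), sd = ph[[paste0("ml_sd", sfx)]])
      rt <- ph[[paste0("root", sfx)]] + d$rt_load +
        rnorm(nrow(d), sd = ph[[paste0("root_sd", sfx)]])
      tl <- ph[[paste0("total", sfx)]] + d$tl_load +
        rnorm(nrow(d), sd = ph[[paste0("total_sd", sfx)]])
      trunc_count <<- trunc_count + sum(ml < 0) + sum(rt < 0) + sum(tl < 0)
      bind_cols(
        select(d, "population_id", "progeny_id"),
        as_tibble(counts),
        tibble(
          depth_cm = depth,
          emerged_total = rowSums(counts),
          seeds_planted = reps * spr,
          germination_pct = germination_percent(rowSums(counts), reps * spr),
          mesocotyl_cm = pmax(ml, 0),
          root_cm = pmax(rt, 0),
          total_cm = pmax(tl, 0)
        )
      )
    })
    if (trunc_count > 0) {
      warn(sprintf("simulate_phenotypes: truncated %d negative length draw(s) at 0",
                   trunc_count))
    }
    attr(res, "truncated_lengths") <- trunc_count
    res
  })
  relocate(out, "population_id", "progeny_id", "depth_cm")
}
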