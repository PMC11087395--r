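# Shared fixtures, all built in code.

# A small variant table: `genos` is a named list of per-sample genotype
# vectors over the same sites.
make_vt <- function(chromosome, position_bp, ref, alt, genos) {
  tab <- tibble::tibble(chromosome = as.character(chromosome),
                        position_bp = as.integer(position_bp),
                        ref_allele = ref, alt_allele = alt)
  for (s in names(genos)) tab[[s]] <- genos[[s]]
  tab
}

# Random variant table with n sites and given samples (homozygous calls
# plus optional het/missing noise), for round-trip and distance tests.
random_vt <- function(n = 50, samples = c("S1", "S2", "S3"), seed = 42,
                      het_rate = 0.1, missing_rate = 0.05) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    genos <- lapply(setNames(samples, samples), function(s) {
      g <- sample(c("0/0", "1/1"), n, replace = TRUE)
      g[runif(n) < het_rate] <- "0/1"
      g[runif(n) < missing_rate] <- NA_character_
      g
    })
    make_vt("1", sort(sample.int(1e6, n)), ref, unname(alt), genos)
  })
}

# A miniature simulation configuration for fast end-to-end tests: same
# genome and parents as the default, but fewer progeny.
tiny_config <- function(seed = 1L, n_scale = 0.25) {
  specs <- default_population_specs()
  specs$n_progeny <- pmax(8L, as.integer(round(specs$n_progeny * n_scale)))
  simulation_config(seed = seed, population_specs = specs)
}

# Reference with a single named chromosome from an explicit sequence.
ref_from_seq <- function(seq, name = "1") {
  r <- Biostrings::DNAStringSet(seq)
  names(r) <- name
  r
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b), label = paste("setequal(", paste(a, collapse = ","),
                                            ";", paste(b, collapse = ","), ")"))
}
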