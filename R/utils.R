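# Internal helpers shared across modules.

# Named RNG substream: every stochastic operation derives its own 32-bit seed
# from the master seed plus a stream label, so adding a new consumer never
# shifts the draws of an existing one.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  p <- 2147483629  # large prime below 2^31
  h <- (abs(seed) %% p)
  for (b in utf8ToInt(stream)) h <- (h * 69069 + b) %% p
  h <- (h * 69069 + 1) %% p
  as.integer(h) + 1L
}

with_sub_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(sub_seed(seed, stream))
  force(code)
}

# Genotype class vocabulary used throughout the package.
GT_CLASSES <- c("recipient_hom", "het", "donor_hom")

# Semicolon-joined label sets (utility sets, provenance lists).
join_set <- function(x) paste(sort(unique(x)), collapse = ";")
split_set <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Dosage coding of the donor ("positive") allele: recipient-hom 0, het 1,
# donor-hom 2, missing NA.
class_to_dosage <- function(class) {
  unname(c(recipient_hom = 0, het = 1, donor_hom = 2)[class])
}

dosage_to_class <- function(dosage) {
  unname(c("recipient_hom", "het", "donor_hom")[dosage + 1L])
}

`%theninform%` <- function(cond, msg) {
  if (isTRUE(cond)) rlang::inform(msg)
  invisible(cond)
}

stop_kaspanel <- function(msg, class = "kaspanel_error") {
  rlang::abort(msg, class = class)
}
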