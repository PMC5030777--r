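# Shared low-level helpers.

#' Round half away from zero
#'
#' Fixed-point rounding used for all user-facing report columns (base R
#' `round()` rounds half to even, which does not match how fold changes are
#' conventionally printed in expression tables).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Normalize a nucleotide string for comparison: uppercase, RNA -> DNA alphabet.
dna_norm <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Reverse complement of a plain character vector (DNA alphabet; U mapped to T).
revcomp <- function(x) {
  x <- dna_norm(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Random DNA string(s).
random_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
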