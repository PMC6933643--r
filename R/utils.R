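#' @import data.table
#' @importFrom stats rnorm runif rbinom median mad setNames na.omit
#' @importFrom utils head tail write.table
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 1299721) %% 2147483587) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform integer draw(s) from [lo, hi], immune to sample()'s scalar gotcha.
sample_range <- function(lo, hi, n = 1L) {
  if (hi < lo) stopf("empty sampling range [%s, %s]", lo, hi)
  as.integer(lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
}
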