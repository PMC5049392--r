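#' @importFrom methods new validObject is setClass setGeneric setMethod slot
#' @importClassesFrom Biostrings DNAStringSet
#' @importMethodsFrom Biostrings reverseComplement
#' @importFrom stats cor phyper rgeom rnorm runif sd setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a substream seed from a base seed and a counter, kept inside the
# 32-bit integer range so stage order never changes results.
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter)) %%
               .Machine$integer.max)
}

DNA_BASES <- c("A", "C", "G", "T")

reverseComplementChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

checkComposition <- function(freq) {
  if (!is.numeric(freq) || is.null(names(freq)) ||
      !setequal(names(freq), DNA_BASES))
    stop("composition must be a numeric vector with names A, C, G, T")
  freq <- freq[DNA_BASES]
  if (any(freq < 0)) stop("composition frequencies must be non-negative")
  # printed compositions are often rounded ratios (e.g. 0.33/0.16/0.16/0.34
  # sums to 0.99); renormalize, but reject anything far from a proportion
  if (abs(sum(freq) - 1) > 0.05)
    stop("composition frequencies must sum to ~1 (got ", sum(freq), ")")
  freq / sum(freq)
}

#' Grapevine-like promoter base composition
#'
#' AT-rich base frequencies typical of plant promoters
#' (A:C:G:T = 0.33:0.16:0.16:0.34), used as the default background for
#' random-promoter generation and synthetic genomes.
#'
#' @return Named numeric vector of base probabilities (A, C, G, T).
#' @export
plantPromoterComposition <- function() {
  c(A = 0.33, C = 0.16, G = 0.16, T = 0.34)
}

# Sample a single random DNA string of length n under a base composition.
randomDnaString <- function(n, freq) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = freq), collapse = "")
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
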