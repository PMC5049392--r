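# Independent brute-force oracles used to validate the fast paths.

# Naive scanner: test every offset on both strands by direct substring
# equality against the concrete motif set (windows computed with base
# substring, no Biostrings machinery).
oracleScan <- function(seq, motifs, bothStrands = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hits <- list()
  for (m in motifs) {
    w <- nchar(m)
    if (n < w) next
    starts <- seq_len(n - w + 1L)
    wins <- substring(seq, starts, starts + w - 1L)
    plus <- starts[wins == m]
    if (length(plus))
      hits[[length(hits) + 1L]] <- data.frame(
        start = plus, strand = "+", concrete_seq = m,
        stringsAsFactors = FALSE)
    if (bothStrands) {
      minus <- starts[wins == rc1(m)]
      if (length(minus))
        hits[[length(hits) + 1L]] <- data.frame(
          start = minus, strand = "-", concrete_seq = m,
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), strand = character(),
                      concrete_seq = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand, out$concrete_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric upper tail: enumerate every size-n subset of a
# population of N genes (K carrying the motif) and count subsets with at
# least `obs` carriers. Feasible for N <= 12.
oracleHyperUpper <- function(N, K, n, obs) {
  genes <- seq_len(N)
  carriers <- seq_len(K)
  if (n == 0) return(as.numeric(obs <= 0))
  sets <- utils::combn(genes, n)
  hits <- apply(sets, 2, function(s) sum(s %in% carriers) >= obs)
  mean(hits)
}

# Mutual-rank neighborhood by explicit loops over the full correlation
# matrix, independent of the package's vectorized ranking.
oracleMutualRank <- function(mat, guide) {
  genes <- rownames(mat)
  cm <- matrix(NA_real_, length(genes), length(genes),
               dimnames = list(genes, genes))
  for (a in genes) for (b in genes) cm[a, b] <- cor(mat[a, ], mat[b, ])
  descRank <- function(values, target) {
    sum(values > values[[target]]) +
      (sum(values == values[[target]]) + 1) / 2
  }
  others <- setdiff(genes, guide)
  res <- data.frame(gene = others, pcc = NA_real_, mr = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in others) {
    gl <- cm[guide, setdiff(genes, guide)]
    r1 <- descRank(gl, g)
    tl <- cm[g, setdiff(genes, g)]
    r2 <- descRank(tl, guide)
    res[res$gene == g, "pcc"] <- cm[guide, g]
    res[res$gene == g, "mr"] <- sqrt(r1 * r2)
  }
  res[order(res$mr, -res$pcc, res$gene), , drop = FALSE]
}

# Random DNA string helper for property tests.
randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# A tiny deterministic synthetic dataset shared by several tests.
smallSimulation <- function(seed = 42, ...) {
  spec <- simulationSpec(nGenes = 200, nTargetGenes = 30, regulonSize = 15,
                         nControlGenes = 30, nSamples = 12, seed = seed, ...)
  sim <- simulateGenome(spec)
  list(spec = spec, sim = sim,
       promoters = extractPromoters(sim$genome, sim$genes))
}
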