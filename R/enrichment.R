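#' Generate composition-matched random promoters
#'
#' Draws i.i.d. bases at the given composition to produce one random
#' promoter per requested length. Used as the null background for the
#' permutation occurrence test ("randomized promoters of similar size":
#' same number of promoters, same per-promoter lengths as the tested
#' set).
#'
#' @param lengths Integer vector of promoter lengths (all positive).
#' @param composition Named base probabilities (A, C, G, T); default the
#'   AT-rich plant promoter composition [plantPromoterComposition()].
#' @param seed RNG seed; the same seed reproduces the same sequences.
#' @return A [PromoterSet-class] named `random_0001`, `random_0002`, ...
#' @export
randomPromoters <- function(lengths,
                            composition = plantPromoterComposition(),
                            seed = 1L) {
  composition <- checkComposition(composition)
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L || anyNA(lengths) || any(lengths < 1L))
    stop("'lengths' must be positive integers")
  seqs <- withSeed(seed, {
    all <- sample(DNA_BASES, sum(lengths), replace = TRUE, prob = composition)
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1L
    vapply(seq_along(lengths),
           function(i) paste(all[starts[i]:ends[i]], collapse = ""),
           character(1))
  })
  names(seqs) <- sprintf("random_%04d", seq_along(seqs))
  PromoterSet(seqs)
}

#' Hypergeometric motif-presence test
#'
#' One-sided upper-tail test of whether more genes in `geneSet` carry the
#' motif in their promoter than expected from the gene universe: with
#' population size `|universe|`, successes = universe genes carrying the
#' motif, and draws = `|geneSet|`, reports `P(X >= observed)`.
#'
#' @param geneSet Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param presence Presence index from [presenceIndex()].
#' @param universe Character vector of all scanned gene ids.
#' @param motif Motif name.
#' @return List with `n_set_with_motif`, `n_universe_with_motif`, and
#'   `hypergeom_p`.
#' @export
hypergeometricPresenceTest <- function(geneSet, presence, universe, motif) {
  outside <- setdiff(geneSet, universe)
  if (length(outside) > 0)
    stop("genes in set absent from universe: ",
         paste(head(outside, 5), collapse = ", "))
  if (!motif %in% names(presence))
    stop("motif '", motif, "' not in presence index")
  with_motif <- intersect(presence[[motif]], universe)
  K <- length(with_motif)
  N <- length(universe)
  n <- length(unique(geneSet))
  obs <- length(intersect(geneSet, with_motif))
  p <- phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
  list(n_set_with_motif = obs, n_universe_with_motif = K, hypergeom_p = p)
}

#' Permutation test of total motif occurrences
#'
#' Compares the total both-strand occurrence count of a motif in the
#' promoters of a gene set against a null of freshly simulated random
#' promoters matched to the set's promoter number and lengths, drawn at
#' the given base composition. The empirical P-value uses the add-one
#' rule `(1 + #\{null >= observed\}) / (nPerm + 1)`, and fold enrichment is
#' `observed / mean(null)`. Each permutation's RNG stream is derived from
#' `seed` and the permutation counter, so results do not depend on
#' evaluation order.
#'
#' @param geneSet Character vector of gene ids; all must have promoters.
#' @param promoters [PromoterSet-class] covering at least `geneSet`.
#' @param catalog [MotifCatalog-class].
#' @param motif Motif name in `catalog`.
#' @param nPerm Number of permutations (default 1000).
#' @param composition Null base composition (default
#'   [plantPromoterComposition()]).
#' @param seed RNG seed.
#' @return List with `observed`, `null_mean`, `fold_enrichment`
#'   (`NA` with a warning when the null mean is zero), and `empirical_p`.
#' @export
permutationOccurrenceTest <- function(geneSet, promoters, catalog, motif,
                                      nPerm = 1000,
                                      composition = plantPromoterComposition(),
                                      seed = 1L) {
  stopifnot(is(promoters, "PromoterSet"), is(catalog, "MotifCatalog"))
  if (nPerm < 1) stop("'nPerm' must be at least 1")
  set_prom <- promoters[unique(geneSet)]
  motifs <- expandedMotifs(catalog, motif)
  dicts <- motifDicts(motifs)
  observed <- countWithDicts(set_prom, dicts)
  lens <- unname(effectiveLength(set_prom))
  composition <- checkComposition(composition)
  null <- vapply(seq_len(nPerm), function(i) {
    rp <- withSeed(deriveSeed(seed, i), {
      Biostrings::DNAStringSet(vapply(lens, randomDnaString,
                                      character(1), freq = composition))
    })
    countWithDicts(rp, dicts)
  }, numeric(1))
  null_mean <- mean(null)
  fold <- if (null_mean == 0) {
    warning("null mean occurrence count is zero; fold enrichment undefined")
    NA_real_
  } else observed / null_mean
  list(observed = observed, null_mean = null_mean, fold_enrichment = fold,
       empirical_p = (1 + sum(null >= observed)) / (nPerm + 1))
}

#' Two-tier significance call from the paired tests
#'
#' A motif is called enriched only when both the hypergeometric presence
#' test and the permutation occurrence test agree: `"p<0.01 strict"` when
#' both P-values are below 0.01, `"p<0.05"` when both are below 0.05, and
#' `"ns"` otherwise.
#'
#' @param hypergeomP Hypergeometric P-value.
#' @param empiricalP Permutation empirical P-value.
#' @return One of `"ns"`, `"p<0.05"`, `"p<0.01 strict"`.
#' @export
classifySignificance <- function(hypergeomP, empiricalP) {
  stopifnot(hypergeomP >= 0, hypergeomP <= 1, empiricalP >= 0, empiricalP <= 1)
  if (hypergeomP < 0.01 && empiricalP < 0.01) "p<0.01 strict"
  else if (hypergeomP < 0.05 && empiricalP < 0.05) "p<0.05"
  else "ns"
}

#' Full enrichment panel for a gene set
#'
#' Runs the hypergeometric presence test and the permutation occurrence
#' test for every motif in the catalog and combines them into one result
#' table with the two-tier significance call.
#'
#' @inheritParams permutationOccurrenceTest
#' @param presence Presence index over the scanned universe.
#' @param universe Character vector of all scanned gene ids.
#' @param geneSetId Label recorded in the output (default `"set"`).
#' @return data.frame with one row per motif: `motif`, `gene_set_id`,
#'   `n_set_with_motif`, `n_universe_with_motif`, `hypergeom_p`,
#'   `observed_occurrences`, `null_mean_occurrences`, `fold_enrichment`,
#'   `empirical_p`, `tier`.
#' @export
motifEnrichment <- function(geneSet, promoters, catalog, presence, universe,
                            nPerm = 1000,
                            composition = plantPromoterComposition(),
                            seed = 1L, geneSetId = "set") {
  rows <- lapply(seq_along(motifNames(catalog)), function(i) {
    nm <- motifNames(catalog)[i]
    hg <- hypergeometricPresenceTest(geneSet, presence, universe, nm)
    pt <- permutationOccurrenceTest(geneSet, promoters, catalog, nm,
                                    nPerm = nPerm, composition = composition,
                                    seed = deriveSeed(seed, i * 1000003))
    data.frame(motif = nm, gene_set_id = geneSetId,
               n_set_with_motif = hg$n_set_with_motif,
               n_universe_with_motif = hg$n_universe_with_motif,
               hypergeom_p = hg$hypergeom_p,
               observed_occurrences = pt$observed,
               null_mean_occurrences = pt$null_mean,
               fold_enrichment = pt$fold_enrichment,
               empirical_p = pt$empirical_p,
               tier = classifySignificance(hg$hypergeom_p, pt$empirical_p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
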