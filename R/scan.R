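# Build forward and reverse-complement PDicts for a set of concrete
# motifs, split by width (PDict requires constant width).
motifDicts <- function(motifs) {
  widths <- nchar(motifs)
  lapply(split(motifs, widths), function(m) {
    list(motifs = m, width = nchar(m[[1]]),
         fwd = Biostrings::PDict(Biostrings::DNAStringSet(m)),
         rev = Biostrings::PDict(
           Biostrings::reverseComplement(Biostrings::DNAStringSet(m))))
  })
}

matchDictOnSeq <- function(dicts, subject, bothStrands = TRUE) {
  hits <- list()
  for (d in dicts) {
    if (length(subject) < d$width) next
    for (strand in if (bothStrands) c("+", "-") else "+") {
      pd <- if (strand == "+") d$fwd else d$rev
      m <- Biostrings::matchPDict(pd, subject)
      starts <- IRanges::start(m)
      nhit <- lengths(starts)
      if (sum(nhit) == 0) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = unlist(starts, use.names = FALSE),
        strand = strand,
        concrete_seq = rep(d$motifs, nhit),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), strand = character(),
                      concrete_seq = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Scan a single sequence for exact motif matches on both strands
#'
#' Reports every exact, possibly overlapping occurrence of any motif in
#' `motifs`. A minus-strand hit is an occurrence of the reverse complement
#' of a motif in `seq`; it is reported at its forward-coordinate start
#' with `strand = "-"` and `concrete_seq` naming the forward-strand motif.
#' `N` positions never match. A palindromic motif therefore yields one
#' record per strand at the same position.
#'
#' @param seq A single sequence (character or [Biostrings::DNAString])
#'   over \{A, C, G, T, N\}.
#' @param motifs Character vector of concrete motif sequences.
#' @param bothStrands Scan the reverse complement too (default TRUE).
#' @return data.frame with columns `start` (1-based position in `seq`),
#'   `strand`, `concrete_seq`, sorted by (start, strand).
#' @export
scanSequence <- function(seq, motifs, bothStrands = TRUE) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  hits <- matchDictOnSeq(motifDicts(motifs), seq, bothStrands)
  hits <- hits[order(hits$start, hits$strand, hits$concrete_seq), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan all promoters of a PromoterSet against a motif catalog
#'
#' Runs the exact both-strand scan of every expanded concrete motif over
#' every promoter and reports matches in TSS-relative coordinates: a match
#' starting at offset -60 occupies bases 60 down to 60 - width + 1
#' upstream of the TSS. Overlapping matches are all counted.
#'
#' @param promoters A [PromoterSet-class].
#' @param catalog A [MotifCatalog-class].
#' @param bothStrands Scan both strands (default TRUE).
#' @return The occurrence table: a data.frame with columns `gene_id`,
#'   `motif`, `concrete_seq`, `tss_offset` (negative; offset of the match
#'   start), `strand`, deterministically ordered by
#'   (gene_id, motif, tss_offset, strand).
#' @export
scanPromoters <- function(promoters, catalog, bothStrands = TRUE) {
  stopifnot(is(promoters, "PromoterSet"), is(catalog, "MotifCatalog"))
  if (length(promoters) == 0L) stop("promoter set is empty")
  seqs <- promoterSeqs(promoters)
  lens <- Biostrings::width(seqs)
  # scan all promoters in one pass per (motif, strand): concatenate with a
  # single N spacer (N never matches, so no window can cross a boundary)
  # and map hit positions back to promoters
  concat <- Biostrings::DNAString(
    paste(as.character(seqs), collapse = "N"))
  starts_in_concat <- cumsum(c(1L, lens[-length(lens)] + 1L))
  out <- list()
  for (nm in motifNames(catalog)) {
    h <- matchDictOnSeq(motifDicts(expandedMotifs(catalog, nm)), concat,
                        bothStrands)
    if (nrow(h) == 0) next
    idx <- findInterval(h$start, starts_in_concat)
    local_start <- h$start - starts_in_concat[idx] + 1L
    out[[length(out) + 1L]] <-
      data.frame(gene_id = names(seqs)[idx], motif = nm,
                 concrete_seq = h$concrete_seq,
                 tss_offset = local_start - lens[idx] - 1L,
                 strand = h$strand, stringsAsFactors = FALSE)
  }
  occ <- if (length(out) == 0L)
    data.frame(gene_id = character(), motif = character(),
               concrete_seq = character(), tss_offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  occ <- occ[order(occ$gene_id, occ$motif, occ$tss_offset, occ$strand), ,
             drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Per-gene motif presence index
#'
#' Collapses an occurrence table to, per motif, the set of genes carrying
#' at least one match. Motifs in the catalog with no hits map to empty
#' sets.
#'
#' @param occurrences Occurrence table from [scanPromoters()].
#' @param catalog Optional [MotifCatalog-class]; if given, every catalog
#'   motif appears in the result.
#' @return Named list of sorted gene-id character vectors.
#' @export
presenceIndex <- function(occurrences, catalog = NULL) {
  idx <- lapply(split(occurrences$gene_id, occurrences$motif),
                function(g) sort(unique(g)))
  if (!is.null(catalog)) {
    empty <- setdiff(motifNames(catalog), names(idx))
    idx[empty] <- list(character())
    idx <- idx[motifNames(catalog)]
  }
  idx
}

#' Total both-strand occurrence count of one motif over sequences
#'
#' Fast counting path used by the permutation test: counts, without
#' recording positions, every exact occurrence of the motif's expanded
#' set (both strands) over a set of sequences.
#'
#' @param seqs A [PromoterSet-class] or [Biostrings::DNAStringSet].
#' @param motifs Character vector of concrete motif sequences.
#' @return Single integer occurrence count.
#' @export
countMotifOccurrences <- function(seqs, motifs) {
  countWithDicts(seqs, motifDicts(motifs))
}

# Counting core with pre-built dictionaries, so repeated counting (the
# permutation loop) does not pay PDict construction per call.
countWithDicts <- function(seqs, dicts) {
  if (is(seqs, "PromoterSet")) seqs <- promoterSeqs(seqs)
  total <- 0L
  for (d in dicts) {
    ok <- Biostrings::width(seqs) >= d$width
    if (!any(ok)) next
    total <- total +
      sum(Biostrings::vcountPDict(d$fwd, seqs[ok])) +
      sum(Biostrings::vcountPDict(d$rev, seqs[ok]))
  }
  total
}

#' Read and write occurrence tables as TSV
#'
#' @param path TSV file path.
#' @return `readOccurrences`: occurrence table data.frame.
#' @export
readOccurrences <- function(path) {
  readTsv(path, colClasses = c(gene_id = "character", motif = "character",
                               concrete_seq = "character",
                               tss_offset = "integer", strand = "character"))
}

#' @rdname readOccurrences
#' @param occurrences Occurrence table from [scanPromoters()].
#' @export
writeOccurrences <- function(occurrences, path) {
  writeTsv(occurrences, path)
}
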