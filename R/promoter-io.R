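#' Parse gene models from a GFF3 annotation
#'
#' Reads gene features from a GFF3 file and derives each gene's
#' transcription start site (TSS) from the gene-feature boundary: the
#' feature start for plus-strand genes and the feature end for
#' minus-strand genes. Coordinates follow the GFF3 convention (1-based,
#' inclusive).
#'
#' @param path Path to a GFF3 file containing `gene` features with `ID`
#'   attributes.
#' @param featureType Feature type to treat as genes (default `"gene"`).
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, and `tss`.
#' @export
parseAnnotation <- function(path, featureType = "gene") {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == featureType]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), tss = integer(),
                      stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("gene features must carry ID attributes")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("gene features must be stranded (+ or -)")
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, start = st, end = en,
             tss = ifelse(strand == "+", st, en),
             stringsAsFactors = FALSE)
}

#' Extract promoter sequences upstream of each TSS
#'
#' Extracts the `length` bases immediately upstream of every gene's TSS.
#' For plus-strand genes this is `genome[tss - length .. tss - 1]`; for
#' minus-strand genes the reverse complement of
#' `genome[tss + 1 .. tss + length]`, so that in every returned sequence
#' the rightmost base is adjacent to the TSS (offset -1). Promoters
#' running off a contig edge are truncated, not padded or dropped, so the
#' gene universe is preserved.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file) of contig sequences.
#' @param genes Gene table as returned by [parseAnnotation()].
#' @param length Promoter length in bases upstream of the TSS
#'   (default 1000).
#' @return A [PromoterSet-class] with one entry per input gene.
#' @export
extractPromoters <- function(genome, genes, length = 1000) {
  if (is.character(genome)) genome <- readGenomeFasta(genome)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be a positive integer")
  missing_chroms <- setdiff(unique(genes$chrom), names(genome))
  if (base::length(missing_chroms) > 0)
    stop("chromosomes absent from genome: ",
         paste(missing_chroms, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table")
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  n <- nrow(genes)
  out <- character(n)
  for (i in seq_len(n)) {
    tss <- genes$tss[i]
    clen <- contig_len[[genes$chrom[i]]]
    if (genes$strand[i] == "+") {
      from <- max(1L, tss - length)
      to <- tss - 1L
      s <- if (to < from) "" else
        as.character(Biostrings::subseq(genome[[genes$chrom[i]]], from, to))
    } else {
      from <- tss + 1L
      to <- min(clen, tss + length)
      s <- if (to < from) "" else
        reverseComplementChar(
          as.character(Biostrings::subseq(genome[[genes$chrom[i]]], from, to)))
    }
    out[i] <- s
  }
  names(out) <- genes$gene_id
  PromoterSet(out)
}

readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first word as the name
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Read and write promoter FASTA files
#'
#' `readPromoterFasta` reads a FASTA file into a [PromoterSet-class],
#' uppercasing soft-masked bases and rejecting records whose sequences
#' contain letters outside \{A, C, G, T, N\}. `writePromoterFasta` writes a
#' `PromoterSet` back out; the two round-trip exactly.
#'
#' @param path FASTA file path.
#' @return `readPromoterFasta`: a [PromoterSet-class].
#' @export
readPromoterFasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("failed to parse FASTA '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  if (base::length(x) == 0L) return(PromoterSet(character()))
  chars <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("sequences contain letters outside {A,C,G,T,N}: ",
         paste(head(names(x)[bad], 5), collapse = ", "))
  names(chars) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  PromoterSet(chars)
}

#' @rdname readPromoterFasta
#' @param promoters A [PromoterSet-class].
#' @export
writePromoterFasta <- function(promoters, path) {
  Biostrings::writeXStringSet(promoterSeqs(promoters), path, width = 70L)
  invisible(path)
}
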