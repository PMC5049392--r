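#' PromoterSet: gene-indexed upstream promoter sequences
#'
#' Holds one upstream sequence per gene, oriented so that reading left to
#' right moves toward the transcription start site (TSS): the last base of
#' every sequence sits at TSS-relative offset -1, immediately upstream of
#' the TSS. Minus-strand promoters are stored reverse-complemented so this
#' convention holds for every gene. Sequences may be shorter than the
#' nominal promoter length when a gene lies near a contig boundary; the
#' effective length is simply the stored width.
#'
#' @slot seqs A named [Biostrings::DNAStringSet] over the alphabet
#'   \{A, C, G, T, N\}; names are unique gene identifiers.
#' @export
setClass("PromoterSet", representation(seqs = "DNAStringSet"))

validPromoterSet <- function(object) {
  msg <- character()
  nms <- names(object@seqs)
  if (length(object@seqs) > 0 && (is.null(nms) || anyNA(nms) || any(nms == "")))
    msg <- c(msg, "every promoter must carry a gene identifier name")
  if (anyDuplicated(nms))
    msg <- c(msg, "gene identifiers must be unique")
  if (length(object@seqs) > 0) {
    af <- Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)
    bad <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
    if (sum(bad) > 0)
      msg <- c(msg, paste0("sequences contain letters outside {A,C,G,T,N}: ",
                           paste(names(bad)[bad > 0], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("PromoterSet", validPromoterSet)

#' Construct a PromoterSet
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector
#'   of promoter sequences. Lowercase (soft-masked) bases are uppercased.
#' @return A [PromoterSet-class] object.
#' @export
PromoterSet <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  new("PromoterSet", seqs = seqs)
}

#' @describeIn PromoterSet-class Number of promoters.
#' @param x A `PromoterSet`.
#' @export
setMethod("length", "PromoterSet", function(x) length(x@seqs))

#' Accessors for PromoterSet
#'
#' `geneIds` returns the gene identifiers, `promoterSeqs` the underlying
#' `DNAStringSet`, and `effectiveLength` the per-gene stored sequence length
#' (equal to the nominal promoter length except where truncated at a contig
#' boundary).
#'
#' @param x A [PromoterSet-class].
#' @return `geneIds`: character vector; `promoterSeqs`: `DNAStringSet`;
#'   `effectiveLength`: named integer vector.
#' @export
geneIds <- function(x) names(x@seqs)

#' @rdname geneIds
#' @export
promoterSeqs <- function(x) x@seqs

#' @rdname geneIds
#' @export
effectiveLength <- function(x) setNames(Biostrings::width(x@seqs), names(x@seqs))

#' @describeIn PromoterSet-class Subset by gene id or index.
#' @param i Gene identifiers or indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    missing_ids <- setdiff(i, names(x@seqs))
    if (length(missing_ids))
      stop("genes absent from PromoterSet: ",
           paste(head(missing_ids, 5), collapse = ", "))
  }
  new("PromoterSet", seqs = x@seqs[i])
})

setMethod("show", "PromoterSet", function(object) {
  n <- length(object@seqs)
  cat("PromoterSet with", n, "promoters\n")
  if (n > 0) {
    w <- Biostrings::width(object@seqs)
    cat("  effective length:", min(w), "-", max(w), "bases\n")
    cat("  genes:", paste(head(names(object@seqs), 3), collapse = ", "),
        if (n > 3) "..." else "", "\n")
  }
})

#' MotifCatalog: degenerate consensus motifs and their concrete expansions
#'
#' A named collection of IUPAC consensus patterns, each stored together
#' with the complete set of concrete (unambiguous) sequences it denotes.
#' Scanning and enrichment operate on the expanded sets: matching is exact
#' string equality, not position-weight scoring.
#'
#' @slot patterns Named character vector of IUPAC consensus patterns.
#' @slot expanded Named list (same names) of character vectors holding
#'   every concrete sequence each pattern expands to.
#' @export
setClass("MotifCatalog",
         representation(patterns = "character", expanded = "list"))

setValidity("MotifCatalog", function(object) {
  msg <- character()
  if (is.null(names(object@patterns)) || anyDuplicated(names(object@patterns)))
    msg <- c(msg, "motif names must be present and unique")
  if (!identical(names(object@patterns), names(object@expanded)))
    msg <- c(msg, "expanded sets must parallel the patterns")
  for (nm in names(object@patterns)) {
    ex <- object@expanded[[nm]]
    if (anyDuplicated(ex))
      msg <- c(msg, paste0("expanded set of '", nm, "' contains duplicates"))
    if (length(ex) != prod(nchar(iupacBaseSets(object@patterns[[nm]]))) &&
        length(ex) > 0)
      msg <- c(msg, paste0("expanded set size of '", nm,
                           "' does not equal the product of degeneracies"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MotifCatalog-class
#' @param patterns Named character vector of IUPAC patterns.
#' @return A [MotifCatalog-class] object with all patterns expanded.
#' @export
MotifCatalog <- function(patterns) {
  if (is.null(names(patterns)) || any(names(patterns) == ""))
    stop("'patterns' must be a named character vector")
  expanded <- lapply(patterns, expandConsensus)
  new("MotifCatalog", patterns = patterns, expanded = expanded)
}

#' @describeIn MotifCatalog-class Number of consensus motifs.
#' @param x A `MotifCatalog`.
#' @export
setMethod("length", "MotifCatalog", function(x) length(x@patterns))

#' Accessors for MotifCatalog
#'
#' @param x A [MotifCatalog-class].
#' @param name Motif name; must exist in the catalog.
#' @return `motifNames`: character vector of motif names; `motifPattern`:
#'   the IUPAC pattern for one motif; `expandedMotifs`: character vector of
#'   that motif's concrete sequences; `totalExpanded`: number of distinct
#'   concrete sequences across the whole catalog.
#' @export
motifNames <- function(x) names(x@patterns)

#' @rdname motifNames
#' @export
motifPattern <- function(x, name) {
  checkMotifName(x, name)
  unname(x@patterns[[name]])
}

#' @rdname motifNames
#' @export
expandedMotifs <- function(x, name) {
  checkMotifName(x, name)
  x@expanded[[name]]
}

#' @rdname motifNames
#' @export
totalExpanded <- function(x) length(unique(unlist(x@expanded, use.names = FALSE)))

checkMotifName <- function(catalog, name) {
  if (!name %in% names(catalog@patterns))
    stop("motif '", name, "' not in catalog (have: ",
         paste(names(catalog@patterns), collapse = ", "), ")")
  invisible(TRUE)
}

setMethod("show", "MotifCatalog", function(object) {
  cat("MotifCatalog with", length(object@patterns), "consensus motifs,",
      totalExpanded(object), "distinct concrete sequences\n")
  for (nm in names(object@patterns))
    cat(sprintf("  %-10s %-10s (%d concrete)\n", nm, object@patterns[[nm]],
                length(object@expanded[[nm]])))
})

#' BinProfile: TSS-anchored binned occurrence profile for one motif
#'
#' Occurrences are binned in fixed-width windows walking upstream from the
#' TSS: bin 1 covers offsets -binSize..-1, bin 2 the next window, and so
#' on. The baseline is the mean count over the distal half of the bins
#' (offsets -span/2-1 .. -span for the defaults, i.e. -501..-1000), and
#' `adjusted` is `counts - baseline`.
#'
#' @slot motif Motif name.
#' @slot binSize Bin width in bases.
#' @slot span Profile span in bases (promoter length covered).
#' @slot counts Integer occurrence count per bin (length span/binSize).
#' @slot baseline Mean count of the distal-half bins (NA until
#'   [baselineAdjust()] is applied).
#' @slot adjusted Baseline-subtracted counts (NA until adjusted).
#' @export
setClass("BinProfile",
         representation(motif = "character", binSize = "integer",
                        span = "integer", counts = "integer",
                        baseline = "numeric", adjusted = "numeric"))

setValidity("BinProfile", function(object) {
  msg <- character()
  nb <- object@span / object@binSize
  if (nb != as.integer(nb) || nb < 2 || as.integer(nb) %% 2L != 0L)
    msg <- c(msg, "span must be an even multiple of binSize")
  if (length(object@counts) != nb)
    msg <- c(msg, "counts must hold one value per bin")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinProfile", function(object) {
  cat("BinProfile for motif '", object@motif, "': ", sum(object@counts),
      " occurrences in ", length(object@counts), " bins of ",
      object@binSize, " bp\n", sep = "")
  if (!is.na(object@baseline))
    cat("  distal baseline:", format(object@baseline), "per bin\n")
})

#' @rdname BinProfile-class
#' @param x A `BinProfile`.
#' @return `binCounts`: integer vector of raw per-bin counts.
#' @export
binCounts <- function(x) x@counts

#' @rdname BinProfile-class
#' @return `binBaseline`: the distal baseline (NA before adjustment).
#' @export
binBaseline <- function(x) x@baseline

#' @rdname BinProfile-class
#' @return `adjustedCounts`: baseline-subtracted counts (NA before
#'   adjustment).
#' @export
adjustedCounts <- function(x) x@adjusted
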