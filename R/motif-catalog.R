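# Per-position base sets for an IUPAC pattern, as a character vector of
# concatenated bases (e.g. "H" -> "ACT").
iupacBaseSets <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0)
    stop("invalid IUPAC code '", bad[[1]], "' in pattern '", pattern, "'")
  unname(map[chars])
}

#' Expand a degenerate IUPAC consensus into concrete sequences
#'
#' Computes the Cartesian product of the per-position base sets of an
#' IUPAC pattern: `"HBACGTCD"` (H = A/C/T, B = C/G/T, D = A/G/T) expands
#' to 3 x 3 x 3 = 27 concrete octamers. Patterns without degenerate codes
#' expand to themselves.
#'
#' @param pattern Non-empty string of IUPAC nucleotide codes.
#' @return Sorted character vector of distinct concrete sequences; its
#'   length equals the product of per-position degeneracies.
#' @export
expandConsensus <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stop("'pattern' must be a single non-empty string")
  sets <- strsplit(iupacBaseSets(toupper(pattern)), "")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' The HY5/UV-B cis-regulatory element catalog
#'
#' The five consensus binding sites used for promoter scanning: the three
#' degenerate ACGT-core octamer boxes bound by HY5-class bZIP factors
#' (C-box `HBACGTCD`, C/A-box `HBACGTAD`, C/G-box `HBACGTGD`; each
#' expands to 27 octamers) and the two fixed UV-B-response elements, the
#' T/G-box `CCACGTTC` and the E-box `CAATTGC`. Together they expand to 83
#' distinct concrete sequences.
#'
#' @return A [MotifCatalog-class] with the five motifs.
#' @export
hy5MotifCatalog <- function() {
  MotifCatalog(c("C-box"   = "HBACGTCD",
                 "C/A-box" = "HBACGTAD",
                 "C/G-box" = "HBACGTGD",
                 "E-box"   = "CAATTGC",
                 "T/G-box" = "CCACGTTC"))
}

#' Read and write motif catalogs as YAML
#'
#' The on-disk form is a flat mapping from motif name to IUPAC pattern.
#'
#' @param path YAML file path.
#' @return `readMotifCatalog`: a [MotifCatalog-class].
#' @export
readMotifCatalog <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(names(x)))
    stop("catalog YAML must map motif names to IUPAC patterns")
  MotifCatalog(vapply(x, as.character, character(1)))
}

#' @rdname readMotifCatalog
#' @param catalog A [MotifCatalog-class].
#' @export
writeMotifCatalog <- function(catalog, path) {
  yaml::write_yaml(as.list(catalog@patterns), path)
  invisible(path)
}
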