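#' Normalize an expression matrix
#'
#' `log2p1` applies `log2(x + 1)` to counts-like values; `passthrough`
#' accepts an already-normalized matrix unchanged (e.g. variance
#' stabilized output of an external tool).
#'
#' @param mat Numeric genes-by-samples matrix with gene row names.
#' @param method `"log2p1"` or `"passthrough"`.
#' @return Numeric matrix of the same shape.
#' @export
normalizeExpression <- function(mat, method = c("log2p1", "passthrough")) {
  method <- match.arg(method)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("'mat' must be a numeric matrix")
  if (method == "passthrough") return(mat)
  if (any(mat < 0)) stop("log2p1 requires non-negative values")
  log2(mat + 1)
}

checkExpressionMatrix <- function(mat, guide) {
  if (is.null(rownames(mat))) stop("expression matrix must have gene row names")
  if (ncol(mat) < 3L) stop("at least 3 samples are required for correlation")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (!guide %in% rownames(mat)) stop("guide gene '", guide, "' not in matrix")
  if (sd(mat[guide, ]) == 0) stop("guide gene '", guide, "' has zero variance")
  invisible(TRUE)
}

#' Pearson correlation of every gene with a guide gene
#'
#' @param mat Normalized genes-by-samples matrix.
#' @param guide Guide gene id (present, non-constant).
#' @return Named numeric vector of PCC for every other gene; genes with
#'   zero variance get `NA` (undefined correlation).
#' @export
pccToGuide <- function(mat, guide) {
  checkExpressionMatrix(mat, guide)
  others <- setdiff(rownames(mat), guide)
  pcc <- suppressWarnings(as.vector(cor(mat[guide, ], t(mat[others, , drop = FALSE]))))
  names(pcc) <- others
  pcc
}

# Descending average rank of value v within vector x (v included in x).
descAvgRank <- function(x, v) sum(x > v) + (sum(x == v) + 1) / 2

#' Mutual-rank co-expression neighborhood of a guide gene
#'
#' For every gene, computes its Pearson correlation with the guide, the
#' descending-PCC rank of the gene in the guide's correlation profile,
#' the descending-PCC rank of the guide in the gene's own profile, and
#' the mutual rank `MR = sqrt(rank_guide_to_gene * rank_gene_to_guide)`
#' (lower = stronger reciprocal co-expression). Ties in PCC receive
#' average ranks; genes with zero expression variance are excluded before
#' ranking; the guide is excluded from its own neighborhood. The result
#' is sorted by MR ascending, PCC descending, then gene id.
#'
#' @param mat Normalized genes-by-samples matrix.
#' @param guide Guide gene id.
#' @return data.frame with columns `gene`, `pcc`, `rank_guide_to_gene`,
#'   `rank_gene_to_guide`, `mutual_rank`.
#' @export
mutualRankNeighborhood <- function(mat, guide) {
  checkExpressionMatrix(mat, guide)
  keep <- apply(mat, 1L, sd) > 0
  mat <- mat[keep, , drop = FALSE]
  cmat <- suppressWarnings(cor(t(mat)))
  genes <- setdiff(rownames(mat), guide)
  gi <- match(guide, rownames(cmat))
  pcc <- cmat[gi, genes]
  # guide -> gene: rank of each gene among the guide's correlations
  r_g2t <- vapply(pcc, function(v) descAvgRank(pcc, v), numeric(1))
  # gene -> guide: rank of the guide within each gene's own profile
  r_t2g <- vapply(genes, function(g) {
    row <- cmat[g, setdiff(rownames(cmat), g)]
    descAvgRank(row, cmat[g, gi])
  }, numeric(1))
  nb <- data.frame(gene = genes, pcc = unname(pcc),
                   rank_guide_to_gene = unname(r_g2t),
                   rank_gene_to_guide = unname(r_t2g),
                   mutual_rank = sqrt(unname(r_g2t) * unname(r_t2g)),
                   stringsAsFactors = FALSE)
  nb <- nb[order(nb$mutual_rank, -nb$pcc, nb$gene), , drop = FALSE]
  rownames(nb) <- NULL
  nb
}

#' Top-N co-expressed genes of a neighborhood
#'
#' Takes the first `n` entries of a neighborhood under the deterministic
#' ordering mutual rank ascending, PCC descending, gene id ascending.
#' Returns all genes when fewer than `n` exist.
#'
#' @param neighborhood Output of [mutualRankNeighborhood()].
#' @param n Number of co-expressed genes to retain (default 300).
#' @return Character vector of gene ids, best first.
#' @export
topCoexpressed <- function(neighborhood, n = 300) {
  if (n < 1) stop("'n' must be at least 1")
  nb <- neighborhood[order(neighborhood$mutual_rank, -neighborhood$pcc,
                           neighborhood$gene), , drop = FALSE]
  head(nb$gene, n)
}

#' Merge per-dataset co-expressed gene lists into an aggregate network
#'
#' Each input is one guide's top-N co-expressed gene list from one
#' dataset. The aggregate keeps one edge per (guide, target) with a
#' support count equal to the number of contributing (guide, dataset)
#' lists containing the target, and records dataset provenance.
#'
#' @param lists List of `list(guide =, dataset =, targets =)` entries; a
#'   (guide, dataset) pair may appear only once.
#' @return data.frame with columns `guide`, `target`, `support_count`,
#'   `datasets` (comma-separated provenance), ordered by
#'   (guide, decreasing support, target).
#' @export
aggregateNetworks <- function(lists) {
  if (length(lists) < 1) stop("at least one co-expression list is required")
  keys <- vapply(lists, function(x) paste(x$guide, x$dataset, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (guide, dataset) pair: ",
         gsub("\r", " / ", keys[duplicated(keys)][1]))
  edges <- do.call(rbind, lapply(lists, function(x) {
    data.frame(guide = x$guide, target = unique(x$targets),
               dataset = x$dataset, stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(edges, list(edges$guide, edges$target),
                                     drop = TRUE), function(d) {
    data.frame(guide = d$guide[1], target = d$target[1],
               support_count = nrow(d),
               datasets = paste(sort(d$dataset), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$guide, -agg$support_count, agg$target), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Overlap statistics between two gene lists
#'
#' @param listA,listB Character vectors of gene ids.
#' @return List with `shared_count`, `fraction_a`, `fraction_b` (the
#'   intersection size as a fraction of each list's length; 0 for empty
#'   lists).
#' @export
overlapStats <- function(listA, listB) {
  a <- unique(listA); b <- unique(listB)
  shared <- length(intersect(a, b))
  list(shared_count = shared,
       fraction_a = if (length(a) == 0) 0 else shared / length(a),
       fraction_b = if (length(b) == 0) 0 else shared / length(b))
}

#' Read and write expression matrices as TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns.
#'
#' @param path TSV file path.
#' @return `readExpressionMatrix`: numeric matrix with gene row names.
#' @export
readExpressionMatrix <- function(path) {
  df <- readTsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionMatrix
#' @param mat Numeric matrix with gene row names.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}
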