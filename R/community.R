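#' Integrate co-expression, promoter motifs, and ortholog evidence
#'
#' Builds the high-confidence community target set: a gene enters the
#' community network iff (i) it is a co-expression target with aggregate
#' support of at least `minSupport` networks, (ii) its promoter carries
#' at least one catalog motif, and (iii) it has at least one ortholog
#' evidence flag (differential expression in the TF loss-of-function
#' mutant, or a ChIP binding target of the orthologous factor). Nodes
#' carry full provenance: guides, per-motif presence, evidence flags, and
#' an optional pass-through functional category.
#'
#' @param aggregate Aggregate network from [aggregateNetworks()].
#' @param presence Presence index from [presenceIndex()].
#' @param evidence data.frame with column `gene_id` plus logical columns
#'   `hy5_mutant_DE` and `chip_binding_target` (genes absent from the
#'   table count as having no evidence), and optionally `category`.
#' @param minSupport Minimum total network support for inclusion
#'   (default 1).
#' @return data.frame with one row per included gene: `gene_id`,
#'   `guides` (comma separated), `support_count` (total supporting
#'   networks across guides), one logical `cre_<motif>` column per motif,
#'   `hy5_mutant_DE`, `chip_binding_target`, `category`.
#' @export
integrateCommunity <- function(aggregate, presence, evidence,
                               minSupport = 1) {
  if (!all(c("gene_id", "hy5_mutant_DE", "chip_binding_target") %in%
           names(evidence)))
    stop("evidence table needs gene_id, hy5_mutant_DE, chip_binding_target")
  targets <- unique(aggregate$target)
  known <- union(unlist(presence, use.names = FALSE), evidence$gene_id)
  if (length(targets) > 0 && length(known) > 0 &&
      length(intersect(targets, known)) == 0)
    stop("no gene id overlap between co-expression targets and ",
         "presence/evidence tables; id namespaces disagree")
  motifs <- names(presence)
  ev <- evidence[match(targets, evidence$gene_id), , drop = FALSE]
  rows <- lapply(seq_along(targets), function(i) {
    g <- targets[i]
    e <- aggregate[aggregate$target == g, , drop = FALSE]
    support <- sum(e$support_count)
    cre <- vapply(motifs, function(m) g %in% presence[[m]], logical(1))
    de <- isTRUE(ev$hy5_mutant_DE[i])
    chip <- isTRUE(ev$chip_binding_target[i])
    if (support < minSupport || !any(cre) || !(de || chip)) return(NULL)
    out <- data.frame(gene_id = g,
                      guides = paste(sort(unique(e$guide)), collapse = ","),
                      support_count = support, stringsAsFactors = FALSE)
    for (m in motifs) out[[paste0("cre_", m)]] <- cre[[m]]
    out$hy5_mutant_DE <- de
    out$chip_binding_target <- chip
    out$category <- if ("category" %in% names(ev) && !is.na(ev$category[i]))
      as.character(ev$category[i]) else NA_character_
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(gene_id = character(), guides = character(),
                      support_count = integer(), stringsAsFactors = FALSE)
    for (m in motifs) out[[paste0("cre_", m)]] <- logical()
    out$hy5_mutant_DE <- logical()
    out$chip_binding_target <- logical()
    out$category <- character()
    return(out)
  }
  nodes <- do.call(rbind, rows)
  nodes <- nodes[order(-nodes$support_count, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Export the community network as node/edge tables and GraphML
#'
#' Writes `nodes.tsv` (one row per included gene with all attributes),
#' `edges.tsv` (guide, target, support_count, datasets; restricted to
#' included nodes), and `network.graphml` for graph viewers. Output is
#' bit-stable across runs for identical inputs.
#'
#' @param nodes Node table from [integrateCommunity()].
#' @param aggregate Aggregate network from [aggregateNetworks()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the three files written.
#' @export
exportNetwork <- function(nodes, aggregate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  node_path <- file.path(dir, "nodes.tsv")
  edge_path <- file.path(dir, "edges.tsv")
  gml_path <- file.path(dir, "network.graphml")
  edges <- aggregate[aggregate$target %in% nodes$gene_id, , drop = FALSE]
  edges <- edges[order(edges$guide, edges$target), , drop = FALSE]
  writeTsv(nodes, node_path)
  writeTsv(edges, edge_path)
  vertices <- data.frame(
    name = unique(c(unique(edges$guide), nodes$gene_id)),
    stringsAsFactors = FALSE)
  vertices$is_guide <- vertices$name %in% edges$guide &
    !vertices$name %in% nodes$gene_id
  g <- igraph::graph_from_data_frame(
    edges[, c("guide", "target", "support_count"), drop = FALSE],
    directed = TRUE, vertices = vertices)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(nodes = node_path, edges = edge_path, graphml = gml_path))
}

#' Read back an exported community node table
#'
#' @param path Path to a `nodes.tsv` written by [exportNetwork()].
#' @return data.frame with the node attributes (logical columns restored).
#' @export
readCommunityNodes <- function(path) {
  readTsv(path)
}

#' Read an ortholog evidence table
#'
#' @param path TSV with columns `gene_id`, `hy5_mutant_DE`,
#'   `chip_binding_target` (TRUE/FALSE) and optionally `category`.
#' @return data.frame.
#' @export
readEvidence <- function(path) {
  ev <- readTsv(path)
  for (cl in c("hy5_mutant_DE", "chip_binding_target"))
    if (cl %in% names(ev)) ev[[cl]] <- as.logical(ev[[cl]])
  ev
}
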