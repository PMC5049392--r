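#' Assemble a pipeline run configuration
#'
#' Collects the inputs and parameters of a full run. Either a promoter
#' FASTA or a genome FASTA plus GFF3 annotation must be supplied.
#' Expression matrices are optional; without them the co-expression,
#' enrichment, and community stages are skipped and the motif stages
#' still run.
#'
#' @param outDir Output directory for all artifacts.
#' @param genome,gff Genome FASTA and GFF3 annotation paths (used when
#'   `promoters` is `NULL`).
#' @param promoters Optional promoter FASTA path (pre-extracted).
#' @param matrices Named list (dataset id -> TSV path) of normalized
#'   expression matrices, or `NULL`.
#' @param guides Character vector of guide gene ids (required when
#'   matrices are given).
#' @param evidence Optional evidence TSV path (see [readEvidence()]);
#'   required for the community stage.
#' @param catalog Optional motif catalog YAML path; default the built-in
#'   HY5/UV-B catalog.
#' @param promoterLength,binSize,zModel,nPerm,topN,minSupport,seed
#'   Analysis parameters (defaults: 1000, 50, `"empirical_baseline"`,
#'   1000, 300, 1, 17).
#' @param normalization `"passthrough"` (default; matrices are expected
#'   pre-normalized) or `"log2p1"` for counts-like input.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(outDir, genome = NULL, gff = NULL, promoters = NULL,
                      matrices = NULL, guides = NULL, evidence = NULL,
                      catalog = NULL, promoterLength = 1000, binSize = 50,
                      zModel = "empirical_baseline", nPerm = 1000,
                      topN = 300, minSupport = 1, seed = 17,
                      normalization = "passthrough") {
  if (is.null(promoters) && (is.null(genome) || is.null(gff)))
    stop("either 'promoters' or both 'genome' and 'gff' must be given")
  for (p in c(genome, gff, promoters, evidence, catalog,
              unlist(matrices, use.names = FALSE)))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (!is.null(matrices) &&
      (is.null(names(matrices)) || any(names(matrices) == "")))
    stop("'matrices' must be a named list (dataset id -> path)")
  if (!is.null(matrices) && is.null(guides))
    stop("'guides' are required when expression matrices are given")
  structure(list(outDir = outDir, genome = genome, gff = gff,
                 promoters = promoters, matrices = matrices, guides = guides,
                 evidence = evidence, catalog = catalog,
                 promoterLength = promoterLength, binSize = binSize,
                 zModel = zModel, nPerm = nPerm, topN = topN,
                 minSupport = minSupport, seed = as.integer(seed),
                 normalization = normalization),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [runConfig()]; relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  args <- y
  for (f in c("genome", "gff", "promoters", "evidence", "catalog"))
    args[[f]] <- resolve(y[[f]])
  if (!is.null(y$matrices))
    args$matrices <- lapply(y$matrices, resolve)
  args$outDir <- resolve(y$outDir)
  do.call(runConfig, args)
}

runStage <- function(name, logPath, expr) {
  t0 <- Sys.time()
  out <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(sprintf("%s\tstage=%s\telapsed=%.2fs\n",
              format(t0, "%Y-%m-%dT%H:%M:%S"), name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = logPath, append = TRUE)
  message("stage '", name, "' done")
  out
}

#' Run the full target-discovery pipeline
#'
#' Sequences the stages — promoter extraction, catalog scan, positional
#' bias, co-expression neighborhoods and aggregation, enrichment of each
#' guide/dataset gene set, and community integration — writing a
#' deterministic directory of artifacts plus a machine-readable manifest.
#' All randomness derives from the single configured seed via per-stage
#' counters, so a rerun with the same config reproduces the statistic
#' tables exactly.
#'
#' Artifacts: `promoters.fasta`, `occurrences.tsv`, `bin_profiles.tsv`,
#' `neighborhood_<guide>_<dataset>.tsv`, `top_<guide>_<dataset>.txt`,
#' `aggregate.tsv`, `enrichment.tsv`, `community/` (nodes, edges,
#' GraphML), `run.log`, `manifest.json`.
#'
#' @param config A `RunConfig` from [runConfig()] or [readRunConfig()],
#'   or a path to a YAML configuration.
#' @return Invisibly, the output directory path.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run.log")
  cat("", file = logPath)

  catalog <- if (is.null(config$catalog)) hy5MotifCatalog()
             else readMotifCatalog(config$catalog)

  promoters <- runStage("promoters", logPath, {
    ps <- if (!is.null(config$promoters)) readPromoterFasta(config$promoters)
    else extractPromoters(config$genome, parseAnnotation(config$gff),
                          length = config$promoterLength)
    writePromoterFasta(ps, file.path(config$outDir, "promoters.fasta"))
    ps
  })

  occ <- runStage("scan", logPath, {
    o <- scanPromoters(promoters, catalog)
    writeOccurrences(o, file.path(config$outDir, "occurrences.tsv"))
    o
  })
  presence <- presenceIndex(occ, catalog)
  universe <- geneIds(promoters)

  runStage("positional_bias", logPath, {
    tab <- binProfileTable(occ, motifNames(catalog),
                           binSize = config$binSize,
                           span = config$promoterLength,
                           model = config$zModel)
    writeTsv(tab, file.path(config$outDir, "bin_profiles.tsv"))
  })

  aggregate <- NULL
  if (is.null(config$matrices)) {
    message("no expression matrices configured; ",
            "skipping co-expression, enrichment, and community stages")
  } else {
    sets <- runStage("coexpression", logPath, {
      sets <- list()
      for (ds in names(config$matrices)) {
        mat <- normalizeExpression(readExpressionMatrix(config$matrices[[ds]]),
                                   config$normalization)
        for (guide in config$guides) {
          nb <- mutualRankNeighborhood(mat, guide)
          safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
          writeTsv(nb, file.path(config$outDir,
                                 sprintf("neighborhood_%s_%s.tsv",
                                         safe(guide), safe(ds))))
          top <- topCoexpressed(nb, config$topN)
          writeLines(top, file.path(config$outDir,
                                    sprintf("top_%s_%s.txt",
                                            safe(guide), safe(ds))))
          sets[[length(sets) + 1L]] <-
            list(guide = guide, dataset = ds, targets = top)
        }
      }
      sets
    })
    aggregate <- runStage("aggregate", logPath, {
      agg <- aggregateNetworks(sets)
      writeTsv(agg, file.path(config$outDir, "aggregate.tsv"))
      agg
    })
    runStage("enrichment", logPath, {
      tabs <- lapply(seq_along(sets), function(i) {
        s <- sets[[i]]
        motifEnrichment(intersect(s$targets, universe), promoters, catalog,
                        presence, universe, nPerm = config$nPerm,
                        seed = deriveSeed(config$seed, i),
                        geneSetId = paste(s$guide, s$dataset, sep = "/"))
      })
      writeTsv(do.call(rbind, tabs),
               file.path(config$outDir, "enrichment.tsv"))
    })
    if (is.null(config$evidence)) {
      message("no evidence table configured; skipping community stage")
    } else {
      runStage("community", logPath, {
        nodes <- integrateCommunity(aggregate, presence,
                                    readEvidence(config$evidence),
                                    minSupport = config$minSupport)
        exportNetwork(nodes, aggregate,
                      file.path(config$outDir, "community"))
      })
    }
  }

  runStage("manifest", logPath, {
    files <- setdiff(list.files(config$outDir, recursive = TRUE),
                     c("manifest.json", "run.log"))
    manifest <- list(
      package = "creNet",
      version = as.character(packageVersion("creNet")),
      seed = config$seed,
      config = config[setdiff(names(config), "outDir")],
      artifacts = as.list(tools::md5sum(file.path(config$outDir, files))))
    names(manifest$artifacts) <- files
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(config$outDir)
}
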