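#' Specification for a synthetic benchmark dataset
#'
#' Describes a synthetic genome, annotation, and expression matrix with
#' known planted structure: every gene receives a background promoter
#' drawn at the AT-rich plant promoter composition; a chosen set of
#' target genes additionally receives one copy of a planted motif at a
#' TSS-biased (or uniform) offset; an optional control motif is planted
#' at uniform offsets in a disjoint gene set so positional statistics can
#' be compared against an unbiased motif; and the expression matrix
#' contains a correlated guide-gene regulon on top of independent noise.
#'
#' @param nGenes Number of genes (default 2000).
#' @param promoterLength Promoter length in bases (default 1000).
#' @param composition Background base composition (default
#'   [plantPromoterComposition()]).
#' @param plantedMotif Concrete motif planted in target promoters
#'   (default the T/G-box `CCACGTTC`).
#' @param nTargetGenes Number of promoters receiving the planted motif
#'   (default 200).
#' @param positionModel `"tss_biased"` (offset magnitude 1 + geometric
#'   with mean `positionScale`, truncated to the promoter) or
#'   `"uniform"`.
#' @param positionScale Mean TSS distance of planted offsets under
#'   `tss_biased`, in bases (default 80).
#' @param controlMotif Concrete motif planted uniformly in a disjoint
#'   gene set (default the E-box `CAATTGC`); `NULL` to skip.
#' @param nControlGenes Number of control promoters (default
#'   `nTargetGenes`).
#' @param nSamples Expression samples (default 30).
#' @param regulonSize Number of regulon member genes co-regulated with
#'   the guide (default 50); drawn from the planted target genes.
#' @param regulonEffect Standard deviation of the shared latent signal in
#'   guide and regulon genes (default 1).
#' @param noiseSd Standard deviation of gene-specific noise added to
#'   regulon genes (default 0.5); background genes get unit-variance
#'   independent noise.
#' @param guideNoiseSd Gene-specific noise of the guide itself (default
#'   0.1): the guide is the factor driving the regulon, so its
#'   expression is modeled as a near-faithful readout of the latent
#'   regulon activity while member genes respond more noisily.
#' @param seed Base RNG seed for all generator stages (default 17).
#' @return A `SimulationSpec` (validated list).
#' @export
simulationSpec <- function(nGenes = 2000, promoterLength = 1000,
                           composition = plantPromoterComposition(),
                           plantedMotif = "CCACGTTC", nTargetGenes = 200,
                           positionModel = c("tss_biased", "uniform"),
                           positionScale = 80,
                           controlMotif = "CAATTGC",
                           nControlGenes = nTargetGenes,
                           nSamples = 30, regulonSize = 50,
                           regulonEffect = 1, noiseSd = 0.5,
                           guideNoiseSd = 0.1, seed = 17) {
  positionModel <- match.arg(positionModel)
  composition <- checkComposition(composition)
  stopifnot(nGenes >= 1, promoterLength >= 1, nTargetGenes >= 0,
            nControlGenes >= 0, nSamples >= 1, regulonSize >= 0,
            regulonEffect >= 0, noiseSd >= 0, guideNoiseSd >= 0,
            positionScale > 0)
  if (nTargetGenes + nControlGenes > nGenes - 1)
    stop("target and control gene sets exceed the gene universe")
  if (regulonSize > max(nTargetGenes, 0))
    stop("regulon members are drawn from the planted targets; ",
         "regulonSize must not exceed nTargetGenes")
  if (nchar(plantedMotif) > promoterLength)
    stop("planted motif is longer than the promoter")
  if (!is.null(controlMotif) && nchar(controlMotif) > promoterLength)
    stop("control motif is longer than the promoter")
  structure(list(nGenes = as.integer(nGenes),
                 promoterLength = as.integer(promoterLength),
                 composition = composition,
                 plantedMotif = toupper(plantedMotif),
                 nTargetGenes = as.integer(nTargetGenes),
                 positionModel = positionModel,
                 positionScale = positionScale,
                 controlMotif = if (is.null(controlMotif)) NULL
                                else toupper(controlMotif),
                 nControlGenes = as.integer(nControlGenes),
                 nSamples = as.integer(nSamples),
                 regulonSize = as.integer(regulonSize),
                 regulonEffect = regulonEffect, noiseSd = noiseSd,
                 guideNoiseSd = guideNoiseSd,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

# Draw one planted offset (negative, match start) for a motif of width w.
drawOffset <- function(model, scale, w, L) {
  repeat {
    mag <- if (model == "tss_biased")
      1 + rgeom(1, prob = 1 / (1 + scale))
    else sample(seq.int(w, L), 1)
    if (mag >= w && mag <= L) return(-mag)
  }
}

#' Simulate a genome with planted promoter motifs
#'
#' Lays genes out on contigs (100 genes per contig, one 2.5-kb slot per
#' gene, strands alternating so both extraction paths are exercised),
#' fills every contig with background sequence at the spec's base
#' composition, and overwrites one window of each target promoter with
#' the planted motif at an offset drawn from the position model (the
#' control motif likewise, at uniform offsets, in a disjoint gene set).
#' Chance background matches are left in place, as in a real genome.
#' Deterministic for a given spec and seed.
#'
#' @param spec A [simulationSpec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `genome` (named [Biostrings::DNAStringSet]),
#'   `genes` (annotation data.frame as from [parseAnnotation()]), and
#'   `truth`: list with `guide`, `targets`, `planted` (data.frame
#'   `gene_id`, `motif`, `offset`), `control` (same layout), `regulon`.
#' @export
simulateGenome <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "SimulationSpec"))
  L <- spec$promoterLength
  slot <- L + 1500L
  genesPerContig <- 100L
  n <- spec$nGenes
  ids <- sprintf("gene_%04d", seq_len(n))
  contig_of <- (seq_len(n) - 1L) %/% genesPerContig + 1L
  j <- (seq_len(n) - 1L) %% genesPerContig
  s <- j * slot
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  start <- ifelse(strand == "+", s + L + 101L, s + 901L)
  end <- ifelse(strand == "+", s + L + 600L, s + 900L + 500L)
  tss <- ifelse(strand == "+", start, end)
  genes <- data.frame(gene_id = ids,
                      chrom = sprintf("chr%d", contig_of),
                      strand = strand, start = start, end = end, tss = tss,
                      stringsAsFactors = FALSE)
  withSeed(seed, {
    contigs <- vapply(seq_len(max(contig_of)), function(ci) {
      ng <- sum(contig_of == ci)
      randomDnaString(ng * slot, spec$composition)
    }, character(1))
    names(contigs) <- sprintf("chr%d", seq_along(contigs))
    guide <- ids[1L]
    pool <- sample(setdiff(ids, guide))
    targets <- sort(head(pool, spec$nTargetGenes))
    remaining <- if (spec$nTargetGenes > 0)
      pool[-seq_len(spec$nTargetGenes)] else pool
    controls <- sort(head(remaining, spec$nControlGenes))
    regulon <- sort(sample(targets, spec$regulonSize))
    plant <- function(gene_set, motif, model) {
      if (length(gene_set) == 0 || is.null(motif))
        return(data.frame(gene_id = character(), motif = character(),
                          offset = integer(), stringsAsFactors = FALSE))
      w <- nchar(motif)
      offs <- vapply(gene_set, function(g)
        drawOffset(model, spec$positionScale, w, L), numeric(1))
      for (k in seq_along(gene_set)) {
        gi <- match(gene_set[k], genes$gene_id)
        o <- offs[k]
        ch <- genes$chrom[gi]
        if (genes$strand[gi] == "+") {
          a <- genes$tss[gi] + o
          substr(contigs[ch], a, a + w - 1L) <<- motif
        } else {
          a <- genes$tss[gi] - o - w + 1L
          substr(contigs[ch], a, a + w - 1L) <<- reverseComplementChar(motif)
        }
      }
      data.frame(gene_id = gene_set, motif = motif,
                 offset = as.integer(offs), stringsAsFactors = FALSE)
    }
    planted <- plant(targets, spec$plantedMotif, spec$positionModel)
    control <- plant(controls, spec$controlMotif, "uniform")
    list(genome = Biostrings::DNAStringSet(contigs), genes = genes,
         truth = list(guide = guide, targets = targets, planted = planted,
                      control = control, regulon = regulon))
  })
}

#' Simulate a counts-like expression matrix with a planted regulon
#'
#' Generates expression under a one-factor latent model: each sample gets
#' a latent activity `z ~ N(0, 1)`; every regulon member follows
#' `regulonEffect * z` plus independent `N(0, noiseSd^2)` noise, the
#' guide follows the same signal with its own (smaller, `guideNoiseSd`)
#' noise, and all other genes are independent unit-variance noise. Latent
#' values are mapped to non-negative counts-like values via
#' `round(2^(x + 8))`, so a `log2(x + 1)` normalization approximately
#' recovers the latent scale. Deterministic for a given spec and seed.
#'
#' @param spec A [simulationSpec()].
#' @param truth Truth list from [simulateGenome()].
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return Numeric genes-by-samples matrix (gene and sample dimnames).
#' @export
simulateExpression <- function(spec, truth, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (spec$nSamples < 3L) stop("at least 3 samples are required")
  ids <- sprintf("gene_%04d", seq_len(spec$nGenes))
  stopifnot(all(c(truth$guide, truth$regulon) %in% ids))
  withSeed(seed, {
    z <- rnorm(spec$nSamples)
    x <- matrix(rnorm(spec$nGenes * spec$nSamples), nrow = spec$nGenes,
                dimnames = list(ids, sprintf("sample_%02d",
                                             seq_len(spec$nSamples))))
    members <- truth$regulon
    if (length(members) > 0)
      x[members, ] <-
        matrix(rep(spec$regulonEffect * z, each = length(members)),
               nrow = length(members)) +
        matrix(rnorm(length(members) * spec$nSamples, sd = spec$noiseSd),
               nrow = length(members))
    x[truth$guide, ] <- spec$regulonEffect * z +
      rnorm(spec$nSamples, sd = spec$guideNoiseSd)
    round(2^(x + 8))
  })
}

#' Simulate an ortholog evidence table for the planted regulon
#'
#' Emulates an incomplete cross-species evidence annotation: regulon
#' members are flagged as differentially expressed in the orthologous
#' loss-of-function mutant with probability 0.9 and as ChIP binding
#' targets with probability 0.5; background genes pick up spurious
#' mutant-DE flags at a 2% rate.
#'
#' @param spec A [simulationSpec()].
#' @param truth Truth list from [simulateGenome()].
#' @param seed RNG seed (default `spec$seed + 2`).
#' @return data.frame with `gene_id`, `hy5_mutant_DE`,
#'   `chip_binding_target` for every gene.
#' @export
simulateEvidence <- function(spec, truth, seed = spec$seed + 2L) {
  ids <- sprintf("gene_%04d", seq_len(spec$nGenes))
  withSeed(seed, {
    de <- runif(length(ids)) < 0.02
    chip <- rep(FALSE, length(ids))
    in_reg <- ids %in% truth$regulon
    de[in_reg] <- runif(sum(in_reg)) < 0.9
    chip[in_reg] <- runif(sum(in_reg)) < 0.5
    data.frame(gene_id = ids, hy5_mutant_DE = de, chip_binding_target = chip,
               stringsAsFactors = FALSE)
  })
}

#' Score pipeline output against the planted truth
#'
#' Set-arithmetic precision and recall of a predicted target list against
#' the planted regulon, plus (when an occurrence table is supplied) the
#' positional Z-scores of the planted and control motifs.
#'
#' @param predicted Character vector of predicted target gene ids.
#' @param truth Truth list from [simulateGenome()].
#' @param occurrences Optional occurrence table from [scanPromoters()].
#' @param binSize,span,model Passed to the positional-bias functions.
#' @return List with `n_shared`, `precision` (`NA` with a warning for an
#'   empty prediction), `recall`, and, if occurrences were given,
#'   `planted_z` and `control_z`.
#' @export
evaluateAgainstTruth <- function(predicted, truth, occurrences = NULL,
                                 binSize = 50, span = 1000,
                                 model = "empirical_baseline") {
  predicted <- unique(predicted)
  shared <- length(intersect(predicted, truth$regulon))
  precision <- if (length(predicted) == 0) {
    warning("empty prediction; precision undefined")
    NA_real_
  } else shared / length(predicted)
  recall <- if (length(truth$regulon) == 0) NA_real_
            else shared / length(truth$regulon)
  out <- list(n_shared = shared, precision = precision, recall = recall)
  if (!is.null(occurrences)) {
    # truth records concrete planted sequences; occurrence tables carry
    # catalog motif names, so match on either column
    zOf <- function(motif) {
      sub <- occurrences[occurrences$motif %in% motif |
                           occurrences$concrete_seq %in% motif, ,
                         drop = FALSE]
      sub$motif <- "planted"
      prof <- binOccurrences(sub, "planted", binSize, span)
      if (sum(binCounts(prof)) == 0L) return(NA_real_)
      suppressWarnings(positionalZscore(prof, model))
    }
    out$planted_z <- if (nrow(truth$planted) > 0)
      zOf(unique(truth$planted$motif)) else NA_real_
    out$control_z <- if (nrow(truth$control) > 0)
      zOf(unique(truth$control$motif)) else NA_real_
  }
  out
}

#' Write a simulated genome and annotation to standard formats
#'
#' @param sim Output of [simulateGenome()].
#' @param fastaPath,gffPath Output file paths.
#' @return Invisibly, the two paths.
#' @export
writeSimulatedGenome <- function(sim, fastaPath, gffPath) {
  Biostrings::writeXStringSet(sim$genome, fastaPath, width = 70L)
  gr <- GenomicRanges::GRanges(
    seqnames = sim$genes$chrom,
    ranges = IRanges::IRanges(sim$genes$start, sim$genes$end),
    strand = sim$genes$strand)
  gr$type <- "gene"
  gr$ID <- sim$genes$gene_id
  gr$source <- "creNet"
  rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(c(fasta = fastaPath, gff = gffPath))
}

#' Write a truth table as TSV
#'
#' One row per planted occurrence (planted and control motifs), with the
#' regulon flag and guide recorded per gene.
#'
#' @param truth Truth list from [simulateGenome()].
#' @param path Output TSV path.
#' @export
writeTruthTable <- function(truth, path) {
  df <- rbind(cbind(truth$planted, role = "target"),
              cbind(truth$control, role = "control"))
  df$in_regulon <- df$gene_id %in% truth$regulon
  df$guide <- truth$guide
  writeTsv(df, path)
}
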