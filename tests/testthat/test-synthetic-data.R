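test_that("the generator is byte-reproducible under a fixed seed", {
  spec <- simulationSpec(nGenes = 120, nTargetGenes = 20, regulonSize = 10,
                         nControlGenes = 20, nSamples = 8, seed = 5)
  a <- simulateGenome(spec)
  b <- simulateGenome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  expect_identical(simulateExpression(spec, a$truth),
                   simulateExpression(spec, b$truth))
  # and through the on-disk formats
  f1 <- tempfile(fileext = ".fa"); g1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".fa"); g2 <- tempfile(fileext = ".gff3")
  writeSimulatedGenome(a, f1, g1)
  writeSimulatedGenome(b, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("background composition converges to the specification", {
  spec <- simulationSpec(nGenes = 400, nTargetGenes = 0, regulonSize = 0,
                         nControlGenes = 0, seed = 9)
  sim <- simulateGenome(spec)  # 400 x 2.5 kb = 1e6 background bases
  freq <- Biostrings::alphabetFrequency(sim$genome, collapse = TRUE)
  freq <- freq[c("A", "C", "G", "T")] / sum(freq)
  want <- plantPromoterComposition() / sum(plantPromoterComposition())
  expect_true(all(abs(freq - want) < 0.01))
  expect_equal(nrow(sim$truth$planted), 0)
})

test_that("planted motifs are recovered by the scanner at recorded offsets", {
  run <- smallSimulation()
  occ <- scanPromoters(run$promoters, hy5MotifCatalog())
  pl <- run$sim$truth$planted
  expect_gt(nrow(pl), 0)
  for (k in seq_len(nrow(pl))) {
    hit <- occ$gene_id == pl$gene_id[k] & occ$motif == "T/G-box" &
      occ$tss_offset == pl$offset[k] & occ$strand == "+"
    expect_true(any(hit), info = pl$gene_id[k])
  }
  ctl <- run$sim$truth$control
  for (k in seq_len(nrow(ctl))) {
    hit <- occ$gene_id == ctl$gene_id[k] & occ$motif == "E-box" &
      occ$tss_offset == ctl$offset[k] & occ$strand == "+"
    expect_true(any(hit), info = ctl$gene_id[k])
  }
})

test_that("the annotation written to GFF3 reparses to the same gene models", {
  run <- smallSimulation()
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  writeSimulatedGenome(run$sim, fa, gff)
  genes <- parseAnnotation(gff)
  genes <- genes[match(run$sim$genes$gene_id, genes$gene_id), ]
  rownames(genes) <- NULL
  expect_equal(genes, run$sim$genes)
  # promoters extracted from disk equal the in-memory ones
  prom <- extractPromoters(fa, genes)
  expect_equal(as.character(promoterSeqs(prom)[geneIds(run$promoters)]),
               as.character(promoterSeqs(run$promoters)))
})

test_that("TSS-biased offsets concentrate near the TSS; uniform ones do not", {
  run <- smallSimulation()
  pl <- run$sim$truth$planted
  ctl <- run$sim$truth$control
  expect_lt(median(-pl$offset), 150)
  expect_gt(median(-ctl$offset), 250)
  expect_true(all(pl$offset <= -nchar("CCACGTTC")))
  expect_true(all(pl$offset >= -run$spec$promoterLength))
})

test_that("expression recovers the regulon when signal exists, not without", {
  spec <- simulationSpec(nGenes = 300, nTargetGenes = 40, regulonSize = 20,
                         nControlGenes = 0, nSamples = 20, seed = 21)
  sim <- simulateGenome(spec)
  mat <- normalizeExpression(simulateExpression(spec, sim$truth), "log2p1")
  top <- topCoexpressed(mutualRankNeighborhood(mat, sim$truth$guide), 20)
  expect_gte(length(intersect(top, sim$truth$regulon)) / 20, 0.9)
  # no signal: recovery collapses to chance levels
  spec0 <- simulationSpec(nGenes = 300, nTargetGenes = 40, regulonSize = 20,
                          nControlGenes = 0, nSamples = 20,
                          regulonEffect = 0, guideNoiseSd = 1, seed = 21)
  mat0 <- normalizeExpression(simulateExpression(spec0, sim$truth), "log2p1")
  top0 <- topCoexpressed(mutualRankNeighborhood(mat0, sim$truth$guide), 20)
  expect_lte(length(intersect(top0, sim$truth$regulon)), 5)
  # vanishing noise: member-guide correlation approaches 1
  specP <- simulationSpec(nGenes = 300, nTargetGenes = 40, regulonSize = 20,
                          nControlGenes = 0, nSamples = 20,
                          noiseSd = 1e-4, guideNoiseSd = 1e-4, seed = 21)
  matP <- normalizeExpression(simulateExpression(specP, sim$truth), "log2p1")
  pcc <- pccToGuide(matP, sim$truth$guide)
  expect_true(all(pcc[sim$truth$regulon] > 0.99))
})

test_that("truth scoring reports precision, recall, and positional Z", {
  run <- smallSimulation()
  truth <- run$sim$truth
  perfect <- evaluateAgainstTruth(truth$regulon, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_warning(empty <- evaluateAgainstTruth(character(), truth),
                 "undefined")
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
  occ <- scanPromoters(run$promoters, hy5MotifCatalog())
  scored <- evaluateAgainstTruth(truth$regulon, truth, occurrences = occ)
  expect_gt(scored$planted_z, 3)
  expect_lt(abs(scored$control_z), 3)
})

test_that("random predictions score at prevalence-level precision", {
  run <- smallSimulation()
  truth <- run$sim$truth
  prevalence <- length(truth$regulon) / run$spec$nGenes
  set.seed(61)
  precisions <- replicate(200, {
    pred <- sample(sprintf("gene_%04d", seq_len(run$spec$nGenes)), 40)
    evaluateAgainstTruth(pred, truth)$precision
  })
  expect_equal(mean(precisions), prevalence, tolerance = 0.3)
})

test_that("inconsistent specifications are rejected", {
  expect_error(simulationSpec(nGenes = 10, nTargetGenes = 8,
                              nControlGenes = 8), "exceed")
  expect_error(simulationSpec(nTargetGenes = 10, regulonSize = 20),
               "regulonSize")
  expect_error(simulationSpec(plantedMotif = strrep("A", 2000)),
               "longer than the promoter")
  expect_error(simulateExpression(simulationSpec(nSamples = 2),
                                  list(guide = "gene_0001",
                                       regulon = character())),
               "3 samples")
})
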