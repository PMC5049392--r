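test_that("IUPAC expansion is the Cartesian product of per-position sets", {
  cbox <- expandConsensus("HBACGTCD")
  expect_length(cbox, 27)
  expect_false(anyDuplicated(cbox) > 0)
  expect_true(all(grepl("^[ACT][CGT]ACGTC[AGT]$", cbox)))
  expect_equal(expandConsensus("ACGT"), "ACGT")
  # expansion is idempotent on concrete sequences
  expect_equal(expandConsensus(cbox[1]), cbox[1])
  expect_length(expandConsensus("NN"), 16)
})

test_that("invalid IUPAC codes are reported by character", {
  expect_error(expandConsensus("ACXGT"), "'X'")
  expect_error(expandConsensus(""), "non-empty")
})

test_that("the default catalog expands to the 83 distinct concrete motifs", {
  cat5 <- hy5MotifCatalog()
  expect_length(cat5, 5)
  expect_setequal(motifNames(cat5),
                  c("C-box", "C/A-box", "C/G-box", "E-box", "T/G-box"))
  expect_equal(expandedMotifs(cat5, "T/G-box"), "CCACGTTC")
  expect_equal(expandedMotifs(cat5, "E-box"), "CAATTGC")
  expect_length(expandedMotifs(cat5, "C-box"), 27)
  expect_equal(totalExpanded(cat5), 83)
})

test_that("catalog YAML round trip preserves patterns and expansions", {
  cat5 <- hy5MotifCatalog()
  path <- tempfile(fileext = ".yaml")
  writeMotifCatalog(cat5, path)
  back <- readMotifCatalog(path)
  expect_equal(motifNames(back), motifNames(cat5))
  for (nm in motifNames(cat5))
    expect_equal(expandedMotifs(back, nm), expandedMotifs(cat5, nm))
})

test_that("single-sequence scanning finds direct, reverse, and overlapping hits", {
  h <- scanSequence("AACCACGTTCAA", "CCACGTTC")
  expect_equal(h$start[h$strand == "+"], 3)  # 1-based
  # revcomp(CCACGTTC) = GAACGTGG appears forward => minus-strand record
  h2 <- scanSequence("GAACGTGG", "CCACGTTC")
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 1)
  expect_equal(h2$concrete_seq, "CCACGTTC")
  # overlapping occurrences are all reported
  h3 <- scanSequence("GCAATTGCAATTGC", "CAATTGC")
  expect_equal(h3$start[h3$strand == "+"], c(2, 8))
})

test_that("N positions never match and palindromes yield one record per strand", {
  expect_equal(nrow(scanSequence("AACCACGNTCAA", "CCACGTTC")), 0)
  pal <- "ACCGGT"  # its own reverse complement
  h <- scanSequence("TTACCGGTTT", pal)
  expect_equal(nrow(h), 2)
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(unique(h$start), 3)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  cat5 <- hy5MotifCatalog()
  motifs <- unlist(lapply(motifNames(cat5), expandedMotifs, x = cat5),
                   use.names = FALSE)
  set.seed(101)
  for (i in 1:60) {
    s <- randomSeq(sample(20:200, 1), c("A", "C", "G", "T", "N"))
    got <- scanSequence(s, motifs)
    want <- oracleScan(s, motifs)
    expect_equal(got, want, info = paste("sequence", i))
  }
})

test_that("minus-strand hits mirror plus-strand hits on the reverse complement", {
  cat5 <- hy5MotifCatalog()
  motifs <- expandedMotifs(cat5, "C-box")
  set.seed(102)
  for (i in 1:25) {
    s <- randomSeq(150)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    minus <- scanSequence(s, motifs)
    minus <- minus[minus$strand == "-", , drop = FALSE]
    plus_rc <- scanSequence(rc, motifs)
    plus_rc <- plus_rc[plus_rc$strand == "+", , drop = FALSE]
    # start i on the minus strand maps to start len - (i + w - 1) + 1 on rc
    w <- 8L
    expect_setequal(151L - (minus$start + w - 1L), plus_rc$start)
  }
})

test_that("promoter scanning reports TSS-relative offsets for planted motifs", {
  ps <- PromoterSet(c(
    planted = paste0(strrep("T", 940), "CCACGTTC", strrep("T", 52)),
    empty = strrep("T", 100)))
  occ <- scanPromoters(ps, hy5MotifCatalog())
  tg <- occ[occ$motif == "T/G-box", ]
  expect_equal(nrow(tg), 1)
  expect_equal(tg$gene_id, "planted")
  expect_equal(tg$tss_offset, -60)
  expect_equal(tg$strand, "+")
  idx <- presenceIndex(occ, hy5MotifCatalog())
  expect_equal(idx[["T/G-box"]], "planted")
  expect_false("empty" %in% unlist(idx))
})

test_that("concatenated scanning equals per-promoter scanning", {
  run <- smallSimulation()
  prom <- run$promoters[1:40]
  cat5 <- hy5MotifCatalog()
  occ <- scanPromoters(prom, cat5)
  for (g in geneIds(prom)[c(1, 7, 20)]) {
    s <- as.character(promoterSeqs(prom)[[g]])
    for (nm in motifNames(cat5)) {
      want <- oracleScan(s, expandedMotifs(cat5, nm))
      got <- occ[occ$gene_id == g & occ$motif == nm, ]
      expect_equal(sort(got$tss_offset), sort(want$start - nchar(s) - 1L))
    }
  }
})

test_that("presence counts never increase when promoters are truncated", {
  run <- smallSimulation()
  prom <- run$promoters
  short <- PromoterSet(setNames(
    substring(as.character(promoterSeqs(prom)), 501),
    geneIds(prom)))  # keep only the TSS-proximal 500 bases
  cat5 <- hy5MotifCatalog()
  full_idx <- presenceIndex(scanPromoters(prom, cat5), cat5)
  short_idx <- presenceIndex(scanPromoters(short, cat5), cat5)
  for (nm in motifNames(cat5)) {
    expect_true(all(short_idx[[nm]] %in% full_idx[[nm]]))
  }
})

test_that("occurrence tables round trip through TSV", {
  run <- smallSimulation()
  occ <- scanPromoters(run$promoters[1:30], hy5MotifCatalog())
  path <- tempfile(fileext = ".tsv")
  writeOccurrences(occ, path)
  expect_equal(readOccurrences(path), occ)
})
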