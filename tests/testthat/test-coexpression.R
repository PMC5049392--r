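toyMatrix <- function() {
  m <- rbind(guide = c(1, 2, 3, 4),
             up    = c(2, 4, 6, 8),
             down  = c(4, 3, 2, 1),
             noisy = c(1, 3, 2, 5),
             flat  = c(2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("normalization applies log2(x+1) or passes through unchanged", {
  m <- matrix(c(0, 7, 3, 15), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  n <- normalizeExpression(m, "log2p1")
  expect_equal(n["a", "s1"], 0)
  expect_equal(n["b", "s1"], 3)  # log2(8)
  expect_identical(normalizeExpression(m, "passthrough"), m)
  expect_error(normalizeExpression(-m, "log2p1"), "non-negative")
})

test_that("guide correlations hit the exact values on toy profiles", {
  m <- toyMatrix()
  pcc <- pccToGuide(m, "guide")
  expect_equal(unname(pcc["up"]), 1)
  expect_equal(unname(pcc["down"]), -1)
  expect_true(is.na(pcc["flat"]))  # zero variance: undefined
  m2 <- rbind(guide = c(1, 2, 3), gene = c(1, 2, 4))
  colnames(m2) <- paste0("s", 1:3)
  # closed form: cov 3/2, sds 1 and sqrt(7/3)
  expect_equal(unname(pccToGuide(m2, "gene")["guide"]),
               1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(round(unname(pccToGuide(m2, "gene")["guide"]), 3), 0.982)
})

test_that("absent or constant guides are rejected", {
  m <- toyMatrix()
  expect_error(pccToGuide(m, "nope"), "not in matrix")
  expect_error(pccToGuide(m, "flat"), "zero variance")
  expect_error(pccToGuide(m[, 1:2], "guide"), "3 samples")
})

test_that("mutual rank is the geometric mean of reciprocal ranks", {
  m <- toyMatrix()
  nb <- mutualRankNeighborhood(m, "guide")
  expect_false("flat" %in% nb$gene)   # zero-variance gene excluded
  expect_false("guide" %in% nb$gene)  # guide excluded from its own list
  up <- nb[nb$gene == "up", ]
  expect_equal(up$rank_guide_to_gene, 1)
  expect_equal(up$rank_gene_to_guide, 1)
  expect_equal(up$mutual_rank, 1)
  expect_equal(nb$mutual_rank, sqrt(nb$rank_guide_to_gene *
                                      nb$rank_gene_to_guide))
})

test_that("neighborhoods match the brute-force oracle on random matrices", {
  set.seed(55)
  for (rep in 1:4) {
    n_genes <- sample(10:50, 1)
    m <- matrix(rnorm(n_genes * 20), n_genes, 20,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), NULL))
    # plant mild structure so ranks are not pure noise
    m[2, ] <- m[1, ] + rnorm(20, sd = 0.5)
    m[3, ] <- m[1, ] + rnorm(20, sd = 0.8)
    got <- mutualRankNeighborhood(m, "g01")
    want <- oracleMutualRank(m, "g01")
    expect_equal(got$gene, want$gene)
    expect_equal(got$mutual_rank, want$mr, tolerance = 1e-12)
    expect_equal(got$pcc, want$pcc, tolerance = 1e-12)
  }
})

test_that("mutual rank is symmetric and at least 1", {
  set.seed(56)
  m <- matrix(rnorm(15 * 10), 15, 10,
              dimnames = list(sprintf("g%02d", 1:15), NULL))
  for (pair in list(c("g01", "g05"), c("g02", "g11"), c("g07", "g03"))) {
    a <- mutualRankNeighborhood(m, pair[1])
    b <- mutualRankNeighborhood(m, pair[2])
    mr_ab <- a$mutual_rank[a$gene == pair[2]]
    mr_ba <- b$mutual_rank[b$gene == pair[1]]
    expect_equal(mr_ab, mr_ba, tolerance = 1e-12)
    expect_gte(mr_ab, 1)
  }
  nb <- mutualRankNeighborhood(m, "g01")
  expect_true(all(nb$mutual_rank >= 1))
  # MR = 1 iff the two genes are each other's top partner
  m2 <- m
  m2["g02", ] <- m2["g01", ] + rnorm(10, sd = 0.01)
  nb2 <- mutualRankNeighborhood(m2, "g01")
  expect_equal(nb2$mutual_rank[nb2$gene == "g02"], 1)
})

test_that("top-N selection is capped, ordered, and deterministically tied", {
  nb <- data.frame(gene = c("b", "a", "c", "d"),
                   pcc = c(0.9, 0.9, 0.8, 0.5),
                   rank_guide_to_gene = c(1.5, 1.5, 3, 4),
                   rank_gene_to_guide = c(1.5, 1.5, 3, 4),
                   mutual_rank = c(1.5, 1.5, 3, 4),
                   stringsAsFactors = FALSE)
  expect_equal(topCoexpressed(nb, 300), c("a", "b", "c", "d"))
  expect_equal(topCoexpressed(nb, 1), "a")  # lexicographic tie-break
  expect_error(topCoexpressed(nb, 0), "at least 1")
})

test_that("aggregation counts dataset support per (guide, target)", {
  lists <- list(
    list(guide = "HY5", dataset = "atlas", targets = c("t1", "t2", "t3")),
    list(guide = "HY5", dataset = "stress", targets = c("t1", "t4")),
    list(guide = "HYH", dataset = "atlas", targets = c("t1", "t5")))
  agg <- aggregateNetworks(lists)
  expect_equal(agg$support_count[agg$guide == "HY5" & agg$target == "t1"], 2)
  expect_equal(agg$datasets[agg$guide == "HY5" & agg$target == "t1"],
               "atlas,stress")
  expect_equal(agg$support_count[agg$guide == "HYH" & agg$target == "t1"], 1)
  expect_equal(nrow(agg), 6)
  expect_false(anyDuplicated(paste(agg$guide, agg$target)) > 0)
  # disjoint lists: edge count is the sum of list lengths
  disj <- aggregateNetworks(list(
    list(guide = "g", dataset = "d1", targets = c("a", "b")),
    list(guide = "g", dataset = "d2", targets = c("c"))))
  expect_equal(nrow(disj), 3)
  expect_true(all(disj$support_count == 1))
  expect_error(aggregateNetworks(list(
    list(guide = "g", dataset = "d1", targets = "a"),
    list(guide = "g", dataset = "d1", targets = "b"))),
    "duplicate")
})

test_that("a target present in all six lists reaches support 6", {
  lists <- lapply(1:6, function(i)
    list(guide = "HY5", dataset = paste0("d", i), targets = "t1"))
  agg <- aggregateNetworks(lists)
  expect_equal(agg$support_count, 6)
})

test_that("overlap statistics reduce to set arithmetic", {
  full <- sprintf("g%03d", 1:300)
  expect_equal(overlapStats(full, full),
               list(shared_count = 300, fraction_a = 1, fraction_b = 1))
  expect_equal(overlapStats(c("a", "b"), c("c", "d"))$shared_count, 0)
  o <- overlapStats(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(o$shared_count, 2)
  expect_equal(o$fraction_a, 2 / 3)
  expect_equal(o$fraction_b, 1 / 2)
})

test_that("expression matrices round trip through TSV", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  path <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, path)
  expect_equal(readExpressionMatrix(path), m, tolerance = 1e-12)
})
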