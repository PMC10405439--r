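makeSE <- function(counts, tm, len = NULL) {
  countTable(counts, tm, lengthBp = len)
}

test_that("CPM divides by total mapped reads, not column sums", {
  cts <- matrix(c(5, 0, 250, 100), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  se <- makeSE(cts, c(s1 = 1e6, s2 = 5e6))
  cpm <- SummarizedExperiment::assay(calcCPM(se), "cpm")
  expect_equal(cpm["g1", "s1"], 5)
  expect_equal(cpm["g2", "s1"], 0)
  expect_equal(cpm["g1", "s2"], 50)
  expect_error(calcCPM(makeSE(matrix(0, 1, 1,
    dimnames = list("g", "s")), c(s = 0))), "positive")
  ## denominators below the column sums are rejected at construction
  expect_error(countTable(cts, c(s1 = 3, s2 = 5e6)), ">=")
})

test_that("CPM column sums never exceed 1e6, with equality at exhaustion", {
  for (seed in 1:5) {
    se <- makeCountTable(
      list(makeGenome(seed, nGenes = 30L,
                      plantedPULs = plantedPUL("xylan", 3L),
                      backgroundCazymeRate = 0.3)$genome),
      groupEffects = list(surface = c(), hadal = c()),
      depth = 1e6, seed = seed)
    cs <- colSums(SummarizedExperiment::assay(calcCPM(se), "cpm"))
    expect_true(all(cs <= 1e6 + 1e-6))
  }
  full <- countTable(matrix(c(4e5, 6e5), 2, 1,
                            dimnames = list(c("a", "b"), "s")), c(s = 1e6))
  expect_equal(sum(SummarizedExperiment::assay(calcCPM(full), "cpm")), 1e6)
})

test_that("RPKM normalizes by gene length and depth", {
  cts <- matrix(c(10, 6), 1, 2, dimnames = list("g1", c("s1", "s2")))
  se <- makeSE(cts, c(s1 = 1e6, s2 = 2e6), len = 1000)
  rpkm <- SummarizedExperiment::assay(calcRPKM(se), "rpkm")
  expect_equal(rpkm["g1", "s1"], 10)
  se3 <- makeSE(matrix(6, 1, 1, dimnames = list("g1", "s1")),
                c(s1 = 2e6), len = 3000)
  expect_equal(as.numeric(
    SummarizedExperiment::assay(calcRPKM(se3), "rpkm")), 1)
  ## doubling length halves RPKM
  se2 <- makeSE(cts, c(s1 = 1e6, s2 = 2e6), len = 2000)
  expect_equal(SummarizedExperiment::assay(calcRPKM(se2), "rpkm"),
               rpkm / 2)
  expect_error(calcRPKM(makeSE(cts, c(s1 = 1e6, s2 = 2e6))), "length_bp")
})

test_that("CAZyme density is genes per megabase", {
  g <- makeGenome(seed = 3L, nGenes = 25L, backgroundCazymeRate = 0)$genome
  expect_equal(cazymeDensity(g), 0)
  gp <- makeGenome(seed = 3L, nGenes = 25L,
                   plantedPULs = plantedPUL("arabinan", 3L),
                   backgroundCazymeRate = 0)$genome
  L <- sum(BiocGenerics::width(contigs(gp)))
  expect_equal(cazymeDensity(gp), 3 / (L / 1e6))
})

test_that("Shannon diversity matches its closed forms", {
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  expect_equal(shannonIndex(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  ## permutation- and scale-invariant
  x <- c(5, 1, 3, 9)
  expect_equal(shannonIndex(x), shannonIndex(rev(x)))
  expect_equal(shannonIndex(x), shannonIndex(10 * x))
  expect_error(shannonIndex(c(0, 0)), "positive")
  expect_error(shannonIndex(c(-1, 2)), "non-negative")
})

test_that("Bray-Curtis dissimilarity behaves as a bounded contrast", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 1)
  expect_equal(brayCurtis(c(1, 2), c(2, 1)), 2 / 6)
  expect_equal(brayCurtis(c(1, 5), c(5, 1)), brayCurtis(c(5, 1), c(1, 5)))
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(1:2, 1:3), "length")
  ## the matrix form agrees with the pairwise form
  m <- rbind(a = c(1, 2, 0), b = c(2, 1, 1), c = c(0, 0, 5))
  d <- as.matrix(brayCurtisMatrix(m))
  expect_equal(d["a", "b"], brayCurtis(m["a", ], m["b", ]))
  expect_equal(d["a", "c"], brayCurtis(m["a", ], m["c", ]))
})

test_that("the exact rank-sum test enumerates all group splits", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p.value, 0.1)          # 2 of the 20 splits are as extreme
  expect_match(r$method, "exact")
  ## identical multisets give p = 1
  expect_equal(rankSumTest(c(1, 2, 7), c(7, 1, 2))$p.value, 1)
  ## symmetric in the group labels
  x <- c(3, 9, 4, 10); y <- c(1, 8, 2)
  expect_equal(rankSumTest(x, y)$p.value, rankSumTest(y, x)$p.value)
  expect_error(rankSumTest(1, c(2, 3)), ">= 2")
})

test_that("exact p-values agree with wilcox.test on tie-free data", {
  set.seed(42)
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 6)
    y <- sample(c(x + 0.5, y), 6)       # interleave, still tie-free
    x <- x[1:5]
    w <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(rankSumTest(x, y)$p.value, w$p.value, tolerance = 1e-12)
  }
})

test_that("permutation p-values converge to the exact answer", {
  x <- c(12, 19, 3, 77, 45); y <- c(21, 8, 60, 33, 9, 51)
  exact <- rankSumTest(x, y)$p.value
  perm <- rankSumTest(x, y, nPerm = 10000L, seed = 7L, exactMax = 4L)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(perm$p.value - exact), 3 * se + 2e-4)
  ## seeded: reproducible
  expect_equal(perm$p.value,
               rankSumTest(x, y, nPerm = 10000L, seed = 7L,
                           exactMax = 4L)$p.value)
})

test_that("count tables round-trip through their TSV form", {
  g <- makeGenome(seed = 9L, nGenes = 30L,
                  plantedPULs = plantedPUL("arabinan", 3L))$genome
  se <- makeCountTable(list(g),
                       groupEffects = list(surface = c(), hadal = c()),
                       seed = 5L, nSamplesPerGroup = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(se, f)
  back <- readCountTable(f)
  expect_equal(SummarizedExperiment::assay(back, "counts"),
               SummarizedExperiment::assay(se, "counts"))
  expect_equal(SummarizedExperiment::colData(back)$total_mapped,
               SummarizedExperiment::colData(se)$total_mapped)
  expect_equal(SummarizedExperiment::rowData(back)$length_bp,
               SummarizedExperiment::rowData(se)$length_bp)
})
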