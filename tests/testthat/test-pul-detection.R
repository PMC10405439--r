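test_that("susC/susD classification follows the Pfam domain sets", {
  g <- tinyGenome(list(
    list(domains = c("PF00593", "PF13715")),
    list(domains = "PF07980"),
    list(domains = "PF00001"),
    list(domains = c("PF00593", "PF07980")),
    list(domains = c("PF07715", "PF99999")),
    list(domains = "PF14322")))
  cls <- unname(classifySusGenes(g))
  expect_identical(cls,
    c("susC", "susD", "none", "ambiguous", "susC", "susD"))
})

test_that("tandem pairs require adjacency, strand, and susC upstream", {
  ## canonical plus-strand pair
  expect_identical(nrow(findTandemPairs(tinyGenome(
    list(susC(), susD(), plain())))), 1L)
  ## intervening gene breaks the pair
  expect_identical(nrow(findTandemPairs(tinyGenome(
    list(susC(), plain(), susD())))), 0L)
  ## minus strand: susD then susC in genomic order is susC-upstream
  p <- findTandemPairs(tinyGenome(list(susD("-"), susC("-"))))
  expect_identical(nrow(p), 1L)
  expect_identical(p$ordinal_susC, 1L)
  ## wrong transcriptional order fails strict mode, passes relaxed
  g <- tinyGenome(list(susD(), susC()))
  expect_identical(nrow(findTandemPairs(g)), 0L)
  expect_identical(nrow(findTandemPairs(g, relaxOrder = TRUE)), 1L)
  ## strand mismatch is never a pair
  expect_identical(nrow(findTandemPairs(tinyGenome(
    list(susC("+"), susD("-"))))), 0L)
  ## ambiguous genes are excluded from pairing
  expect_identical(nrow(findTandemPairs(tinyGenome(
    list(list(domains = c("PF00593", "PF07980")), susD())))), 0L)
  ## greedy left-to-right: each gene in at most one pair
  p2 <- findTandemPairs(tinyGenome(list(susC(), susD(), susC(), susD())))
  expect_identical(nrow(p2), 2L)
  expect_identical(anyDuplicated(c(p2$susC_gene_id, p2$susD_gene_id)), 0L)
})

test_that("the seven-gene window rule calls PULs as specified", {
  ## susCD pair + two GH13 genes: one alpha-1,4-glucan PUL
  g <- tinyGenome(list(susC(), susD(), cazyme("GH13"), cazyme("GH13")))
  p <- callPULs(g)
  expect_identical(length(p), 1L)
  expect_identical(puls(p)$substrate, "alpha-1,4-glucan")
  expect_identical(puls(p)$n_genes, 4L)
  ## only one degradative gene: no call
  expect_identical(length(callPULs(tinyGenome(
    list(susC(), susD(), cazyme("GH13"))))), 0L)
  ## a gene with two GH domains counts once toward min_degradative
  expect_identical(length(callPULs(tinyGenome(
    list(susC(), susD(), cazyme(c("GH13", "GH13_8")))))), 0L)
  ## pair and degradative genes further apart than the window: no call
  far <- tinyGenome(c(list(susC(), susD()), rep(list(plain()), 6),
                      list(cazyme("GH13"), cazyme("GH13"))))
  expect_identical(length(callPULs(far)), 0L)
  ## window parameter below 3 is rejected
  expect_error(callPULs(g, window = 2L), "window")
})

test_that("trimming keeps interior accessory genes and drops edge genes", {
  g <- tinyGenome(list(plain(), susC(), susD(), cazyme("GH43"),
                       list(product = "arylsulfatase"),
                       cazyme("GH51"), plain()))
  p <- callPULs(g)
  expect_identical(length(p), 1L)
  ids <- puls(p)$gene_ids[[1]]
  expect_identical(ids, sprintf("tiny_g%03d", 2:6))  # accessory retained
})

test_that("an arabinan PUL with the hadal-strain architecture is one call", {
  ## susC, susD, then xynD/abn43/abf51/abf43/hypBA-like GH content,
  ## ending in a susB-like glucosidase
  g <- tinyGenome(list(
    susC(), susD(),
    cazyme("GH43_29"),                       # arabinoxylan hydrolase
    cazyme("GH43_4"), cazyme("GH43_5"),      # arabinanases
    cazyme("GH51"), cazyme("GH43_26"), cazyme("GH51"),  # arabinofuranosidases
    cazyme("GH127"),                         # beta-L-arabinofuranosidase
    list(families = "GH97", product = "alpha-glucosidase SusB")))
  p <- callPULs(g)
  expect_identical(length(p), 1L)
  expect_identical(puls(p)$gene_ids[[1]], genes(g)$gene_id)
  expect_identical(puls(p)$substrate, "arabinan")
})

test_that("calls are invariant to reversing the contig", {
  g <- makeGenome(seed = 21L, nGenes = 50L,
                  plantedPULs = list(plantedPUL("xylan", 3L),
                                     plantedPUL("alginate", 2L)),
                  backgroundCazymeRate = 0.2)$genome
  p1 <- pulGeneSets(callPULs(g))
  p2 <- pulGeneSets(callPULs(reverseGenome(g)))
  expect_identical(p1, p2)
})

test_that("re-calling on a called PUL's genes returns that PUL", {
  g <- makeGenome(seed = 22L, nGenes = 40L,
                  plantedPULs = plantedPUL("arabinan", 4L))$genome
  p <- callPULs(g)
  ids <- puls(p)$gene_ids[[1]]
  keep <- genes(g)[genes(g)$gene_id %in% ids]
  sub <- GenomeAnnotation(genomeID(g), contigs(g), keep,
                          proteins(g)[ids])
  p2 <- callPULs(sub)
  expect_identical(length(p2), 1L)
  expect_identical(puls(p2)$gene_ids[[1]], ids)
})

test_that("every call satisfies the PUL invariants", {
  nCalls <- 0L
  for (seed in 31:35) {
    g <- makeRandomGenome(seed, nGenes = 80L, susRate = 0.3,
                          degradativeRate = 0.4)
    p <- callPULs(g)
    nCalls <- nCalls + length(p)
    cl <- puls(p)
    for (i in seq_len(nrow(cl))) {
      expect_gte(length(cl$susC[[i]]), 1L)
      degGenes <- unique(cl$degradative_genes[[i]])
      expect_gte(length(degGenes), 2L)
      ## members consecutive in ordinal on one contig
      memb <- match(cl$gene_ids[[i]], genes(g)$gene_id)
      expect_identical(memb, seq(min(memb), max(memb)))
      expect_length(unique(as.character(
        GenomicRanges::seqnames(genes(g))[memb])), 1L)
    }
  }
  expect_gt(nCalls, 0L)
})

test_that("key-gene scans count genes genome-wide", {
  g <- tinyGenome(list(cazyme("GH16"), cazyme("GH16_3"),
                       cazyme(c("GH16", "CBM6")), cazyme("GH13"), plain()))
  expect_identical(keyGeneScan(g, c("GH16", "GH13", "PL7")),
                   c(GH16 = 3L, GH13 = 1L, PL7 = 0L))
  expect_length(keyGeneScan(g, character(0)), 0L)
  ## equals an exhaustive per-gene scan on a random genome
  rg <- makeRandomGenome(41L, nGenes = 60L)
  keys <- c("GH13", "GH43", "PL7")
  manual <- vapply(keys, function(k) sum(vapply(
    genes(rg)$cazyme_families, function(f)
      any(sub("_[0-9]+$", "", f) == k), logical(1))), integer(1))
  expect_identical(keyGeneScan(rg, keys), manual)
})
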