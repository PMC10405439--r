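test_that("GC windows are non-overlapping with the trailing partial dropped", {
  expect_equal(gcValues(gcProfile(strrep("GC", 1000))), 1.0)
  ## 2000 bp at 40% then 2000 bp at 60%
  s <- paste0(strrep(paste0(strrep("A", 3), "GG", strrep("T", 3), "CC"), 200),
              strrep(paste0("AGGG", "TCCC", "AT"), 200))
  p <- gcProfile(s)
  expect_equal(gcValues(p), c(0.40, 0.60))
  expect_warning(p0 <- gcProfile(strrep("A", 1999)), "shorter")
  expect_length(gcValues(p0), 0L)
  expect_error(gcProfile(strrep("A", 5000), windowBp = 50), ">= 100")
  ## ambiguous bases are excluded from both numerator and denominator
  pn <- gcProfile(paste0(strrep("GCAT", 250), strrep("N", 1000)))
  expect_equal(gcValues(pn), 0.5)
  expect_equal(pn@informativeBases, 1000L)
})

test_that("base-weighted window means reconstruct prefix GC exactly", {
  for (seed in c(2L, 8L)) {
    g <- makeGenome(seed, nGenes = 60L)$genome
    seqc <- contigs(g)[[1]]
    p <- gcProfile(seqc, windowBp = 2000L)
    covered <- length(p) * 2000L
    lf <- Biostrings::letterFrequency(
      Biostrings::subseq(seqc, 1, covered), c("A", "C", "G", "T"))
    prefixGC <- (lf[["G"]] + lf[["C"]]) / sum(lf)
    expect_equal(sum(gcValues(p) * p@informativeBases) /
                   sum(p@informativeBases),
                 as.numeric(prefixGC), tolerance = 1e-12)
  }
})

test_that("region GC delta compares a span against the whole genome", {
  g <- makeGenome(seed = 4L, nGenes = 30L)$genome
  L <- BiocGenerics::width(contigs(g))[1]
  r <- regionGCDelta(g, "contig_1", 1L, L)
  expect_equal(r$delta, 0)
  expect_error(regionGCDelta(g, "contig_1", 10L, L + 10L), "bounds")
  expect_error(regionGCDelta(g, "nope", 1L, 10L), "unknown contig")
})

test_that("alignment identity excludes terminal overhangs", {
  expect_equal(alignIdentity("MKLVNNW", "MKLVNNW")$percent_identity, 100)
  expect_equal(alignIdentity("AAAA", "AAAT",
                             type = "protein")$percent_identity, 75)
  ## symmetry
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYIRKQRQISFVKSHFSRELEERLGLIE"
  expect_equal(alignIdentity(a, b)$percent_identity,
               alignIdentity(b, a)$percent_identity)
  ## a trailing extension is not counted against identity
  expect_equal(alignIdentity("MKLVNNW", "MKLVNNWEEEE")$percent_identity, 100)
  expect_error(alignIdentity(Biostrings::AAString("MKL"),
                             Biostrings::DNAString("ACGT")), "alphabet")
  expect_error(alignIdentity("", "ACGT"), "non-empty")
  ## bounded in [0, 100] on arbitrary pairs
  set.seed(1)
  for (i in 1:5) {
    x <- paste(sample(Biostrings::AA_STANDARD, 30, TRUE), collapse = "")
    y <- paste(sample(Biostrings::AA_STANDARD, 25, TRUE), collapse = "")
    pid <- alignIdentity(x, y)$percent_identity
    expect_gte(pid, 0); expect_lte(pid, 100)
  }
})

test_that("self-comparison returns 100% for PUL and background", {
  g <- makeGenome(seed = 71L, nGenes = 25L,
                  plantedPULs = plantedPUL("arabinan", 3L))$genome
  p <- callPULs(g)
  res <- pulVsBackgroundIdentity(g, g, p, p)
  expect_equal(res$pul_mean_identity, 100)
  expect_equal(res$background_mean_identity, 100)
})

test_that("planted identity contrast is recovered from an HGT pair", {
  hp <- makeHGTPair(seed = 5L, donorIdentity = 80, backgroundIdentity = 60)
  pr <- callPULs(hp$recipient); pd <- callPULs(hp$donor)
  res <- pulVsBackgroundIdentity(hp$recipient, hp$donor, pr, pd)
  expect_lt(abs(res$pul_mean_identity - 80), 3)
  expect_lt(abs(res$background_mean_identity - 60), 3)
  ## pooling the (higher-identity) PUL pairs into the mean cannot lower it
  pooled <- mean(res$per_gene$percent_identity)
  expect_gte(pooled, res$background_mean_identity)
  expect_error(makeHGTPair(seed = 1L, donorIdentity = 0), "identity")
})

test_that("deletion partners are detected and intact genomes are not", {
  g <- makeGenome(seed = 81L, nGenes = 30L, meanGeneLen = 600L,
                  plantedPULs = plantedPUL("arabinan", 4L))$genome
  tr <- makeGenome(seed = 81L, nGenes = 30L, meanGeneLen = 600L,
                   plantedPULs = plantedPUL("arabinan", 4L))$truth
  rp <- callPULs(g)

  ## clean excision: one event, flanks at 100%
  q100 <- makeDeletionPartner(g, tr[1, ], flankIdentity = 100, seed = 2L)
  ev <- detectPULDeletion(g, rp, q100)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$upstream_flank_identity, 100)
  expect_equal(ev$downstream_flank_identity, 100)
  expect_identical(ev$boundary_start_gene, puls(rp)$gene_ids[[1]][1])

  ## mutated flanks: identities near the planted value
  q98 <- makeDeletionPartner(g, tr[1, ], flankIdentity = 98, seed = 3L)
  ev98 <- detectPULDeletion(g, rp, q98)
  expect_identical(nrow(ev98), 1L)
  expect_lt(abs(ev98$upstream_flank_identity - 98), 0.5)
  expect_lt(abs(ev98$downstream_flank_identity - 98), 0.5)

  ## the unmodified genome and an intact mutated partner give no events
  expect_identical(nrow(detectPULDeletion(g, rp, g)), 0L)
  intact <- makeDeletionPartner(g, tr[1, ], flankIdentity = 98, seed = 4L,
                                excise = FALSE)
  expect_identical(nrow(detectPULDeletion(g, rp, intact)), 0L)

  ## flanks diverged below the threshold are not reported
  qFar <- makeDeletionPartner(g, tr[1, ], flankIdentity = 90, seed = 5L)
  expect_identical(nrow(detectPULDeletion(g, rp, qFar)), 0L)
})

test_that("integrase proximity is reported as an annotation note", {
  spec <- c(list(list(product = "tyrosine recombinase XerC")),
            rep(list(plain()), 3),
            list(susC(), susD(), cazyme("GH43"), cazyme("GH51")))
  g <- tinyGenome(spec)
  p <- callPULs(g)
  note <- integraseNearby(g, p)
  expect_identical(nrow(note), 1L)
  expect_identical(note$distance_genes, 4L)
  expect_identical(nrow(integraseNearby(g, p, maxDistance = 2L)), 0L)
})
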