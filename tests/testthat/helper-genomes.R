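## Hand-built miniature genomes and an independent brute-force PUL caller
## used as the oracle for the sliding-window rule.

## genesSpec: list of list(domains=, families=, strand=, product=)
tinyGenome <- function(genesSpec, geneLen = 300L, gap = 100L, id = "tiny",
                       contig = "c1") {
  n <- length(genesSpec)
  starts <- gap + (seq_len(n) - 1L) * (geneLen + gap) + 1L
  ends <- starts + geneLen - 1L
  contigLen <- ends[n] + gap
  dna <- Biostrings::DNAStringSet(paste(
    rep(c("A", "C", "G", "T"), length.out = contigLen), collapse = ""))
  names(dna) <- contig
  getf <- function(g, f, d) if (is.null(g[[f]])) d else g[[f]]
  gid <- sprintf("%s_g%03d", id, seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = contig, ranges = IRanges::IRanges(starts, ends),
    strand = vapply(genesSpec, getf, character(1), "strand", "+"),
    gene_id = gid,
    domains = IRanges::CharacterList(
      lapply(genesSpec, getf, "domains", character(0))),
    cazyme_families = IRanges::CharacterList(
      lapply(genesSpec, getf, "families", character(0))),
    product = vapply(genesSpec, getf, character(1), "product", "protein"))
  prot <- Biostrings::AAStringSet(rep(paste(rep("M", 80), collapse = ""), n))
  names(prot) <- gid
  GenomeAnnotation(id, dna, gr, prot)
}

susC <- function(strand = "+") list(domains = "PF00593", strand = strand)
susD <- function(strand = "+") list(domains = "PF07980", strand = strand)
cazyme <- function(fam, strand = "+") list(families = fam, strand = strand)
plain <- function(strand = "+") list(strand = strand)

## Exhaustive window enumeration + interval merge + trim, written from
## the rule definition and independent of callPULs' implementation.
bruteForcePULs <- function(genome, window = 7L, minDeg = 2L) {
  gr <- genes(genome)
  sq <- as.character(GenomicRanges::seqnames(gr))
  std <- as.character(GenomicRanges::strand(gr))
  isC <- vapply(gr$domains, function(d)
    any(d %in% c("PF00593", "PF13715", "PF07715")), logical(1))
  isD <- vapply(gr$domains, function(d)
    any(d %in% c("PF07980", "PF12741", "PF12771", "PF14322")), logical(1))
  cls <- ifelse(isC & isD, "amb", ifelse(isC, "C", ifelse(isD, "D", "n")))
  deg <- vapply(gr$cazyme_families, function(f)
    any(grepl("^(GH|PL)[0-9]", f)), logical(1))
  out <- list()
  for (ct in unique(sq)) {
    idx <- which(sq == ct)
    n <- length(idx)
    ## greedy adjacent pairing, susC transcriptionally upstream
    pairs <- list()
    i <- 1L
    while (i < n) {
      a <- idx[i]; b <- idx[i + 1L]
      ok <- FALSE
      if (std[a] == std[b]) {
        if (std[a] == "+" && cls[a] == "C" && cls[b] == "D") ok <- TRUE
        if (std[a] == "-" && cls[a] == "D" && cls[b] == "C") ok <- TRUE
      }
      if (ok) { pairs[[length(pairs) + 1L]] <- c(i, i + 1L); i <- i + 2L }
      else i <- i + 1L
    }
    if (!length(pairs)) next
    w <- min(window, n)
    allS <- seq_len(n - w + 1L)
    degOK <- vapply(allS, function(s)
      sum(deg[idx[s:(s + w - 1L)]]) >= minDeg, logical(1))
    pairOK <- vapply(allS, function(s) any(vapply(pairs, function(p)
      p[1] >= s && p[2] <= s + w - 1L, logical(1))), logical(1))
    fired <- allS[degOK]
    anchors <- allS[degOK & pairOK]
    if (!length(anchors)) next
    ## merge overlapping fired windows; drop runs without an anchor
    merged <- list(); cur <- c(fired[1], fired[1] + w - 1L)
    curAnchor <- fired[1] %in% anchors
    for (s in fired[-1]) {
      if (s <= cur[2]) {
        cur[2] <- s + w - 1L
        curAnchor <- curAnchor || s %in% anchors
      } else {
        if (curAnchor) merged[[length(merged) + 1L]] <- cur
        cur <- c(s, s + w - 1L); curAnchor <- s %in% anchors
      }
    }
    if (curAnchor) merged[[length(merged) + 1L]] <- cur
    for (m in merged) {
      pin <- Filter(function(p) p[1] >= m[1] && p[2] <= m[2], pairs)
      qual <- sort(unique(c(unlist(pin),
                            intersect(m[1]:m[2], which(deg[idx])))))
      if (!length(qual)) next
      out[[length(out) + 1L]] <- gr$gene_id[idx[min(qual):max(qual)]]
    }
  }
  out
}

## reverse-complement a whole single-contig genome, flipping coordinates
## and strands
reverseGenome <- function(genome) {
  ctg <- contigs(genome)
  stopifnot(length(ctg) == 1L)
  L <- BiocGenerics::width(ctg)[1]
  gr <- genes(genome)
  st <- L - GenomicRanges::end(gr) + 1L
  en <- L - GenomicRanges::start(gr) + 1L
  gr2 <- GenomicRanges::GRanges(
    seqnames = names(ctg), ranges = IRanges::IRanges(st, en),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+", "-", "+"),
    gene_id = gr$gene_id, domains = gr$domains,
    cazyme_families = gr$cazyme_families, product = gr$product)
  rc <- Biostrings::reverseComplement(ctg)
  names(rc) <- names(ctg)
  GenomeAnnotation(genomeID(genome), rc, gr2, proteins(genome))
}

expectSameGenome <- function(a, b) {
  expect_identical(as.character(contigs(a)), as.character(contigs(b)))
  expect_identical(as.character(proteins(a)), as.character(proteins(b)))
  expect_identical(as.data.frame(genes(a)), as.data.frame(genes(b)))
  expect_identical(genomeID(a), genomeID(b))
}

## gene-id sets of a PULSet, canonically ordered, for set comparison
pulGeneSets <- function(p) {
  s <- lapply(puls(p)$gene_ids, function(x) sort(as.character(x)))
  s[order(vapply(s, `[`, character(1), 1L))]
}
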