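## Seeded synthetic annotated genomes with the statistical structure the
## pipeline assumes: ordered gene models on contigs, Pfam/CAZyme
## annotations, planted PULs of named substrate types, GC-shifted
## segments, cross-genome identity structure, and deletion partners.
## The nucleotide and protein tracks are statistically independent
## (proteins are not translations of their CDS spans); each carries the
## planted signal relevant to the operations that read it.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## non-degradative CAZyme families used as annotation noise
.NOISE_FAMILIES <- c("GT2", "GT4", "CE1", "CE4", "CBM6", "CBM32", "AA3")

## Composition-exact random DNA: exactly round(n * gc) G/C bases in random
## arrangement, so planted GC contrasts carry no binomial sampling noise.
.randomDNA <- function(n, gc) {
  nGC <- round(n * gc)
  nG <- nGC %/% 2L
  nA <- (n - nGC) %/% 2L
  paste(sample(c(rep("G", nG), rep("C", nGC - nG),
                 rep("A", nA), rep("T", n - nGC - nA))), collapse = "")
}

.randomProtein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

## per-residue substitution to a random different residue at rate
## (100 - identity)/100, so realized identity is binomial around target
## exactly round(L * rate) positions, uniformly placed, each substituted
## by a random different residue, so realized identity hits the target
.mutateSeq <- function(seq, identity, alphabet) {
  x <- strsplit(as.character(seq), "")[[1]]
  nMut <- round(length(x) * (100 - identity) / 100)
  for (i in sample(length(x), nMut))
    x[i] <- sample(setdiff(alphabet, x[i]), 1L)
  paste(x, collapse = "")
}

#' Specify a planted PUL
#'
#' @param substrate substrate name from the rule table.
#' @param nDiagnostic number of diagnostic degradative genes (>= 2).
#' @param includeAccessory if TRUE, an accessory (sulfatase) gene is
#'   inserted between the diagnostic genes.
#' @return list consumed by [makeGenome()].
#' @export
plantedPUL <- function(substrate, nDiagnostic = 3L, includeAccessory = FALSE) {
  stopifnot(nDiagnostic >= 2L)
  list(substrate = substrate, nDiagnostic = as.integer(nDiagnostic),
       includeAccessory = isTRUE(includeAccessory))
}

#' Generate a synthetic annotated genome with planted PULs
#'
#' Lays out \code{nGenes} gene models on one contig (lengths around
#' \code{meanGeneLen}, fixed intergenic spacing), draws the contig
#' sequence at \code{backgroundGC}, and plants each requested PUL as an
#' adjacent susC (PF00593) + susD (PF07980) pair followed by
#' \code{nDiagnostic} genes carrying families from the substrate's rule
#' entry. Planted PULs are separated from each other by at least
#' \code{minSeparation} background genes and from the contig ends by at
#' least \code{edgeGenes} (enough flanking context for deletion-partner
#' derivation); a fraction
#' \code{backgroundCazymeRate} of background genes carries a random
#' non-degradative (GT/CE/CBM/AA) family as annotation noise. All
#' randomness derives from \code{seed}: the same seed reproduces the
#' genome byte for byte.
#'
#' @param seed integer seed.
#' @param nGenes total gene count.
#' @param meanGeneLen mean gene length in bp.
#' @param intergenicLen fixed intergenic gap in bp.
#' @param backgroundGC genome GC fraction.
#' @param plantedPULs list of [plantedPUL()] specs.
#' @param backgroundCazymeRate fraction of background genes given a
#'   random non-degradative family.
#' @param minSeparation minimum background genes between planted PULs.
#' @param edgeGenes minimum background genes between a planted PUL and a
#'   contig end.
#' @param genomeID,contigID identifiers.
#' @param rules [SubstrateRules-class] the substrates are drawn from.
#' @return list with \code{genome} (a [GenomeAnnotation-class]) and
#'   \code{truth} (data.frame of planted PULs: pul_id, contig, start,
#'   end, first_gene, last_gene, gene_ids, substrate, n_diagnostic).
#' @export
makeGenome <- function(seed, nGenes = 60L, meanGeneLen = 900L,
                       intergenicLen = 150L, backgroundGC = 0.312,
                       plantedPULs = list(), backgroundCazymeRate = 0.05,
                       minSeparation = 10L, edgeGenes = 5L,
                       genomeID = paste0("synthetic-", seed),
                       contigID = "contig_1",
                       rules = substrateRules()) {
  if (length(plantedPULs) && !is.null(plantedPULs$substrate))
    plantedPULs <- list(plantedPULs)   # single spec given bare
  r <- ruleTable(rules)
  for (p in plantedPULs)
    if (!p$substrate %in% r$substrate)
      stop("unknown substrate in planted PUL: ", p$substrate)
  blockLens <- vapply(plantedPULs, function(p)
    2L + p$nDiagnostic + as.integer(p$includeAccessory), integer(1))
  nBackground <- nGenes - sum(blockLens)
  k <- length(plantedPULs)
  need <- if (k == 0L) 0L else
    2L * edgeGenes + (k - 1L) * minSeparation
  if (nBackground < need)
    stop("nGenes too small to separate ", k, " planted PUL(s) by >= ",
         minSeparation, " background genes (", edgeGenes, " at the edges)")

  withSeed(seed, {
    ## random composition of background genes into k+1 gaps: edge gaps
    ## >= edgeGenes, interior gaps >= minSeparation
    gaps <- if (k == 0L) nBackground else
      c(edgeGenes, rep(minSeparation, max(0L, k - 1L)), edgeGenes)
    extra <- nBackground - sum(gaps)
    if (k > 0L && extra > 0L) {
      add <- tabulate(sample.int(k + 1L, extra, replace = TRUE), k + 1L)
      gaps <- gaps + add
    }

    ## per-gene annotation plan
    role <- character(0); fam <- list(); dom <- list(); prod <- character(0)
    pulOf <- integer(0)
    addBackground <- function(n) {
      for (i in seq_len(n)) {
        f <- if (stats::runif(1) < backgroundCazymeRate)
          sample(.NOISE_FAMILIES, 1L) else character(0)
        role <<- c(role, "background"); fam[[length(fam) + 1L]] <<- f
        dom[[length(dom) + 1L]] <<- character(0)
        prod <<- c(prod, "hypothetical protein")
        pulOf <<- c(pulOf, 0L)
      }
    }
    addBackground(gaps[1])
    for (pi in seq_along(plantedPULs)) {
      p <- plantedPULs[[pi]]
      diagFams <- r$families[[match(p$substrate, r$substrate)]]
      role <- c(role, "susC", "susD")
      dom[[length(dom) + 1L]] <- "PF00593"
      dom[[length(dom) + 1L]] <- "PF07980"
      fam[[length(fam) + 1L]] <- character(0)
      fam[[length(fam) + 1L]] <- character(0)
      prod <- c(prod, "TonB-dependent transporter SusC",
                "SusD family glycan-binding lipoprotein")
      pulOf <- c(pulOf, pi, pi)
      nd <- p$nDiagnostic
      accAt <- if (p$includeAccessory) nd %/% 2L else -1L
      drawn <- c(diagFams[seq_len(min(nd, length(diagFams)))],
                 if (nd > length(diagFams))
                   sample(diagFams, nd - length(diagFams), replace = TRUE))
      for (d in seq_len(nd)) {
        role <- c(role, "diagnostic")
        fam[[length(fam) + 1L]] <- drawn[d]
        dom[[length(dom) + 1L]] <- character(0)
        prod <- c(prod, paste(p$substrate, "degradation enzyme"))
        pulOf <- c(pulOf, pi)
        if (d == accAt) {
          role <- c(role, "accessory")
          fam[[length(fam) + 1L]] <- character(0)
          dom[[length(dom) + 1L]] <- character(0)
          prod <- c(prod, "arylsulfatase")
          pulOf <- c(pulOf, pi)
        }
      }
      addBackground(gaps[pi + 1L])
    }
    stopifnot(length(role) == nGenes)

    ## geometry
    lens <- pmax(300L, as.integer(round(
      stats::rnorm(nGenes, meanGeneLen, 0.2 * meanGeneLen) / 3) * 3L))
    starts <- intergenicLen + cumsum(c(0L, utils::head(lens, -1L) +
                                         intergenicLen)) + 1L
    ends <- starts + lens - 1L
    contigLen <- ends[nGenes] + intergenicLen
    strand <- ifelse(role == "background",
                     sample(c("+", "-"), nGenes, TRUE), "+")

    gid <- sprintf("%s_g%04d", genomeID, seq_len(nGenes))
    seqDNA <- Biostrings::DNAStringSet(.randomDNA(contigLen, backgroundGC))
    names(seqDNA) <- contigID
    prots <- Biostrings::AAStringSet(vapply(lens, function(L)
      .randomProtein(max(50L, L %/% 3L - 1L)), character(1)))
    names(prots) <- gid

    gr <- GenomicRanges::GRanges(
      seqnames = contigID,
      ranges = IRanges::IRanges(starts, ends), strand = strand,
      gene_id = gid, domains = IRanges::CharacterList(dom),
      cazyme_families = IRanges::CharacterList(fam), product = prod)
    genome <- GenomeAnnotation(genomeID, seqDNA, gr, prots)

    truth <- do.call(rbind, lapply(seq_along(plantedPULs), function(pi) {
      idx <- which(pulOf == pi)
      data.frame(
        pul_id = sprintf("%s_true%02d", genomeID, pi),
        contig = contigID, start = starts[min(idx)], end = ends[max(idx)],
        first_gene = gid[min(idx)], last_gene = gid[max(idx)],
        gene_ids = paste(gid[idx], collapse = ";"),
        substrate = plantedPULs[[pi]]$substrate,
        n_diagnostic = plantedPULs[[pi]]$nDiagnostic)
    }))
    if (is.null(truth))
      truth <- data.frame(pul_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          first_gene = character(), last_gene = character(),
                          gene_ids = character(), substrate = character(),
                          n_diagnostic = integer())
    list(genome = genome, truth = truth)
  })
}

#' Generate an adversarial random genome
#'
#' Unlike [makeGenome()], which plants well-separated intact PULs, this
#' scrambler sprinkles susC/susD domains and degradative GH/PL families
#' over genes independently at the given rates, producing the tangled,
#' partially overlapping window configurations that exercise the
#' sliding-window caller against a brute-force oracle.
#'
#' @param seed integer seed.
#' @param nGenes gene count.
#' @param susRate per-gene probability of a susC (half) or susD (half)
#'   domain.
#' @param degradativeRate per-gene probability of a random GH/PL family.
#' @param meanGeneLen mean gene length in bp.
#' @return A [GenomeAnnotation-class].
#' @export
makeRandomGenome <- function(seed, nGenes = 120L, susRate = 0.10,
                             degradativeRate = 0.15, meanGeneLen = 450L) {
  pool <- c("GH13", "GH16", "GH43", "GH43_4", "GH5", "GH10", "GH92",
            "PL7", "PL6", "PL17", "GH2", "GH51")
  withSeed(seed, {
    lens <- pmax(150L, as.integer(round(
      stats::rnorm(nGenes, meanGeneLen, 0.2 * meanGeneLen))))
    starts <- 100L + cumsum(c(0L, utils::head(lens, -1L) + 100L)) + 1L
    ends <- starts + lens - 1L
    u <- stats::runif(nGenes)
    dom <- lapply(u, function(p) {
      if (p < susRate / 2) "PF00593"
      else if (p < susRate) "PF07980" else character(0)
    })
    fam <- lapply(stats::runif(nGenes), function(p)
      if (p < degradativeRate) sample(pool, 1L) else character(0))
    gid <- sprintf("rnd%d_g%03d", seed, seq_len(nGenes))
    dna <- Biostrings::DNAStringSet(.randomDNA(ends[nGenes] + 100L, 0.4))
    names(dna) <- "contig_1"
    gr <- GenomicRanges::GRanges(
      seqnames = "contig_1", ranges = IRanges::IRanges(starts, ends),
      strand = sample(c("+", "-"), nGenes, TRUE),
      gene_id = gid, domains = IRanges::CharacterList(dom),
      cazyme_families = IRanges::CharacterList(fam),
      product = rep("hypothetical protein", nGenes))
    GenomeAnnotation(paste0("random-", seed), dna, gr)
  })
}

#' Generate a donor/recipient genome pair sharing a PUL
#'
#' Emulates a horizontal PUL acquisition: the donor carries a planted
#' PUL; the recipient carries a copy whose proteins are mutated to
#' \code{donorIdentity} percent while all background proteins are mutated
#' to \code{backgroundIdentity} percent (orthologs throughout, so the
#' reciprocal-best-hit background is well defined). The recipient's
#' contig is drawn at \code{recipientGC} except for the PUL span, drawn
#' at \code{recipientGC + gcShift/100}; the donor genome is drawn at
#' \code{donorGC}. Defaults reproduce the contrast typical of a recently
#' acquired locus: PUL identity 79 vs background 61.8 percent, and a
#' +3.1-point GC anomaly on a 31.2 percent-GC host.
#'
#' @param seed integer seed.
#' @param nGenes genes per genome.
#' @param substrate,nDiagnostic planted PUL composition.
#' @param donorIdentity,backgroundIdentity target percent identities.
#' @param gcShift GC offset of the recipient PUL span, percentage points.
#' @param recipientGC,donorGC genome GC fractions.
#' @param ... further arguments to [makeGenome()].
#' @return list with \code{recipient}, \code{donor}
#'   ([GenomeAnnotation-class]) and \code{truth} (planted-PUL table plus
#'   the generating parameters).
#' @export
makeHGTPair <- function(seed, nGenes = 40L, substrate = "arabinan",
                        nDiagnostic = 6L, donorIdentity = 79,
                        backgroundIdentity = 61.8, gcShift = 3.1,
                        recipientGC = 0.312, donorGC = 0.362, ...) {
  if (donorIdentity <= 0 || donorIdentity > 100 ||
      backgroundIdentity <= 0 || backgroundIdentity > 100)
    stop("identity parameters must lie in (0, 100]")
  don <- makeGenome(seed, nGenes = nGenes, backgroundGC = donorGC,
                    plantedPULs = plantedPUL(substrate, nDiagnostic),
                    backgroundCazymeRate = 0,
                    genomeID = paste0("donor-", seed), ...)
  withSeed(seed + 1L, {
    grD <- genes(don$genome)
    pulGenes <- strsplit(don$truth$gene_ids, ";")[[1]]
    inPul <- grD$gene_id %in% pulGenes
    protD <- proteins(don$genome)
    newIDs <- sub("^donor", "recipient", names(protD))
    protR <- Biostrings::AAStringSet(vapply(seq_along(protD), function(i)
      .mutateSeq(protD[[i]],
                 if (inPul[i]) donorIdentity else backgroundIdentity,
                 AA20), character(1)))
    names(protR) <- newIDs

    contigLen <- BiocGenerics::width(contigs(don$genome))[1]
    span <- don$truth$start:don$truth$end
    ## the span contributes to the genome-wide mean too; inflate its GC by
    ## 1/(1 - f) so the measured region-vs-genome delta equals gcShift
    f <- length(span) / contigLen
    spanGC <- recipientGC + (gcShift / 100) / (1 - f)
    dna <- character(contigLen)
    dna[-span] <- strsplit(.randomDNA(contigLen - length(span),
                                      recipientGC), "")[[1]]
    dna[span] <- strsplit(.randomDNA(length(span), spanGC), "")[[1]]
    dnaR <- Biostrings::DNAStringSet(paste(dna, collapse = ""))
    names(dnaR) <- names(contigs(don$genome))

    grR <- grD
    grR$gene_id <- newIDs
    rec <- GenomeAnnotation(paste0("recipient-", seed), dnaR, grR, protR)

    truth <- don$truth
    truth$recipient_gene_ids <- paste(
      sub("^donor", "recipient", pulGenes), collapse = ";")
    truth$donor_identity <- donorIdentity
    truth$background_identity <- backgroundIdentity
    truth$gc_shift <- gcShift
    list(recipient = rec, donor = don$genome, truth = truth)
  })
}

#' Derive a deletion partner from a genome with a planted PUL
#'
#' Returns a copy of \code{genome} in which the planted PUL's interior
#' (every gene strictly between its first and last member) is excised —
#' gene models removed, the nucleotide span cut out, downstream
#' coordinates shifted — and the remaining sequence point-mutated to
#' \code{flankIdentity} percent nucleotide identity. With
#' \code{excise = FALSE} the PUL is left intact (only the mutation is
#' applied), giving the matched negative control.
#'
#' @param genome a [GenomeAnnotation-class] from [makeGenome()].
#' @param truthRow one row of the generator's truth table.
#' @param flankIdentity target nucleotide percent identity of conserved
#'   regions.
#' @param seed integer seed.
#' @param excise whether to actually remove the PUL interior.
#' @param id identifier of the derived genome.
#' @return A [GenomeAnnotation-class].
#' @export
makeDeletionPartner <- function(genome, truthRow, flankIdentity = 98,
                                seed = 1L, excise = TRUE,
                                id = paste0(genomeID(genome), "-partner")) {
  gr <- genes(genome)
  pulGenes <- strsplit(truthRow$gene_ids, ";")[[1]]
  memb <- match(pulGenes, gr$gene_id)
  if (anyNA(memb)) stop("planted PUL genes absent from genome")
  lo <- min(memb); hi <- max(memb)
  interior <- setdiff(lo:hi, c(lo, hi))
  ct <- as.character(GenomicRanges::seqnames(gr))[lo]

  withSeed(seed, {
    dna <- strsplit(as.character(contigs(genome)[[ct]]), "")[[1]]
    keepGene <- rep(TRUE, length(gr))
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    if (excise && length(interior)) {
      cutFrom <- en[lo] + 1L
      cutTo <- st[hi] - 1L
      shift <- cutTo - cutFrom + 1L
      dna <- dna[-(cutFrom:cutTo)]
      keepGene[interior] <- FALSE
      move <- st >= cutFrom
      st[move] <- st[move] - shift
      en[move] <- en[move] - shift
    }
    ## stratified mutation placement: an exact count per 500-bp chunk, so
    ## the realized local divergence matches the target everywhere along
    ## the contig, not just on genome average
    chunk <- 500L
    for (cs in seq(1L, length(dna), by = chunk)) {
      ce <- min(cs + chunk - 1L, length(dna))
      nMut <- round((ce - cs + 1L) * (100 - flankIdentity) / 100)
      for (i in cs - 1L + sample(ce - cs + 1L, nMut))
        dna[i] <- sample(setdiff(c("A", "C", "G", "T"), dna[i]), 1L)
    }
    dnaQ <- Biostrings::DNAStringSet(paste(dna, collapse = ""))
    names(dnaQ) <- ct

    oldIDs <- gr$gene_id[keepGene]
    gr2 <- GenomicRanges::GRanges(
      seqnames = ct,
      ranges = IRanges::IRanges(st[keepGene], en[keepGene]),
      strand = GenomicRanges::strand(gr)[keepGene],
      gene_id = paste0(id, "_", oldIDs),
      domains = gr$domains[keepGene],
      cazyme_families = gr$cazyme_families[keepGene],
      product = gr$product[keepGene])
    prot <- proteins(genome)[oldIDs[oldIDs %in% names(proteins(genome))]]
    names(prot) <- paste0(id, "_", names(prot))
    GenomeAnnotation(id, dnaQ, gr2, prot)
  })
}

#' Simulate a gene count table across sample groups
#'
#' Draws negative-binomial read counts for every CAZyme gene of the input
#' genomes across \code{nSamplesPerGroup} samples per group, with
#' per-family mean multipliers per group (e.g. a 10x multiplier for GH43
#' in the hadal group). Per-sample totals are set to \code{depth}.
#'
#' @param genomes list of [GenomeAnnotation-class] objects.
#' @param groupEffects named list: group -> named numeric vector of
#'   family-level mean multipliers (families not listed get 1).
#' @param depth total mapped reads per sample.
#' @param seed integer seed.
#' @param nSamplesPerGroup samples per group.
#' @param baseMean baseline negative-binomial mean per gene.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @return A \code{SummarizedExperiment} from [countTable()] with the
#'   group design in \code{colData(se)$group}.
#' @export
makeCountTable <- function(genomes, groupEffects, depth = 1e6, seed = 1L,
                           nSamplesPerGroup = 5L, baseMean = 50,
                           dispersion = 0.2) {
  if (any(unlist(groupEffects) <= 0)) stop("multipliers must be > 0")
  gr <- do.call(c, lapply(genomes, function(g) {
    x <- genes(g)
    x[lengths(x$cazyme_families) > 0]
  }))
  if (!length(gr)) stop("no CAZyme genes in the input genomes")
  fam <- familyLevel(vapply(gr$cazyme_families, `[`, character(1), 1L))
  groups <- names(groupEffects)
  samples <- paste0(rep(groups, each = nSamplesPerGroup), "_",
                    rep(seq_len(nSamplesPerGroup), length(groups)))
  withSeed(seed, {
    cts <- matrix(0, nrow = length(gr), ncol = length(samples),
                  dimnames = list(gr$gene_id, samples))
    for (gi in seq_along(groups)) {
      mult <- groupEffects[[gi]]
      m <- ifelse(fam %in% names(mult), mult[fam], 1)
      for (s in seq_len(nSamplesPerGroup))
        cts[, (gi - 1L) * nSamplesPerGroup + s] <-
          stats::rnbinom(length(gr), mu = baseMean * m,
                         size = 1 / dispersion)
    }
    if (any(colSums(cts) > depth))
      stop("simulated counts exceed depth; increase depth")
    countTable(cts, stats::setNames(rep(depth, length(samples)), samples),
               lengthBp = BiocGenerics::width(gr), family = fam,
               group = rep(groups, each = nSamplesPerGroup))
  })
}
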