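#' Classify susC-like / susD-like genes by Pfam domain content
#'
#' A gene is susC-like iff its domain set intersects the TonB-dependent
#' receptor domains \code{PF00593}, \code{PF13715}, \code{PF07715}; it is
#' susD-like iff it intersects the SusD-family domains \code{PF07980},
#' \code{PF12741}, \code{PF12771}, \code{PF14322}. A gene matching both
#' sets is annotation-ambiguous: it is labelled \code{"ambiguous"} and
#' excluded from tandem pairing.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param susCDomains,susDDomains domain accession sets; defaults are the
#'   canonical Sus system domains above.
#' @return Named character vector (gene_id ->
#'   \code{"susC"|"susD"|"ambiguous"|"none"}).
#' @export
classifySusGenes <- function(genome, susCDomains = SUSC_DOMAINS,
                             susDDomains = SUSD_DOMAINS) {
  dom <- genes(genome)$domains
  isC <- vapply(dom, function(d) any(d %in% susCDomains), logical(1))
  isD <- vapply(dom, function(d) any(d %in% susDDomains), logical(1))
  cls <- rep("none", length(dom))
  cls[isC] <- "susC"
  cls[isD] <- "susD"
  cls[isC & isD] <- "ambiguous"
  stats::setNames(cls, genes(genome)$gene_id)
}

#' Find tandem susCD gene pairs
#'
#' Scans each contig for the canonical Sus architecture: a susC-like and a
#' susD-like gene strictly adjacent in gene order (ordinal difference 1),
#' on the same strand, with susC transcriptionally upstream of susD (on
#' the minus strand that means susD precedes susC in genomic order).
#' Pairing is greedy left-to-right and each gene joins at most one pair.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param relaxOrder if TRUE, accept either transcriptional order of the
#'   two genes (still adjacent and same strand).
#' @return data.frame with columns \code{susC_gene_id},
#'   \code{susD_gene_id}, \code{contig_id}, \code{ordinal_susC},
#'   \code{ordinal_susD}.
#' @export
findTandemPairs <- function(genome, relaxOrder = FALSE) {
  gr <- genes(genome)
  cls <- unname(classifySusGenes(genome))
  empty <- data.frame(susC_gene_id = character(), susD_gene_id = character(),
                      contig_id = character(), ordinal_susC = integer(),
                      ordinal_susD = integer())
  if (length(gr) < 2L) return(empty)
  sq <- as.character(GenomicRanges::seqnames(gr))
  std <- as.character(GenomicRanges::strand(gr))
  rows <- list()
  for (idx in split(seq_along(gr), factor(sq, unique(sq)))) {
    i <- 1L
    while (i < length(idx)) {
      a <- idx[i]; b <- idx[i + 1L]
      ok <- std[a] == std[b] && std[a] %in% c("+", "-")
      if (ok) {
        ## transcriptionally upstream gene comes first on "+", last on "-"
        up <- if (std[a] == "+") a else b
        dn <- if (std[a] == "+") b else a
        isPair <- (cls[up] == "susC" && cls[dn] == "susD") ||
          (relaxOrder && cls[up] == "susD" && cls[dn] == "susC")
        if (isPair) {
          cIdx <- if (cls[up] == "susC") up else dn
          dIdx <- if (cls[up] == "susC") dn else up
          rows[[length(rows) + 1L]] <- data.frame(
            susC_gene_id = gr$gene_id[cIdx], susD_gene_id = gr$gene_id[dIdx],
            contig_id = sq[a], ordinal_susC = gr$ordinal[cIdx],
            ordinal_susD = gr$ordinal[dIdx])
          i <- i + 2L  # each gene belongs to at most one pair
          next
        }
      }
      i <- i + 1L
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Call polysaccharide utilization loci
#'
#' Slides a window of \code{window} consecutive genes (step 1, gene
#' ordinals, not base pairs) along each contig. An \emph{anchor} window
#' fires iff it fully contains at least one tandem susCD pair and at
#' least \code{minDegradative} distinct genes carrying a GH or PL family
#' (a gene with several GH/PL domains counts once); an \emph{extension}
#' window fires on the degradative criterion alone. Overlapping fired
#' windows on a contig are merged, merged runs lacking an anchor window
#' are discarded, and each surviving locus is trimmed to the minimal
#' consecutive gene run covering all its susCD pairs and GH/PL genes.
#' Extension windows let a locus grow past the anchor to cover its full
#' catalytic gene complement (real PULs routinely run 10+ genes beyond
#' the susCD pair), while every call still requires the strict
#' pair-plus-two-enzymes co-occurrence within one window. Accessory genes
#' (sulfatases, peptidases, transporters) interior to the trimmed run are
#' retained as members. A contig shorter than the window is scanned as a
#' single whole-contig window.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param window sliding-window width in genes (>= 3); default 7.
#' @param minDegradative minimum distinct GH/PL-carrying genes per window.
#' @param rules a [SubstrateRules-class] used to fill each call's
#'   substrate via [classifyPUL()]; \code{NULL} leaves substrates
#'   \code{"unclassified"}.
#' @param relaxOrder passed to [findTandemPairs()].
#' @param verbose if TRUE, log fired-window counts per contig.
#' @return A [PULSet-class].
#' @examples
#' g <- makeGenome(seed = 7, nGenes = 40,
#'                 plantedPULs = plantedPUL("arabinan", 4))$genome
#' callPULs(g)
#' @export
callPULs <- function(genome, window = 7L, minDegradative = 2L,
                     rules = substrateRules(), relaxOrder = FALSE,
                     verbose = FALSE) {
  if (window < 3L) stop("window must be >= 3 genes")
  gr <- genes(genome)
  pairs <- findTandemPairs(genome, relaxOrder = relaxOrder)
  degradative <- .isDegradative(gr$cazyme_families)
  sq <- as.character(GenomicRanges::seqnames(gr))

  calls <- list()
  for (ct in unique(sq)) {
    idx <- which(sq == ct)            # already in ordinal order
    n <- length(idx)
    pc <- pairs[pairs$contig_id == ct, , drop = FALSE]
    if (!nrow(pc)) next
    ## pair position = 1-based index pair within this contig
    pLo <- pmin(pc$ordinal_susC, pc$ordinal_susD) + 1L
    pHi <- pmax(pc$ordinal_susC, pc$ordinal_susD) + 1L
    deg <- degradative[idx]
    w <- min(window, n)
    fired <- integer(0)
    anchors <- integer(0)
    for (s in seq_len(n - w + 1L)) {
      e <- s + w - 1L
      if (sum(deg[s:e]) >= minDegradative) {
        fired <- c(fired, s)
        if (any(pLo >= s & pHi <= e)) anchors <- c(anchors, s)
      }
    }
    if (verbose)
      message(sprintf("contig %s: %d fired window(s), %d anchor(s)",
                      ct, length(fired), length(anchors)))
    if (!length(anchors)) next
    ## merge fired windows overlapping in gene space; keep runs holding
    ## at least one anchor window
    runs <- list()
    cur <- c(fired[1], fired[1] + w - 1L)
    hasAnchor <- fired[1] %in% anchors
    for (s in fired[-1]) {
      if (s <= cur[2]) {
        cur[2] <- s + w - 1L
        hasAnchor <- hasAnchor || s %in% anchors
      } else {
        if (hasAnchor) runs[[length(runs) + 1L]] <- cur
        cur <- c(s, s + w - 1L)
        hasAnchor <- s %in% anchors
      }
    }
    if (hasAnchor) runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      inRun <- r[1]:r[2]
      pin <- which(pLo >= r[1] & pHi <= r[2])
      qual <- sort(unique(c(pLo[pin], pHi[pin], inRun[deg[inRun]])))
      if (!length(qual)) next
      memb <- idx[min(qual):max(qual)]
      pin <- which(pLo >= min(qual) & pHi <= max(qual))
      degMemb <- memb[degradative[memb]]
      famPer <- lapply(gr$cazyme_families[degMemb], function(f)
        f[grepl("^(GH|PL)[0-9]", f)])
      calls[[length(calls) + 1L]] <- list(
        contig = ct,
        start = min(GenomicRanges::start(gr)[memb]),
        end = max(GenomicRanges::end(gr)[memb]),
        gene_ids = gr$gene_id[memb],
        susC = pc$susC_gene_id[pin], susD = pc$susD_gene_id[pin],
        degradative_families = unlist(famPer, use.names = FALSE),
        degradative_genes = rep(gr$gene_id[degMemb], lengths(famPer)))
    }
  }

  df <- S4Vectors::DataFrame(
    pul_id = if (length(calls))
      sprintf("%s_PUL%02d", genomeID(genome), seq_along(calls))
      else character(),
    contig = vapply(calls, `[[`, character(1), "contig"),
    start = vapply(calls, `[[`, integer(1), "start"),
    end = vapply(calls, `[[`, integer(1), "end"),
    n_genes = vapply(calls, function(x) length(x$gene_ids), integer(1)),
    gene_ids = IRanges::CharacterList(lapply(calls, `[[`, "gene_ids")),
    susC = IRanges::CharacterList(lapply(calls, `[[`, "susC")),
    susD = IRanges::CharacterList(lapply(calls, `[[`, "susD")),
    degradative_families = IRanges::CharacterList(
      lapply(calls, `[[`, "degradative_families")),
    degradative_genes = IRanges::CharacterList(
      lapply(calls, `[[`, "degradative_genes")),
    substrate = rep("unclassified", length(calls)),
    confidence = rep("complete", length(calls)))
  out <- new("PULSet", genomeID = genomeID(genome), calls = df)
  if (!is.null(rules) && length(out))
    out@calls$substrate <- vapply(seq_len(nrow(df)), function(i)
      classifyPUL(out, i, rules)$substrate, character(1))
  out
}

#' Count key PUL genes genome-wide
#'
#' Counts, for each key CAZyme family, the genes carrying it anywhere in
#' the genome (not restricted to called PULs). Family-level keys (GH16)
#' also count subfamily annotations (GH16_3); a key naming a subfamily
#' counts only that subfamily.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param keyFamilies character vector of GH/PL family labels.
#' @return Named integer vector, one count per key family.
#' @export
keyGeneScan <- function(genome, keyFamilies) {
  fams <- genes(genome)$cazyme_families
  out <- vapply(keyFamilies, function(k)
    sum(vapply(fams, function(f) any(matchesRuleFamily(f, k)), logical(1))),
    integer(1))
  stats::setNames(as.integer(out), keyFamilies)
}
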