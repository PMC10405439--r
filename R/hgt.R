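#' GC content in non-overlapping windows
#'
#' Splits a sequence into non-overlapping windows of \code{windowBp}
#' (trailing partial window dropped) and reports per-window GC fractions.
#' Ambiguous bases are excluded from numerator and denominator; the
#' window values, weighted by their unambiguous base counts, reconstruct
#' the GC of the covered prefix exactly.
#'
#' @param seq a \code{DNAString} or character scalar.
#' @param windowBp window size in bp (>= 100); default 2000.
#' @param contigID label stored in the profile.
#' @return A [GCProfile-class]; empty (with a warning) if the sequence is
#'   shorter than one window.
#' @export
gcProfile <- function(seq, windowBp = 2000L, contigID = "contig") {
  if (windowBp < 100L) stop("windowBp must be >= 100")
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  n <- length(seq)
  nWin <- n %/% windowBp
  overall <- .gcFraction(Biostrings::letterFrequency(seq, c("A", "C", "G", "T")))
  if (nWin == 0L) {
    warning("sequence (", n, " bp) shorter than one window of ",
            windowBp, " bp; empty profile")
    return(new("GCProfile", contigID = contigID,
               windowBp = as.integer(windowBp), gc = numeric(),
               informativeBases = integer(), overallGC = overall))
  }
  v <- Biostrings::Views(seq, start = (seq_len(nWin) - 1L) * windowBp + 1L,
                         width = windowBp)
  lf <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  info <- as.integer(rowSums(lf))
  gc <- ifelse(info > 0, (lf[, "G"] + lf[, "C"]) / info, NA_real_)
  new("GCProfile", contigID = contigID, windowBp = as.integer(windowBp),
      gc = as.numeric(gc), informativeBases = info, overallGC = overall)
}

.gcFraction <- function(lf) {
  lf <- as.numeric(lf)
  names(lf) <- c("A", "C", "G", "T")
  tot <- sum(lf)
  if (tot == 0) return(NA_real_)
  unname((lf["G"] + lf["C"]) / tot)
}

#' GC contrast between a region and its genome
#'
#' GC content of an exact nucleotide span versus the genome-wide GC over
#' all contigs, as percentages, with their difference in percentage
#' points. A horizontally acquired locus typically deviates from the host
#' genome's GC.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param contig contig ID.
#' @param start,end 1-based inclusive span on the contig.
#' @return list with \code{region_gc}, \code{genome_gc} (percent) and
#'   \code{delta} (region minus genome, percentage points).
#' @export
regionGCDelta <- function(genome, contig, start, end) {
  ctg <- contigs(genome)
  if (!contig %in% names(ctg)) stop("unknown contig: ", contig)
  len <- BiocGenerics::width(ctg)[match(contig, names(ctg))]
  if (start < 1L || end > len || start > end)
    stop("region out of bounds for contig ", contig)
  sub <- Biostrings::subseq(ctg[[contig]], start, end)
  regionGC <- .gcFraction(
    Biostrings::letterFrequency(sub, c("A", "C", "G", "T")))
  lf <- colSums(Biostrings::letterFrequency(ctg, c("A", "C", "G", "T")))
  genomeGC <- .gcFraction(lf)
  list(region_gc = 100 * regionGC, genome_gc = 100 * genomeGC,
       delta = 100 * (regionGC - genomeGC))
}

#' Percent identity from global pairwise alignment
#'
#' Global (Needleman-Wunsch, affine gaps) alignment of two sequences of
#' the same alphabet: BLOSUM62 for protein, +2/-2 match/mismatch for
#' nucleotide. Identity is the fraction of identical columns over the
#' aligned columns after excluding terminal gap overhangs.
#'
#' @param a,b sequences (\code{AAString}/\code{DNAString} or character).
#' @param type \code{"auto"} guesses protein vs nucleotide from the
#'   letters; or force \code{"protein"}/\code{"nucleotide"}.
#' @return list with \code{percent_identity} and \code{alignment_length}.
#' @examples
#' alignIdentity("AAAA", "AAAT", type = "protein")$percent_identity  # 75
#' @export
alignIdentity <- function(a, b, type = c("auto", "protein", "nucleotide")) {
  type <- match.arg(type)
  kind <- function(s) {
    if (is(s, "AAString")) return("protein")
    if (is(s, "DNAString")) return("nucleotide")
    if (grepl("[^ACGTUNacgtun]", as.character(s))) "protein" else "nucleotide"
  }
  if (type == "auto") {
    ka <- kind(a); kb <- kind(b)
    if ((is(a, "AAString") || is(b, "AAString") ||
         is(a, "DNAString") || is(b, "DNAString")) && ka != kb)
      stop("sequence alphabets differ (", ka, " vs ", kb, ")")
    type <- if (ka == "protein" || kb == "protein") "protein" else "nucleotide"
  }
  if (nchar(as.character(a)) == 0 || nchar(as.character(b)) == 0)
    stop("sequences must be non-empty")
  if (type == "protein") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(as.character(a)),
      Biostrings::AAString(as.character(b)),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(as.character(a))),
      Biostrings::DNAString(toupper(as.character(b))),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  .identityFromAlignment(pa)
}

.identityFromAlignment <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- p == "-" | s == "-"
  keep <- seq_along(p)
  while (length(keep) && gap[keep[1]]) keep <- keep[-1]
  while (length(keep) && gap[keep[length(keep)]]) keep <- keep[-length(keep)]
  if (!length(keep))
    return(list(percent_identity = 0, alignment_length = 0L))
  list(percent_identity = 100 * mean(p[keep] == s[keep]),
       alignment_length = length(keep))
}

## Alignment scores of one sequence against a set (for best-hit searches).
.scoreAgainst <- function(query, subjects) {
  Biostrings::pairwiseAlignment(
    subjects, Biostrings::AAString(as.character(query)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
}

#' PUL versus genome-background protein identity
#'
#' Quantifies the horizontal-acquisition signal of a shared PUL: the mean
#' percent identity over positionally matched PUL gene pairs, against the
#' genome-wide background mean over reciprocal-best-hit (RBH) ortholog
#' pairs among all genes outside both PULs. A laterally transferred locus
#' shows PUL identity well above the background.
#'
#' @param genomeA,genomeB [GenomeAnnotation-class] objects with proteins.
#' @param pulA,pulB [PULSet-class] calls in the two genomes.
#' @param iA,iB row index of the PUL to compare in each set.
#' @param background \code{"rbh"} (default) pairs reciprocal best hits;
#'   \code{"best"} uses every A-gene's best unidirectional hit.
#' @return list with \code{pul_mean_identity},
#'   \code{background_mean_identity} and \code{per_gene} (data.frame of
#'   all [HomologyPair-like] records with a \code{set} column).
#' @export
pulVsBackgroundIdentity <- function(genomeA, genomeB, pulA, pulB,
                                    iA = 1L, iB = 1L,
                                    background = c("rbh", "best")) {
  background <- match.arg(background)
  protA <- proteins(genomeA); protB <- proteins(genomeB)
  gidsA <- puls(pulA)$gene_ids[[iA]]
  gidsB <- puls(pulB)$gene_ids[[iB]]
  if (!all(gidsA %in% names(protA)) || !all(gidsB %in% names(protB)))
    stop("PUL member proteins missing from the genome annotation")

  ## positionally matched PUL gene pairs
  k <- min(length(gidsA), length(gidsB))
  if (length(gidsA) != length(gidsB))
    message("PUL gene counts differ (", length(gidsA), " vs ",
            length(gidsB), "); ", abs(length(gidsA) - length(gidsB)),
            " unmatched gene(s) skipped")
  pulRows <- lapply(seq_len(k), function(i) {
    al <- alignIdentity(protA[[gidsA[i]]], protB[[gidsB[i]]])
    data.frame(gene_a = gidsA[i], gene_b = gidsB[i],
               percent_identity = al$percent_identity,
               alignment_length = al$alignment_length, set = "pul")
  })

  ## background: all genes outside both PULs
  bgA <- setdiff(names(protA), gidsA)
  bgB <- setdiff(names(protB), gidsB)
  if (!length(bgA) || !length(bgB)) stop("no background genes to compare")
  sA <- protA[bgA]; sB <- protB[bgB]
  score <- matrix(NA_real_, length(bgA), length(bgB),
                  dimnames = list(bgA, bgB))
  for (j in seq_along(bgB))
    score[, j] <- .scoreAgainst(sB[[j]], sA)
  bestB <- max.col(score, ties.method = "first")        # best B per A gene
  bestA <- apply(score, 2, which.max)                   # best A per B gene
  keep <- if (background == "rbh")
    which(bestA[bestB] == seq_along(bgA)) else seq_along(bgA)
  if (!length(keep)) stop("no reciprocal-best-hit background pairs found")
  bgRows <- lapply(keep, function(i) {
    al <- alignIdentity(sA[[i]], sB[[bestB[i]]])
    data.frame(gene_a = bgA[i], gene_b = bgB[bestB[i]],
               percent_identity = al$percent_identity,
               alignment_length = al$alignment_length, set = "background")
  })

  perGene <- do.call(rbind, c(pulRows, bgRows))
  list(
    pul_mean_identity = mean(perGene$percent_identity[perGene$set == "pul"]),
    background_mean_identity =
      mean(perGene$percent_identity[perGene$set == "background"]),
    per_gene = perGene)
}

#' Detect flank-conserved PUL deletion events
#'
#' Tests whether a query genome descends from an ancestor that carried
#' the reference PUL but lost its interior: the \code{flankGenes} genes
#' on each side of the reference PUL are located in the query (each flank
#' gene anchored to its best protein match, then the flank nucleotide
#' blocks aligned globally), and a deletion event is reported iff both
#' flank blocks align at \code{>= minFlankIdentity} percent on the same
#' query contig in consistent orientation while the intervening query
#' span lacks at least 80\% of the PUL's interior genes (a gene counts as
#' present if any intervening query protein aligns at
#' \code{>= presenceIdentity} percent).
#'
#' @param reference [GenomeAnnotation-class] carrying the PUL.
#' @param refPul [PULSet-class] for the reference.
#' @param query [GenomeAnnotation-class] to screen.
#' @param iRef row index of the PUL in \code{refPul}.
#' @param flankGenes genes per flank block (default 3).
#' @param minFlankIdentity minimum nucleotide percent identity per flank.
#' @param presenceIdentity protein percent identity above which an
#'   interior gene counts as still present.
#' @return data.frame of deletion events (possibly zero rows) with
#'   columns \code{reference_pul_id}, \code{query_genome_id},
#'   \code{upstream_flank_identity}, \code{downstream_flank_identity},
#'   \code{boundary_start_gene}, \code{boundary_end_gene},
#'   \code{interior_missing_fraction}.
#' @export
detectPULDeletion <- function(reference, refPul, query, iRef = 1L,
                              flankGenes = 3L, minFlankIdentity = 97.0,
                              presenceIdentity = 40.0) {
  grR <- genes(reference)
  memb <- match(puls(refPul)$gene_ids[[iRef]], grR$gene_id)
  ct <- as.character(GenomicRanges::seqnames(grR))[memb[1]]
  onCt <- which(as.character(GenomicRanges::seqnames(grR)) == ct)
  lo <- min(memb); hi <- max(memb)
  if (lo - flankGenes < min(onCt) || hi + flankGenes > max(onCt))
    stop("reference PUL needs >= ", flankGenes, " genes on each side")
  upIdx <- (lo - flankGenes):(lo - 1L)
  dnIdx <- (hi + 1L):(hi + flankGenes)

  empty <- data.frame(
    reference_pul_id = character(), query_genome_id = character(),
    upstream_flank_identity = numeric(), downstream_flank_identity = numeric(),
    boundary_start_gene = character(), boundary_end_gene = character(),
    interior_missing_fraction = numeric())

  grQ <- genes(query)
  protQ <- proteins(query)
  protR <- proteins(reference)
  qLen <- BiocGenerics::width(protQ)

  anchor <- function(refGene) {
    p <- protR[[refGene]]
    dl <- abs(qLen - length(p)) / length(p)
    cand <- which(dl <= 0.3)
    if (!length(cand)) cand <- order(dl)[seq_len(min(10L, length(dl)))]
    if (length(cand) > 30L) cand <- cand[order(dl[cand])][1:30]
    sc <- .scoreAgainst(p, protQ[cand])
    best <- cand[which.max(sc)]
    al <- alignIdentity(p, protQ[[best]])
    if (al$percent_identity < 50) return(NA_integer_)
    match(names(protQ)[best], grQ$gene_id)
  }
  upQ <- vapply(grR$gene_id[upIdx], anchor, integer(1))
  dnQ <- vapply(grR$gene_id[dnIdx], anchor, integer(1))
  if (anyNA(upQ) || anyNA(dnQ)) return(empty)

  sqQ <- as.character(GenomicRanges::seqnames(grQ))
  if (length(unique(sqQ[c(upQ, dnQ)])) != 1L) return(empty)
  ## consistent orientation: both blocks internally monotone the same way,
  ## and the two blocks ordered accordingly
  dirUp <- sign(diff(range(upQ))) * sign(upQ[length(upQ)] - upQ[1])
  forward <- all(diff(upQ) > 0) && all(diff(dnQ) > 0) && max(upQ) < min(dnQ)
  reverse <- all(diff(upQ) < 0) && all(diff(dnQ) < 0) && min(upQ) > max(dnQ)
  if (!forward && !reverse) return(empty)

  blockSpan <- function(gr, idx)
    c(min(GenomicRanges::start(gr)[idx]), max(GenomicRanges::end(gr)[idx]))
  flankIdent <- function(refIdx, qIdx) {
    rs <- blockSpan(grR, refIdx); qs <- blockSpan(grQ, qIdx)
    a <- Biostrings::subseq(contigs(reference)[[ct]], rs[1], rs[2])
    b <- Biostrings::subseq(contigs(query)[[sqQ[qIdx[1]]]], qs[1], qs[2])
    if (reverse) b <- Biostrings::reverseComplement(b)
    alignIdentity(a, b, type = "nucleotide")$percent_identity
  }
  upId <- flankIdent(upIdx, upQ)
  dnId <- flankIdent(dnIdx, dnQ)
  if (upId < minFlankIdentity || dnId < minFlankIdentity) return(empty)

  ## interior presence test between the located flank blocks
  interior <- memb[-c(which.min(memb), which.max(memb))]
  between <- if (forward)
    which(seq_along(grQ) > max(upQ) & seq_along(grQ) < min(dnQ) &
            sqQ == sqQ[upQ[1]])
  else
    which(seq_along(grQ) > max(dnQ) & seq_along(grQ) < min(upQ) &
            sqQ == sqQ[upQ[1]])
  present <- vapply(interior, function(i) {
    if (!length(between)) return(FALSE)
    p <- protR[[grR$gene_id[i]]]
    any(vapply(between, function(j) {
      q <- protQ[[grQ$gene_id[j]]]
      alignIdentity(p, q)$percent_identity >= presenceIdentity
    }, logical(1)))
  }, logical(1))
  missingFrac <- if (length(interior)) mean(!present) else 1
  if (missingFrac < 0.8) return(empty)

  data.frame(
    reference_pul_id = puls(refPul)$pul_id[iRef],
    query_genome_id = genomeID(query),
    upstream_flank_identity = upId,
    downstream_flank_identity = dnId,
    boundary_start_gene = grR$gene_id[lo],
    boundary_end_gene = grR$gene_id[hi],
    interior_missing_fraction = missingFrac)
}

#' Note phage integrases near a PUL
#'
#' Reports, as an informational annotation (no score), any gene whose
#' product label mentions an integrase or recombinase within a given
#' ordinal distance of a called PUL — tyrosine recombinases near acquired
#' PULs are a recurrent mobilization signature.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param pulSet a [PULSet-class].
#' @param maxDistance maximum gene-ordinal distance (default 40).
#' @return data.frame with columns \code{pul_id}, \code{gene_id},
#'   \code{product}, \code{distance_genes}.
#' @export
integraseNearby <- function(genome, pulSet, maxDistance = 40L) {
  gr <- genes(genome)
  hits <- grepl("integrase|recombinase", gr$product, ignore.case = TRUE)
  out <- list()
  cl <- puls(pulSet)
  for (i in seq_len(nrow(cl))) {
    memb <- match(cl$gene_ids[[i]], gr$gene_id)
    sameCt <- as.character(GenomicRanges::seqnames(gr)) ==
      as.character(cl$contig[i])
    for (j in which(hits & sameCt)) {
      d <- min(abs(gr$ordinal[j] - gr$ordinal[memb]))
      if (d > 0 && d <= maxDistance)
        out[[length(out) + 1L]] <- data.frame(
          pul_id = cl$pul_id[i], gene_id = gr$gene_id[j],
          product = gr$product[j], distance_genes = d)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pul_id = character(), gene_id = character(),
               product = character(), distance_genes = integer())
}
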